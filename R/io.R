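# CSV readers with fail-fast schema validation (named column and row in
# every diagnostic) and a writer that keeps outputs byte-stable.

.check_columns <- function(df, need, what) {
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(what, " is missing column(s): ", paste(missing_cols, collapse = ", "))
}

.check_numeric <- function(df, cols, what) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v))
      stop(what, ": column '", col, "' must be numeric")
    if (anyNA(v))
      stop(what, ": column '", col, "' has missing value(s) in row(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
  }
}

#' Read a recapture-session table
#'
#' One row per recapture replicate; columns `colony`, `year`, `marked`,
#' `replicate_id`, `total_count`, `marked_count`.  Violations of the
#' session invariants (`marked_count <= min(marked, total_count)`) abort
#' with the offending row numbers.
#'
#' @param path CSV path (UTF-8, header row).
#' @return Validated data frame.
#' @export
read_recapture_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("colony", "year", "marked", "replicate_id",
                       "total_count", "marked_count"), "recapture table")
  .check_numeric(df, c("year", "marked", "total_count", "marked_count"),
                 "recapture table")
  bad <- which(df$marked_count > df$total_count | df$marked_count > df$marked |
                 df$marked_count < 0 | df$total_count < 0 | df$marked < 0)
  if (length(bad))
    stop("recapture table: invalid replicate(s) in row(s) ",
         paste(bad, collapse = ", "),
         " (need 0 <= marked_count <= min(marked, total_count))")
  df
}

#' Read a dead-pup count table
#'
#' @param path CSV with columns `colony`, `year`, `dead_count`.
#' @return Validated data frame.
#' @export
read_dead_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("colony", "year", "dead_count"), "dead-count table")
  .check_numeric(df, c("year", "dead_count"), "dead-count table")
  if (any(df$dead_count < 0))
    stop("dead-count table: negative count(s) in row(s) ",
         paste(which(df$dead_count < 0), collapse = ", "))
  df
}

#' Read a pup biometric table
#'
#' Columns `colony`, `year`, `day`, `sex`, `mass`, `length`; records
#' outside the plausibility windows are dropped with a warning (see
#' [validate_pup_records()]).
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_biometrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("colony", "year", "day", "sex", "mass", "length"),
                 "biometric table")
  .check_numeric(df, c("year", "day", "mass", "length"), "biometric table")
  validate_pup_records(df)
}

#' Write a pipeline table
#'
#' Plain `write.csv` without row names so re-runs of an identical
#' configuration are byte-identical.
#'
#' @param df Data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
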