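#' Body condition index 1: mass over length
#'
#' @param mass Pup mass in kg (> 0).
#' @param length Pup nose-to-tail length in cm (> 0).
#' @return Mass/length in kg/cm (vectorised).
#' @export
bci1 <- function(mass, length) {
  if (any(length <= 0)) stop("length must be positive")
  if (any(mass <= 0)) stop("mass must be positive")
  mass / length
}

# Plausibility windows for loaded biometric records, padded outward from the
# observed across-colony ranges (~2.16-13 kg, lengths implied by those masses).
.mass_window <- c(1, 20)     # kg
.length_window <- c(40, 120) # cm

#' Validate pup biometric records
#'
#' Rejects records with mass outside \[1, 20\] kg or length outside
#' \[40, 120\] cm, with a warning naming how many were dropped — rejection
#' is logged, never silent.
#'
#' @param records Data frame with columns `colony`, `year`, `day`, `sex`,
#'   `mass`, `length` (sex in `"male"`, `"female"`, `"unknown"`).
#' @return The validated (possibly reduced) data frame.
#' @export
validate_pup_records <- function(records) {
  need <- c("colony", "year", "day", "sex", "mass", "length")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("biometric table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_sex <- !records$sex %in% c("male", "female", "unknown")
  if (any(bad_sex))
    stop("invalid sex value(s) in row(s) ",
         paste(utils::head(which(bad_sex), 5), collapse = ", "))
  ok <- records$mass >= .mass_window[1] & records$mass <= .mass_window[2] &
    records$length >= .length_window[1] & records$length <= .length_window[2]
  if (any(!ok))
    warning(sum(!ok), " record(s) outside the mass [1,20] kg / length ",
            "[40,120] cm plausibility window were rejected")
  records[ok, , drop = FALSE]
}

#' Fit the pooled log-log allometric mass-length regression
#'
#' Ordinary least squares of `log(mass)` on `log(length)`:
#' `log(ExpM) = a + b * log(Length)`.  The default reference population is
#' every pup at every colony in every year; expected mass for any pup then
#' comes from the fitted power law.
#'
#' @param records Data frame with `mass` (kg) and `length` (cm) columns.
#' @return An object of class `allometry_fit` with elements `a` (intercept,
#'   log-kg scale), `b` (allometric elasticity), `n`, `residual_sd` and the
#'   underlying `lm` fit.
#' @export
fit_allometry <- function(records) {
  if (nrow(records) < 3L) stop("need at least 3 records to fit the allometry")
  if (length(unique(records$length)) < 2L)
    stop("all lengths identical: singular design")
  fit <- stats::lm(log(mass) ~ log(length), data = records)
  r <- stats::residuals(fit)
  structure(
    list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
         n = nrow(records),
         residual_sd = if (nrow(records) > 2) stats::sigma(fit) else 0,
         lm = fit),
    class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf("Allometric fit: log(ExpM) = %.4f + %.4f * log(Length)  (n = %d, residual sd = %.4f)\n",
              x$a, x$b, x$n, x$residual_sd))
  invisible(x)
}

#' Expected mass under an allometric fit
#'
#' @param length Length in cm.
#' @param fit An [fit_allometry()] object.
#' @return Expected mass in kg.
#' @export
expected_mass <- function(length, fit) {
  stopifnot(inherits(fit, "allometry_fit"))
  exp(fit$a + fit$b * log(length))
}

#' Add condition indices to pup records
#'
#' Computes BCI1 (mass/length), the allometric expected mass, and BCI2
#' (observed mass / expected mass).  BCI2 > 1 means a pup is heavier than
#' the pooled mass-length relation predicts (better-than-expected
#' condition); BCI2 < 1 means worse-than-expected.
#'
#' @param records Validated pup records (see [validate_pup_records()]).
#' @param fit An [fit_allometry()] object; defaults to a fit on `records`
#'   themselves (the pooled all-colonies, all-years reference).
#' @return `records` with columns `bci1`, `expected_mass` and `bci2` added.
#' @export
add_condition <- function(records, fit = fit_allometry(records)) {
  records$bci1 <- bci1(records$mass, records$length)
  records$expected_mass <- expected_mass(records$length, fit)
  records$bci2 <- records$mass / records$expected_mass
  records
}

#' Classify colony-year condition as better or worse than expected
#'
#' A colony-year is `better` when the arithmetic mean of its pups' BCI2
#' values is strictly greater than 1, otherwise `worse` (a mean of exactly
#' 1 is labelled worse: better-than-expected is a strict inequality).
#'
#' @param cond Data frame from [add_condition()] (needs `colony`, `year`,
#'   `bci2`).
#' @return Data frame with `colony`, `year`, `n`, `mean_bci2`, `status`.
#' @export
classify_condition <- function(cond) {
  if (!"bci2" %in% names(cond)) stop("run add_condition() first: no bci2 column")
  parts <- split(cond, list(cond$colony, cond$year), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    if (nrow(d) == 0L) stop("empty colony-year group")
    m <- mean(d$bci2)
    data.frame(colony = d$colony[1], year = d$year[1], n = nrow(d),
               mean_bci2 = m, status = if (m > 1) "better" else "worse",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$colony, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}
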