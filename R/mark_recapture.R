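#' Bias-corrected (Chapman) Petersen estimate for one recapture replicate
#'
#' Computes the modified Petersen estimate
#' \deqn{P_i = \frac{(M+1)(C_i+1)}{R_i+1} - 1}
#' where `M` pups were marked, `Ci` pups were counted in the recapture
#' replicate and `Ri` of those were marked.  The +1 correction keeps the
#' estimate finite when no marked pups are resighted and removes most of the
#' small-sample bias of the raw Lincoln-Petersen ratio.
#'
#' @param marked Integer, number of pups marked (M >= 0).
#' @param total_count Integer, total pups counted in the replicate (Ci >= 0).
#' @param marked_count Integer, marked pups counted in the replicate
#'   (Ri, with Ri <= min(M, Ci)).
#' @return Numeric abundance estimate (vectorised over the inputs).
#' @examples
#' petersen_replicate(100, 50, 25)  # 101 * 51 / 26 - 1
#' @export
petersen_replicate <- function(marked, total_count, marked_count) {
  if (any(marked < 0) || any(total_count < 0) || any(marked_count < 0))
    stop("marked, total_count and marked_count must all be non-negative")
  if (any(marked_count > marked))
    stop("marked_count exceeds the number of marked pups: inconsistent field data")
  if (any(marked_count > total_count))
    stop("marked_count exceeds total_count: inconsistent field data")
  (marked + 1) * (total_count + 1) / (marked_count + 1) - 1
}

#' Construct a recapture session
#'
#' One colony-year marking event: `M` marked pups followed by `Q` replicate
#' recapture counts.  Replicates are assumed independent given the (closed)
#' population: pups mingle between counts and tag loss over the short
#' marking-to-recapture interval is taken to be zero.
#'
#' @param colony Colony identifier.
#' @param year Integer breeding-season label (later-year convention, e.g.
#'   1991 for the 1990/91 season).
#' @param marked Integer number of pups marked.
#' @param total_counts Integer vector, total pups counted per replicate.
#' @param marked_counts Integer vector, marked pups counted per replicate.
#' @return An object of class `recapture_session`.
#' @export
recapture_session <- function(colony, year, marked, total_counts, marked_counts) {
  if (length(total_counts) != length(marked_counts))
    stop("total_counts and marked_counts must have equal length")
  if (length(total_counts) < 1L)
    stop("a recapture session needs at least one replicate")
  if (any(marked_counts > total_counts))
    stop("marked_count exceeds total_count in replicate(s) ",
         paste(which(marked_counts > total_counts), collapse = ", "))
  if (any(marked_counts > marked))
    stop("marked_count exceeds the number marked in replicate(s) ",
         paste(which(marked_counts > marked), collapse = ", "))
  structure(
    list(colony = as.character(colony), year = as.integer(year),
         marked = as.integer(marked),
         replicates = data.frame(total_count = as.integer(total_counts),
                                 marked_count = as.integer(marked_counts))),
    class = "recapture_session")
}

#' Mean Petersen estimate with replicate-based uncertainty
#'
#' The session estimate `P` is the arithmetic mean of the `Q` per-replicate
#' Petersen estimates; its standard error is the replicate spread
#' \deqn{SE = \sqrt{\frac{1}{Q(Q-1)} \sum_i (P_i - P)^2},}
#' algebraically the sample standard deviation of the `Pi` divided by
#' `sqrt(Q)`.  Confidence intervals use a Student-t quantile with `Q - 1`
#' degrees of freedom by default (`ci_method = "normal"` gives the plain
#' z-interval); intervals are truncated below at zero.  With a single
#' replicate the mean is defined but SE and CI are reported as `NA` —
#' a zero there would misrepresent certainty.
#'
#' @param session A [recapture_session()].
#' @param ci_level Confidence level, default 0.95.
#' @param ci_method `"t"` (default) or `"normal"`.
#' @return A one-row data frame with columns `colony`, `year`,
#'   `mean_estimate`, `se`, `ci_lower`, `ci_upper`, `n_replicates`.
#' @export
petersen_mean <- function(session, ci_level = 0.95, ci_method = c("t", "normal")) {
  stopifnot(inherits(session, "recapture_session"))
  ci_method <- match.arg(ci_method)
  reps <- session$replicates
  pi_hat <- petersen_replicate(session$marked, reps$total_count, reps$marked_count)
  q <- length(pi_hat)
  p <- mean(pi_hat)
  if (q >= 2L) {
    se <- sqrt(sum((pi_hat - p)^2) / (q * (q - 1)))
    mult <- switch(ci_method,
                   t      = stats::qt(1 - (1 - ci_level) / 2, df = q - 1),
                   normal = stats::qnorm(1 - (1 - ci_level) / 2))
    lo <- max(0, p - mult * se)
    hi <- p + mult * se
  } else {
    se <- NA_real_; lo <- NA_real_; hi <- NA_real_
  }
  data.frame(colony = session$colony, year = session$year,
             mean_estimate = p, se = se, ci_lower = lo, ci_upper = hi,
             n_replicates = q, stringsAsFactors = FALSE)
}

#' Abundance estimates for a table of recapture sessions
#'
#' Applies [petersen_mean()] to every colony-year in a tidy replicate table
#' (one row per recapture count).
#'
#' @param sessions Data frame with columns `colony`, `year`, `marked`,
#'   `total_count`, `marked_count`.
#' @inheritParams petersen_mean
#' @return Data frame of abundance estimates, one row per colony-year,
#'   ordered by colony then year.
#' @export
estimate_abundance <- function(sessions, ci_level = 0.95,
                               ci_method = c("t", "normal")) {
  ci_method <- match.arg(ci_method)
  need <- c("colony", "year", "marked", "total_count", "marked_count")
  missing_cols <- setdiff(need, names(sessions))
  if (length(missing_cols))
    stop("sessions table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(sessions$marked_count > pmin(sessions$marked, sessions$total_count))
  if (length(bad))
    stop("marked_count exceeds min(marked, total_count) in row(s) ",
         paste(bad, collapse = ", "))
  parts <- split(sessions, list(sessions$colony, sessions$year), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    m <- unique(d$marked)
    if (length(m) != 1L)
      stop("inconsistent 'marked' within colony ", d$colony[1],
           " year ", d$year[1])
    petersen_mean(recapture_session(d$colony[1], d$year[1], m,
                                    d$total_count, d$marked_count),
                  ci_level = ci_level, ci_method = ci_method)
  }))
  out <- out[order(out$colony, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dead pups as a percentage of total pups (live plus dead)
#'
#' @param dead_count Integer count of dead pups (>= 0).
#' @param live_estimate Live pup abundance estimate (>= 0).
#' @return Percentage in \[0, 100\] (vectorised).
#' @export
dead_pup_fraction <- function(dead_count, live_estimate) {
  if (any(dead_count < 0) || any(live_estimate < 0))
    stop("dead_count and live_estimate must be non-negative")
  if (any(dead_count + live_estimate <= 0))
    stop("empty colony-year record: dead_count and live_estimate both zero")
  100 * dead_count / (dead_count + live_estimate)
}

#' Percentage change between two surveys
#'
#' @param start_value Abundance (or any positive quantity) at the first survey.
#' @param end_value Value at the later survey.
#' @return `100 * (end - start) / start` (vectorised).
#' @export
period_percent_change <- function(start_value, end_value) {
  if (any(start_value <= 0)) stop("start_value must be positive")
  100 * (end_value - start_value) / start_value
}

#' Compose period percentage changes multiplicatively
#'
#' Successive period changes compound: a -78.7% fall followed by -20.5%
#' totals `100 * (0.213 * 0.795 - 1)` = -83.1%, not the sum.  Order of the
#' periods does not matter.
#'
#' @param changes Numeric vector of period percentage changes, each > -100.
#' @return The compound percentage change.
#' @export
compound_percent_changes <- function(changes) {
  if (any(changes <= -100)) stop("a percentage change of -100 or below cannot compound")
  100 * (prod(1 + changes / 100) - 1)
}

#' Annual average (geometric) percentage change
#'
#' Annualises a period change multiplicatively:
#' `100 * ((end/start)^(1/n_years) - 1)`.  With `n_years = 1` this equals
#' [period_percent_change()].
#'
#' @param start_value Positive value at the start of the period.
#' @param end_value Positive value at the end of the period.
#' @param n_years Integer number of years spanned (>= 1).
#' @return Percentage change per year.
#' @export
annualized_percent_change <- function(start_value, end_value, n_years) {
  if (any(start_value <= 0) || any(end_value <= 0))
    stop("start_value and end_value must be positive")
  if (any(n_years < 1)) stop("n_years must be at least 1")
  100 * ((end_value / start_value)^(1 / n_years) - 1)
}

#' Mortality summary for dead-pup counts
#'
#' Joins dead-pup counts to live abundance estimates by colony-year and
#' reports the dead fraction of total pups.
#'
#' @param dead Data frame with columns `colony`, `year`, `dead_count`.
#' @param abundance Data frame from [estimate_abundance()].
#' @return Data frame with `colony`, `year`, `dead_count`, `live_estimate`,
#'   `dead_fraction_pct`.
#' @export
mortality_summary <- function(dead, abundance) {
  need <- c("colony", "year", "dead_count")
  missing_cols <- setdiff(need, names(dead))
  if (length(missing_cols))
    stop("dead-count table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- merge(dead, abundance[, c("colony", "year", "mean_estimate")],
             by = c("colony", "year"))
  out <- data.frame(colony = m$colony, year = m$year,
                    dead_count = m$dead_count,
                    live_estimate = m$mean_estimate,
                    dead_fraction_pct = dead_pup_fraction(m$dead_count,
                                                          m$mean_estimate),
                    stringsAsFactors = FALSE)
  out[order(out$colony, out$year), , drop = FALSE]
}
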