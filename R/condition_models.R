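# Linear models of pup mass and BCI1: candidate enumeration, AICc ranking,
# day-of-season standardisation, inter-survey change, mass-abundance
# correlation.

.term_vars <- c(Year = "factor(year)", Sex = "sex", Colony = "colony",
                Day = "day")

#' Specify a candidate linear model for pup mass or condition
#'
#' Terms are drawn from `Year` (categorical breeding season), `Sex`,
#' `Colony` and `Day` (numeric day-of-season covariate), plus pairwise
#' interactions among included main effects.
#'
#' @param response `"mass"` or `"bci1"`.
#' @param terms Character vector, subset of
#'   `c("Year", "Sex", "Colony", "Day")` (may be empty: intercept-only).
#' @param interactions Character vector of pairwise interactions written
#'   `"A:B"`, each between included main effects.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response = c("mass", "bci1"), terms = character(),
                       interactions = character()) {
  response <- match.arg(response)
  terms <- unique(terms)
  bad <- setdiff(terms, names(.term_vars))
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  for (ia in interactions) {
    pair <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (length(pair) != 2L || !all(pair %in% terms))
      stop("interaction ", ia, " is not a pair of included main effects")
  }
  structure(list(response = response, terms = terms,
                 interactions = unique(interactions)),
            class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  rhs <- c(x$terms, x$interactions)
  paste(x$response, "~", if (length(rhs)) paste(rhs, collapse = " + ") else "1")
}

#' @export
print.model_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

.spec_formula <- function(spec) {
  rhs <- vapply(spec$terms, function(t) .term_vars[[t]], character(1))
  for (ia in spec$interactions) {
    pair <- strsplit(ia, ":", fixed = TRUE)[[1]]
    rhs <- c(rhs, paste(.term_vars[pair[1]], .term_vars[pair[2]], sep = ":"))
  }
  stats::as.formula(paste(spec$response, "~",
                          if (length(rhs)) paste(rhs, collapse = " + ") else "1"))
}

#' Second-order Akaike Information Criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)` with the full Gaussian
#' log-likelihood (variance profiled out) and `k` counting every estimated
#' parameter including the error variance.
#'
#' @param object An `lm` fit or a [fit_condition_model()] result.
#' @return The AICc value.
#' @export
aicc <- function(object) UseMethod("aicc")

#' @export
aicc.lm <- function(object) {
  ll <- stats::logLik(object)
  k <- attr(ll, "df")
  n <- stats::nobs(object)
  if (n - k - 1 <= 0) stop("AICc undefined: n - k - 1 <= 0")
  -2 * as.numeric(ll) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @export
aicc.condition_model <- function(object) object$aicc

#' Fit one candidate model by ordinary least squares
#'
#' `Year` enters as a categorical factor (baseline: earliest year), `Colony`
#' as a factor (baseline: alphabetically first colony), `Day` as a numeric
#' covariate.  Records with unknown sex are excluded whenever the model
#' contains a `Sex` term.  Rank-deficient designs (aliased levels) are an
#' error naming the offending columns.
#'
#' @param spec A [model_spec()].
#' @param data Pup records (with `bci1` already added if it is the response).
#' @return An object of class `condition_model`: the `lm` fit plus `n`, `k`
#'   (parameters incl. error variance), `rss`, `adj_r2`, `aicc` and a
#'   coefficient table with standard errors and 95% CIs.
#' @export
fit_condition_model <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  if (any(c("Sex") %in% spec$terms))
    data <- data[data$sex != "unknown", , drop = FALSE]
  if ("Sex" %in% spec$terms) data$sex <- factor(data$sex)
  data$colony <- as.character(data$colony)
  fit <- stats::lm(.spec_formula(spec), data = data)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; aliased column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  n <- stats::nobs(fit)
  k <- length(stats::coef(fit)) + 1L  # + error variance
  if (n <= k) stop("too few records for this model: n <= k")
  ci <- stats::confint(fit, level = 0.95)
  sm <- summary(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      se = sm$coefficients[, 2],
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      p_value = sm$coefficients[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(spec = spec, lm = fit, n = n, k = k,
                 rss = sum(stats::residuals(fit)^2),
                 adj_r2 = sm$adj.r.squared,
                 # AICc needs n > k + 1; saturated fits carry NA
                 aicc = if (n - k - 1 > 0) aicc(fit) else NA_real_,
                 coefficients = coefs),
            class = "condition_model")
}

#' @export
print.condition_model <- function(x, ...) {
  cat(format(x$spec), sprintf(" [n = %d, k = %d, adj R2 = %.3f, AICc = %.2f]\n",
                              x$n, x$k, x$adj_r2, x$aicc))
  invisible(x)
}

# Parameter count a spec would need on this data, without fitting.
.spec_n_params <- function(spec, data) {
  df_of <- c(Year = length(unique(data$year)) - 1L, Sex = 1L,
             Colony = length(unique(data$colony)) - 1L, Day = 1L)
  p <- 1L + sum(df_of[spec$terms])
  for (ia in spec$interactions) {
    pair <- strsplit(ia, ":", fixed = TRUE)[[1]]
    p <- p + df_of[[pair[1]]] * df_of[[pair[2]]]
  }
  p + 1L  # error variance
}

#' Enumerate candidate model structures
#'
#' All main-effect subsets of `{Year, Sex, Colony, Day}`, optionally
#' extended by every subset of pairwise interactions among the included
#' main effects, dropping structures whose parameter count (including
#' intercept and error variance) would exceed `max_params` — large
#' parameterisations are excluded a priori to avoid overfitting.
#'
#' @param response `"mass"` or `"bci1"`.
#' @param data The records the candidates will be fitted to (used only to
#'   count factor levels for the parameter cap).
#' @param include_interactions Include pairwise-interaction structures?
#' @param max_params Parameter cap, default 60.
#' @return A list of [model_spec()] objects.
#' @export
candidate_specs <- function(response, data, include_interactions = TRUE,
                            max_params = 60) {
  mains <- names(.term_vars)
  out <- list()
  for (i in 0:(2^length(mains) - 1)) {
    sel <- mains[bitwAnd(i, 2^(seq_along(mains) - 1)) > 0]
    ia_sets <- list(character())
    if (include_interactions && length(sel) >= 2) {
      pairs <- utils::combn(sort(sel), 2,
                            FUN = function(p) paste(p, collapse = ":"))
      ia_sets <- c(ia_sets, unlist(lapply(seq_along(pairs), function(m)
        utils::combn(pairs, m, simplify = FALSE)), recursive = FALSE))
    }
    for (ias in ia_sets) {
      sp <- model_spec(response, sel, ias)
      if (.spec_n_params(sp, data) <= max_params) out <- c(out, list(sp))
    }
  }
  out
}

#' Select the AICc-preferred model structure
#'
#' Fits every candidate and returns the one with minimal AICc together with
#' the full ranking table.  Candidates that fail to fit are kept in the
#' ranking with the error message rather than aborting selection; exact
#' AICc ties go to the earlier candidate (logged via `message()`).
#'
#' @param candidates List of [model_spec()]s (length >= 2).
#' @param data Records to fit.
#' @return List with `best` (a `condition_model`) and `ranking` (data frame
#'   with spec, k, n, AICc, delta_AICc, and any fit error).
#' @export
select_model <- function(candidates, data) {
  if (length(candidates) < 2L) stop("need at least 2 candidate structures")
  fits <- lapply(candidates, function(sp)
    tryCatch(fit_condition_model(sp, data), error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("no candidate could be fitted")
  ranking <- data.frame(
    spec = vapply(candidates, format, character(1)),
    k = vapply(fits, function(f) if (inherits(f, "error")) NA_integer_ else f$k,
               integer(1)),
    n = vapply(fits, function(f) if (inherits(f, "error")) NA_integer_ else f$n,
               integer(1)),
    aicc = vapply(fits, function(f) if (inherits(f, "error")) NA_real_ else f$aicc,
                  numeric(1)),
    error = vapply(fits, function(f) if (inherits(f, "error")) conditionMessage(f)
                   else "", character(1)),
    stringsAsFactors = FALSE)
  best_i <- which(ranking$aicc == min(ranking$aicc, na.rm = TRUE))
  if (length(best_i) > 1L)
    message("AICc tie among candidates ", paste(best_i, collapse = ", "),
            "; keeping the first")
  best_i <- best_i[1]
  ranking$delta_aicc <- ranking$aicc - ranking$aicc[best_i]
  ranking <- ranking[order(ranking$aicc), , drop = FALSE]
  rownames(ranking) <- NULL
  list(best = fits[[best_i]], ranking = ranking)
}

#' Day-standardised per-colony year means
#'
#' Refits a per-colony `Year + Sex` model with the day-of-season slope
#' constrained to a value estimated on pooled pan-colony data (exact
#' constraint via a response offset: `response - day_effect * (day -
#' reference_day)` is modelled, which is equivalent to fixing the Day
#' coefficient).  Standardised year means are model predictions at the
#' reference day under a 50/50 sex mix; their standard errors come from the
#' coefficient covariance.
#'
#' @param data Records for one colony (column `colony` must be constant).
#' @param response `"mass"` or `"bci1"`.
#' @param fixed_day_effect Day slope (response units per day) from the
#'   pan-colony model.
#' @param reference_day Day-of-season at which to standardise; a reference
#'   day outside the observed range triggers an extrapolation warning.
#' @return Data frame of class `standardised_series`: `colony`, `year`,
#'   `std_mean`, `se`, with attributes `reference_day` and `response`.
#' @export
standardise_by_day <- function(data, response = c("mass", "bci1"),
                               fixed_day_effect, reference_day) {
  response <- match.arg(response)
  if (length(unique(data$colony)) != 1L)
    stop("standardise_by_day() expects records from a single colony")
  if (reference_day < min(data$day) || reference_day > max(data$day))
    warning("reference_day ", reference_day,
            " is outside the observed day range: standardised means extrapolate")
  use_sex <- length(setdiff(unique(data$sex), "unknown")) == 2L
  if (use_sex) data <- data[data$sex != "unknown", , drop = FALSE]
  y <- data[[response]] - fixed_day_effect * (data$day - reference_day)
  data$.offset_resp <- y
  data$.yearf <- factor(data$year)
  fml <- if (use_sex) .offset_resp ~ .yearf + sex else .offset_resp ~ .yearf
  if (use_sex) data$sex <- factor(data$sex, levels = c("female", "male"))
  fit <- stats::lm(fml, data = data)
  years <- sort(unique(data$year))
  X <- matrix(0, length(years), length(stats::coef(fit)),
              dimnames = list(NULL, names(stats::coef(fit))))
  X[, "(Intercept)"] <- 1
  for (i in seq_along(years)) {
    col <- paste0(".yearf", years[i])
    if (col %in% colnames(X)) X[i, col] <- 1
  }
  if (use_sex) X[, "sexmale"] <- 0.5  # balanced sex mix
  est <- drop(X %*% stats::coef(fit))
  se <- sqrt(rowSums((X %*% stats::vcov(fit)) * X))
  out <- data.frame(colony = data$colony[1], year = years,
                    std_mean = est, se = se, stringsAsFactors = FALSE)
  attr(out, "reference_day") <- reference_day
  attr(out, "response") <- response
  class(out) <- c("standardised_series", "data.frame")
  out
}

#' Inter-survey percentage change of a standardised series
#'
#' Consecutive-survey percent change of the standardised means, one entry
#' fewer than the number of surveyed years.
#'
#' @param series A [standardise_by_day()] result (or any data frame with
#'   `year` and `std_mean`).
#' @return Numeric vector named `"<year_t-1>-<year_t>"`.
#' @export
inter_survey_change <- function(series) {
  series <- series[order(series$year), , drop = FALSE]
  if (nrow(series) < 2L) stop("need at least 2 surveyed years")
  if (any(series$std_mean <= 0)) stop("non-positive standardised mean")
  n <- nrow(series)
  ch <- period_percent_change(series$std_mean[-n], series$std_mean[-1])
  names(ch) <- paste(series$year[-n], series$year[-1], sep = "-")
  ch
}

#' Correlation between standardised pup mass and inter-survey abundance change
#'
#' Pearson product-moment correlation pairing the standardised mass at
#' survey `t` with the change in live pup abundance from survey `t-1` to
#' `t` (the first survey of a colony has no pair).
#'
#' @param std_series [standardise_by_day()] result for one colony.
#' @param abundance Abundance estimates for the same colony (columns `year`,
#'   `mean_estimate`).
#' @return List with `r`, `p`, `n` (number of paired surveys).
#' @export
mass_abundance_correlation <- function(std_series, abundance) {
  ab <- abundance[order(abundance$year), , drop = FALSE]
  n_ab <- nrow(ab)
  if (n_ab < 2L) stop("need at least 2 abundance surveys")
  diffs <- data.frame(year = ab$year[-1],
                      abundance_change = diff(ab$mean_estimate))
  m <- merge(std_series[, c("year", "std_mean")], diffs, by = "year")
  if (nrow(m) < 3L) stop("fewer than 3 paired years after alignment")
  if (stats::sd(m$std_mean) == 0 || stats::sd(m$abundance_change) == 0)
    stop("zero variance in a paired series")
  ct <- stats::cor.test(m$std_mean, m$abundance_change, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
}
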