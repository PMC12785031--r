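# Smooth abundance-vs-year trends: penalized cubic B-spline smooths (second
# difference penalty), pointwise CIs, first-derivative confidence bands,
# turning points and significant periods.

#' Fit a penalized-spline trend of abundance against year
#'
#' A cubic B-spline smooth with a second-order difference penalty
#' (`mgcv::gam` with `bs = "ps"`, `m = c(2, 2)`), smoothing parameter chosen
#' by GCV (default) or REML.  The Gaussian/identity family suits estimate
#' series with roughly constant error; the gamma/log family keeps fitted
#' means strictly positive and suits series whose spread scales with the
#' mean.  Pointwise 95% CIs come from the Bayesian posterior covariance of
#' the coefficients, back-transformed to the response scale.
#'
#' @param years Ordered numeric survey years (>= 6 distinct).
#' @param estimates Mean abundance estimates, one per year (strictly
#'   positive when `family = "gamma_log"`).
#' @param family `"gaussian_identity"` or `"gamma_log"`.
#' @param basis_dim Basis dimension `k`, default 10.
#' @param method Smoothness selection: `"GCV.Cp"` (default) or `"REML"`.
#' @param weights Optional fit weights (e.g. inverse SE^2); unweighted by
#'   default — the mean estimates are fitted directly.
#' @param sp Optional fixed smoothing parameter; `NULL` (default) selects
#'   it by `method`.
#' @param grid_step Evaluation grid spacing in years, default 0.25.
#' @param ci_level Pointwise CI level, default 0.95.
#' @return An object of class `trend_fit`: the `gam` fit plus a `grid` data
#'   frame (`year`, `fit`, `se`, `ci_lower`, `ci_upper` on the response
#'   scale), `edf`, `sp`, `family`.
#' @export
fit_trend <- function(years, estimates, family = c("gaussian_identity", "gamma_log"),
                      basis_dim = 10, method = c("GCV.Cp", "REML"),
                      weights = NULL, sp = NULL, grid_step = 0.25,
                      ci_level = 0.95) {
  family <- match.arg(family)
  method <- match.arg(method)
  if (length(years) != length(estimates)) stop("years and estimates differ in length")
  if (length(unique(years)) < 6L) stop("need at least 6 distinct years")
  if (family == "gamma_log" && any(estimates <= 0))
    stop("gamma_log requires strictly positive estimates")
  if (basis_dim > length(unique(years)))
    basis_dim <- length(unique(years))  # mgcv cannot exceed unique covariate values
  fam <- switch(family,
                gaussian_identity = stats::gaussian(link = "identity"),
                gamma_log = stats::Gamma(link = "log"))
  d <- data.frame(year = as.numeric(years), est = as.numeric(estimates))
  g <- mgcv::gam(est ~ s(year, k = basis_dim, bs = "ps", m = c(2, 2)),
                 data = d, family = fam, method = method, weights = weights,
                 sp = sp)
  if (!g$converged) stop("trend smoother failed to converge")
  grid_years <- seq(min(d$year), max(d$year), by = grid_step)
  pr <- mgcv::predict.gam(g, newdata = data.frame(year = grid_years),
                          type = "link", se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  inv <- fam$linkinv
  grid <- data.frame(year = grid_years,
                     fit = inv(as.numeric(pr$fit)),
                     se = as.numeric(pr$se.fit),
                     ci_lower = inv(as.numeric(pr$fit) - z * as.numeric(pr$se.fit)),
                     ci_upper = inv(as.numeric(pr$fit) + z * as.numeric(pr$se.fit)))
  structure(list(gam = g, grid = grid, family = family,
                 basis_dim = basis_dim, method = method,
                 edf = sum(g$edf), sp = unname(g$sp),
                 deviance_explained = summary(g)$dev.expl,
                 years = d$year, estimates = d$est),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Penalized-spline trend (%s): %d surveys %.0f-%.0f, edf = %.2f, deviance explained = %.1f%%\n",
              x$family, length(x$years), min(x$years), max(x$years),
              x$edf, 100 * x$deviance_explained))
  invisible(x)
}

#' First derivative of a fitted trend with pointwise confidence band
#'
#' The derivative of the smooth on the linear-predictor scale, obtained by
#' central differencing of the spline basis at a step far below the grid
#' spacing (the basis is piecewise cubic, so this is exact to well below
#' any tolerance of interest); the pointwise CI is a delta-method interval
#' from the coefficient posterior covariance.  A grid point is flagged
#' significant when its CI excludes zero.
#'
#' @param fit A [fit_trend()] object.
#' @param grid_step Grid spacing in years, default 0.25.
#' @param ci_level CI level, default 0.95.
#' @param n_sim If > 0, also compute CI limits from this many posterior
#'   coefficient draws (columns `sim_lower`, `sim_upper`) as a cross-check.
#' @param seed Seed for the posterior draws (only used when `n_sim > 0`).
#' @return Data frame of class `derivative_series`: `year`, `derivative`,
#'   `se`, `ci_lower`, `ci_upper`, `significant`.
#' @export
derivative <- function(fit, grid_step = 0.25, ci_level = 0.95,
                       n_sim = 0, seed = NULL) {
  stopifnot(inherits(fit, "trend_fit"))
  g <- fit$gam
  grid_years <- seq(min(fit$years), max(fit$years), by = grid_step)
  eps <- 1e-5
  X1 <- mgcv::predict.gam(g, newdata = data.frame(year = grid_years + eps / 2),
                          type = "lpmatrix")
  X0 <- mgcv::predict.gam(g, newdata = data.frame(year = grid_years - eps / 2),
                          type = "lpmatrix")
  Xd <- (X1 - X0) / eps
  beta <- stats::coef(g)
  V <- g$Vp
  dfit <- drop(Xd %*% beta)
  dse <- sqrt(rowSums((Xd %*% V) * Xd))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- data.frame(year = grid_years, derivative = dfit, se = dse,
                    ci_lower = dfit - z * dse, ci_upper = dfit + z * dse)
  if (n_sim > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    }
    draws <- Xd %*% t(mgcv::rmvn(n_sim, beta, V))
    qs <- apply(draws, 1, stats::quantile,
                probs = c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2))
    out$sim_lower <- qs[1, ]
    out$sim_upper <- qs[2, ]
  }
  out$significant <- out$ci_lower > 0 | out$ci_upper < 0
  class(out) <- c("derivative_series", "data.frame")
  out
}

#' Locate turning points of a fitted trend
#'
#' A turning point is an adjacent pair of grid years between which the
#' first-derivative point estimate changes sign.  It is flagged significant
#' when the derivative CI excludes zero on at least one of the two flanking
#' grid points.
#'
#' @param derivs A [derivative()] series.
#' @return Data frame with `year_before`, `year_after`, `direction`
#'   (`"positive_to_negative"` or `"negative_to_positive"`), `significant`.
#'   Zero rows for monotone trends.
#' @export
find_turning_points <- function(derivs) {
  if (nrow(derivs) < 2L) stop("derivative grid needs at least 2 points")
  s <- sign(derivs$derivative)
  idx <- which(s[-length(s)] * s[-1] < 0)
  out <- data.frame(year_before = derivs$year[idx],
                    year_after = derivs$year[idx + 1],
                    direction = ifelse(s[idx] > 0, "positive_to_negative",
                                       "negative_to_positive"),
                    significant = derivs$significant[idx] |
                      derivs$significant[idx + 1],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Maximal periods of significant trend gradient
#'
#' Maximal runs of consecutive grid points whose derivative CI excludes
#' zero, labelled by the sign of the gradient.
#'
#' @param derivs A [derivative()] series.
#' @return Data frame with `start_year`, `end_year`, `sign`
#'   (`"positive"`/`"negative"`); zero rows when no gradient is significant.
#' @export
significant_periods <- function(derivs) {
  sig <- derivs$significant
  lab <- ifelse(!sig, "none", ifelse(derivs$derivative > 0, "positive", "negative"))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != "none"
  out <- data.frame(start_year = derivs$year[starts[keep]],
                    end_year = derivs$year[ends[keep]],
                    sign = r$values[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit, differentiate and summarise trends for several colonies
#'
#' Convenience wrapper running [fit_trend()], [derivative()],
#' [find_turning_points()] and [significant_periods()] per colony.
#'
#' @param abundance Abundance estimates (columns `colony`, `year`,
#'   `mean_estimate`).
#' @param family Named character vector mapping colony to family, or a
#'   single family applied to all colonies.
#' @param ... Passed to [fit_trend()].
#' @return Named list per colony with elements `fit`, `derivatives`,
#'   `turning_points`, `significant_periods`.
#' @export
trend_by_colony <- function(abundance, family = "gaussian_identity", ...) {
  colonies <- sort(unique(abundance$colony))
  out <- lapply(colonies, function(cl) {
    d <- abundance[abundance$colony == cl, , drop = FALSE]
    d <- d[order(d$year), , drop = FALSE]
    fam <- if (length(family) > 1 || !is.null(names(family)))
      unname(family[[cl]]) else family
    f <- fit_trend(d$year, d$mean_estimate, family = fam, ...)
    dv <- derivative(f)
    list(fit = f, derivatives = dv,
         turning_points = find_turning_points(dv),
         significant_periods = significant_periods(dv))
  })
  names(out) <- colonies
  out
}
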