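years <- 1991:2025

test_that("exact straight-line data are reproduced at any smoothing level", {
  est <- 100 + 5 * (years - 1991)
  for (sp in c(0.01, 1, 1000)) {
    f <- fit_trend(years, est, sp = sp)
    expect_lt(max(abs(f$grid$fit - (100 + 5 * (f$grid$year - 1991)))), 1e-6)
    dv <- derivative(f)
    expect_equal(dv$derivative, rep(5, nrow(dv)), tolerance = 1e-3 / 5)
    expect_equal(nrow(find_turning_points(dv)), 0)
  }
  # GCV is free to keep flexibility (all fits interpolate an exact line),
  # but the fitted curve must still be the line itself
  fg <- fit_trend(years, est)
  expect_lt(max(abs(fg$grid$fit - (100 + 5 * (fg$grid$year - 1991)))), 1e-6)
})

test_that("constant data give a flat fit with a zero-covering derivative", {
  set.seed(50)
  est <- rep(400, 35) + stats::rnorm(35, 0, 1e-6)
  f <- fit_trend(years, est)
  dv <- derivative(f)
  expect_lt(max(abs(dv$derivative)), 1e-3)
  expect_true(all(dv$ci_lower <= 0 & dv$ci_upper >= 0))
  expect_equal(nrow(significant_periods(dv)), 0)
})

test_that("a sinusoidal trajectory is recovered with its extrema located", {
  set.seed(51)
  t <- 0:34
  mu <- 500 + 200 * sin(2 * pi * t / 14)
  est <- mu + stats::rnorm(35, 0, 30)
  f <- fit_trend(1991 + t, est)
  # fit tracks the generating mean
  mu_grid <- 500 + 200 * sin(2 * pi * (f$grid$year - 1991) / 14)
  expect_lt(sqrt(mean((f$grid$fit - mu_grid)^2)), 40)
  dv <- derivative(f)
  tp <- find_turning_points(dv)
  # analytic extrema of the generating function at t = 3.5, 10.5, ..., 31.5
  expected_t <- 1991 + c(3.5, 10.5, 17.5, 24.5, 31.5)
  expect_equal(nrow(tp), 5)
  mid <- (tp$year_before + tp$year_after) / 2
  expect_true(all(abs(mid - expected_t) <= 1))
  expect_true(all(tp$direction == rep(c("positive_to_negative",
                                        "negative_to_positive"),
                                      length.out = 5)))
})

test_that("analytic and finite-difference derivatives agree everywhere", {
  set.seed(52)
  est <- 500 + 200 * sin(2 * pi * (0:34) / 14) + stats::rnorm(35, 0, 30)
  for (fam in c("gaussian_identity", "gamma_log")) {
    f <- fit_trend(years, est, family = fam)
    dv <- derivative(f)
    h <- 1e-4
    lp <- function(y) mgcv::predict.gam(f$gam, newdata = data.frame(year = y),
                                        type = "link")
    fd <- (lp(dv$year + h) - lp(dv$year - h)) / (2 * h)
    expect_lt(max(abs(dv$derivative - as.numeric(fd))), 1e-3)
  }
})

test_that("the gamma/log family keeps fitted means strictly positive", {
  set.seed(53)
  est <- pmax(5, 200 * exp(-0.1 * (0:34)) + stats::rnorm(35, 0, 10))
  f <- fit_trend(years, est, family = "gamma_log")
  expect_true(all(f$grid$fit > 0))
  expect_true(all(f$grid$ci_lower > 0))
  expect_error(fit_trend(years, est - 200, family = "gamma_log"), "positive")
})

test_that("turning points are in bijection with derivative sign changes", {
  set.seed(54)
  for (r in 1:10) {
    est <- 400 + 150 * sin(2 * pi * (0:34) / stats::runif(1, 8, 20)) +
      stats::rnorm(35, 0, 25)
    dv <- derivative(fit_trend(years, est))
    s <- sign(dv$derivative)
    expect_equal(nrow(find_turning_points(dv)),
                 sum(s[-length(s)] * s[-1] < 0))
  }
})

test_that("steep-then-flat declines yield one negative significant period", {
  set.seed(55)
  mu <- c(1000 - 50 * (0:17), rep(1000 - 50 * 17, 17))
  est <- mu + stats::rnorm(35, 0, 5)
  # a finer basis resolves the corner between the two regimes
  dv <- derivative(fit_trend(years, est, basis_dim = 15))
  sp <- significant_periods(dv)
  neg <- sp[sp$sign == "negative", ]
  expect_equal(nrow(neg), 1)
  expect_lt(abs(neg$start_year - 1991), 1.5)
  # the spline rounds the kink, so the significant gradient persists a
  # little beyond the true corner
  expect_lt(abs(neg$end_year - (1991 + 17)), 2)
  # strictly monotone steep series: a single period spanning nearly all years
  est2 <- 2000 - 40 * (0:34) + stats::rnorm(35, 0, 5)
  sp2 <- significant_periods(derivative(fit_trend(years, est2)))
  expect_equal(nrow(sp2), 1)
  expect_gt(sp2$end_year - sp2$start_year, 30)
})

test_that("pointwise intervals cover a known smooth trajectory", {
  t <- 0:34
  mu <- 500 + 200 * sin(2 * pi * t / 14)
  covered <- 0L; total <- 0L
  # REML smoothness selection: the Bayesian-interval calibration results
  # hold for it, where GCV undersmoothing slightly erodes coverage
  for (r in 1:200) {
    set.seed(6000 + r)
    f <- fit_trend(1991 + t, mu + stats::rnorm(35, 0, 30), method = "REML",
                   grid_step = 1)
    g <- f$grid[f$grid$year >= 1993 & f$grid$year <= 2023, ]
    mu_g <- 500 + 200 * sin(2 * pi * (g$year - 1991) / 14)
    covered <- covered + sum(g$ci_lower <= mu_g & mu_g <= g$ci_upper)
    total <- total + nrow(g)
  }
  expect_gte(covered / total, 0.90)
  expect_lte(covered / total, 0.99)
})

test_that("posterior-simulation intervals corroborate the delta-method band", {
  set.seed(57)
  est <- 500 + 200 * sin(2 * pi * (0:34) / 14) + stats::rnorm(35, 0, 30)
  f <- fit_trend(years, est)
  dv <- derivative(f, n_sim = 10000, seed = 99)
  expect_equal(dv$sim_lower, dv$ci_lower, tolerance = 0.05)
  expect_equal(dv$sim_upper, dv$ci_upper, tolerance = 0.05)
})

test_that("degenerate inputs are rejected with clear messages", {
  expect_error(fit_trend(2001:2005, 1:5), "6 distinct")
  expect_error(fit_trend(2001:2010, 1:9), "length")
})
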