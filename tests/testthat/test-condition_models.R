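test_that("OLS fits recover hand-computable and zero-noise systems", {
  # intercept-only on {5, 6, 7}
  d <- data.frame(colony = "a", year = 1L, day = 30L, sex = "female",
                  mass = c(5, 6, 7), length = 75, bci1 = c(5, 6, 7) / 75)
  f <- fit_condition_model(model_spec("mass"), d)
  expect_equal(unname(f$coefficients$estimate), 6)
  expect_equal(f$rss, 2)
  # zero-noise additive system is recovered exactly (lm's perfect-fit
  # advisory is expected here)
  d2 <- make_condition_data(noise_sd = 0)
  f2 <- suppressWarnings(
    fit_condition_model(model_spec("mass", c("Year", "Sex", "Colony", "Day")), d2))
  cf <- f2$coefficients
  expect_equal(cf$estimate[cf$term == "sexmale"], 0.69, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "day"], 0.04, tolerance = 1e-8)
  expect_equal(cf$estimate[cf$term == "colonyB"], -0.5, tolerance = 1e-8)
  expect_equal(f2$adj_r2, 1, tolerance = 1e-8)
})

test_that("paper-scale effects are recovered within their confidence intervals", {
  cfg <- default_sim_config(103)
  cfg$colonies <- lapply(cfg$colonies, function(cc) { cc$pups_measured <- 48L; cc })
  world <- simulate_colony_dataset(cfg)  # ~5000 records
  cond <- add_condition(world$biometrics)
  fit <- fit_condition_model(model_spec("mass", c("Year", "Sex", "Colony", "Day")),
                             cond)
  cf <- fit$coefficients
  inside <- function(term, truth) {
    row <- cf[cf$term == term, ]
    row$ci_lower <= truth && truth <= row$ci_upper
  }
  expect_true(inside("sexmale", 0.69))
  expect_true(inside("day", 0.04))
  expect_true(inside("colonyTaumaka", -0.75))
  expect_true(inside("colonyWekakura", -0.14))
})

test_that("AICc follows the small-sample-corrected Gaussian form", {
  set.seed(31)
  d <- data.frame(y = stats::rnorm(10), x = stats::rnorm(10))
  f <- stats::lm(y ~ x, data = d)            # k = 3 incl. error variance
  ll <- stats::logLik(f)
  # correction term 2k(k+1)/(n-k-1) = 2*3*4/6 = 4 at n = 10, k = 3
  expect_equal(aicc(f), -2 * as.numeric(ll) + 2 * 3 + 4)
  # identical RSS and k give identical AICc
  d$x2 <- -d$x
  expect_equal(aicc(stats::lm(y ~ x, d)), aicc(stats::lm(y ~ x2, d)))
  # parsimony on pure noise: intercept-only beats 18 junk predictors
  set.seed(32)
  nz <- as.data.frame(matrix(stats::rnorm(100 * 19), 100))
  names(nz) <- c("y", paste0("j", 1:18))
  f0 <- stats::lm(y ~ 1, nz)
  f1 <- stats::lm(y ~ ., nz)
  expect_lt(aicc(f0), aicc(f1))
  expect_error(aicc(stats::lm(y ~ ., nz[1:20, ])), "n - k - 1")
})

test_that("AICc differences are invariant to shifting the response", {
  d <- make_condition_data(noise_sd = 0.8, seed = 5)
  s1 <- model_spec("mass", c("Sex"))
  s2 <- model_spec("mass", c("Sex", "Day"))
  d1 <- fit_condition_model(s1, d)$aicc - fit_condition_model(s2, d)$aicc
  d$mass <- d$mass + 100
  d2 <- fit_condition_model(s1, d)$aicc - fit_condition_model(s2, d)$aicc
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("AICc selection finds the generating structure and logs ties", {
  d <- make_condition_data(n_per_cell = 25, noise_sd = 1,
                           year_effects = stats::setNames(
                             c(-0.4, 0.3, 0, 0.5, -0.2), 2000:2004),
                           seed = 12)
  cands <- list(model_spec("mass", "Sex"),
                model_spec("mass", c("Sex", "Day")),
                model_spec("mass", c("Year", "Sex", "Colony", "Day")))
  sel <- select_model(cands, d)
  expect_equal(sort(sel$best$spec$terms), c("Colony", "Day", "Sex", "Year"))
  expect_equal(nrow(sel$ranking), 3)
  expect_equal(sel$ranking$delta_aicc[1], 0)
  # two literally identical specs: first wins, tie logged
  expect_message(sel2 <- select_model(list(model_spec("mass", "Sex"),
                                           model_spec("mass", "Sex")), d),
                 "tie")
  expect_equal(format(sel2$best$spec), "mass ~ Sex")
})

test_that("a lone Sex signal is detected over intercept-only in almost all replicates", {
  hits <- 0L
  for (r in 1:100) {
    set.seed(4000 + r)
    n <- 5000
    d <- data.frame(colony = "a", year = 1L, day = 30L,
                    sex = sample(c("female", "male"), n, replace = TRUE),
                    length = 75)
    d$mass <- 6 + 0.69 * (d$sex == "male") + stats::rnorm(n)
    sel <- select_model(list(model_spec("mass"), model_spec("mass", "Sex")), d)
    if ("Sex" %in% sel$best$spec$terms) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("candidate enumeration respects the parameter cap", {
  d <- make_condition_data(years = 2000:2034)  # 35 year levels
  cands <- candidate_specs("mass", d, include_interactions = TRUE,
                           max_params = 60)
  ks <- vapply(cands, pupwatch:::.spec_n_params, numeric(1), data = d)
  expect_true(all(ks <= 60))
  # with a 35-level Year factor any Year interaction adds 34+ parameters,
  # blowing the cap on top of the 40-parameter full main-effect model
  specs <- vapply(cands, format, character(1))
  expect_false(any(grepl(":Year", specs, fixed = TRUE)))
  mains_only <- candidate_specs("mass", d, include_interactions = FALSE)
  expect_length(mains_only, 16)
})

test_that("day standardisation reduces to raw means and removes known offsets", {
  # balanced sexes, everyone measured at the reference day
  d <- make_condition_data(n_per_cell = 6, colonies = "A", noise_sd = 0.3,
                           seed = 8)
  d$day <- 30L
  ser <- standardise_by_day(d, "mass", fixed_day_effect = 0.04,
                            reference_day = 30)
  raw <- tapply(d$mass, d$year, mean)
  expect_equal(ser$std_mean, as.numeric(raw), tolerance = 1e-8)
  # zero day effect degenerates to per-year adjusted means
  d2 <- make_condition_data(n_per_cell = 6, colonies = "A", noise_sd = 0,
                            seed = 9)
  ser2 <- standardise_by_day(d2, "mass", fixed_day_effect = 0,
                             reference_day = 30)
  expect_equal(ser2$std_mean, as.numeric(tapply(d2$mass, d2$year, mean)),
               tolerance = 1e-8)
})

test_that("a late-measured year is pulled back by the fixed day effect", {
  set.seed(14)
  years <- 2000:2004
  n <- 200
  rows <- do.call(rbind, lapply(years, function(yr) {
    day <- sample(20:40, n, replace = TRUE) + if (yr == 2002) 10L else 0L
    sex <- sample(c("female", "male"), n, replace = TRUE)
    data.frame(colony = "A", year = yr, day = day, sex = sex,
               mass = 6 + 0.04 * (day - 30) + 0.69 * (sex == "male") +
                 stats::rnorm(n, 0, 0.5),
               length = 75)
  }))
  ser <- standardise_by_day(rows, "mass", fixed_day_effect = 0.04,
                            reference_day = 30)
  raw_2002 <- mean(rows$mass[rows$year == 2002])
  std_2002 <- ser$std_mean[ser$year == 2002]
  expect_equal(raw_2002 - std_2002, 0.40, tolerance = 0.05 / 0.4)
  # idempotence: standardising a series already at the reference day is a no-op
  rows30 <- rows; rows30$day <- 30L
  s1 <- standardise_by_day(rows30, "mass", 0.04, 30)
  expect_equal(standardise_by_day(rows30, "mass", 0.04, 30)$std_mean,
               s1$std_mean)
  expect_warning(standardise_by_day(rows, "mass", 0.04, reference_day = 5),
                 "extrapolate")
})

test_that("inter-survey change is the consecutive percent change of the series", {
  ser <- data.frame(year = 2001:2003, std_mean = c(7, 7, 7))
  expect_equal(unname(inter_survey_change(ser)), c(0, 0))
  expect_equal(unname(inter_survey_change(
    data.frame(year = 1:2, std_mean = c(8, 6.4)))), -20)
  expect_equal(unname(inter_survey_change(
    data.frame(year = 1:3, std_mean = c(6, 7.2, 6.48)))), c(20, -10))
  expect_error(inter_survey_change(data.frame(year = 1, std_mean = 7)),
               "at least 2")
})

test_that("mass-abundance correlation pairs survey t with the change into t", {
  # abundance whose consecutive diffs are the target series y
  y <- c(2, 1, 4, 3); x <- c(1, 2, 3, 4)
  ab <- data.frame(colony = "A", year = 2000:2004,
                   mean_estimate = 500 + cumsum(c(0, y)))
  ser <- data.frame(year = 2001:2004, std_mean = x)
  res <- mass_abundance_correlation(ser, ab)
  expect_equal(res$r, 0.6, tolerance = 1e-9)
  expect_equal(res$n, 4)
  # perfectly (anti)proportional series
  ab2 <- data.frame(year = 2000:2003, mean_estimate = 500 + cumsum(c(0, 1, 2, 3)))
  expect_equal(mass_abundance_correlation(
    data.frame(year = 2001:2003, std_mean = c(10, 20, 30)), ab2)$r, 1)
  expect_equal(mass_abundance_correlation(
    data.frame(year = 2001:2003, std_mean = c(3, 2, 1)), ab2)$r, -1)
})

test_that("correlation is label-consistent and collapses under misalignment", {
  set.seed(77)
  years <- 2001:2020
  x <- stats::rnorm(20)
  ab <- data.frame(year = 2000:2020,
                   mean_estimate = 500 + cumsum(c(0, x + stats::rnorm(20, 0, 0.5))))
  ser <- data.frame(year = years, std_mean = 7 + x)
  r0 <- mass_abundance_correlation(ser, ab)$r
  # shuffling rows (labels follow values) leaves the paired r unchanged
  perm <- sample(20)
  expect_equal(mass_abundance_correlation(ser[perm, ], ab)$r, r0)
  # breaking the pairing in one series drives r toward zero on average
  rs <- replicate(500, {
    broken <- ser; broken$std_mean <- sample(broken$std_mean)
    mass_abundance_correlation(broken, ab)$r
  })
  expect_lt(mean(abs(rs)), 0.2)
})
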