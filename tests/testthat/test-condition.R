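test_that("BCI1 is mass over length and strictly monotone", {
  expect_equal(bci1(8.0, 80.0), 0.10)
  expect_equal(bci1(6.0, 60.0), 0.10)
  expect_equal(bci1(6.68, 74.2), 0.09003, tolerance = 1e-5 / 0.09)
  expect_error(bci1(5, 0), "positive")
  m <- seq(3, 12, by = 0.5)
  expect_true(all(diff(bci1(m, 80)) > 0))
  l <- seq(50, 100, by = 5)
  expect_true(all(diff(bci1(6, l)) < 0))
})

test_that("log-log allometry recovers exact and noisy power laws", {
  # noiseless power law: log-log data are exactly linear
  rec <- data.frame(length = c(50, 60, 70, 80, 90))
  rec$mass <- exp(-7) * rec$length^2.5
  f <- fit_allometry(rec)
  expect_equal(f$a, -7, tolerance = 1e-9)
  expect_equal(f$b, 2.5, tolerance = 1e-9)
  # two records, two lengths: saturated fit passes through both points
  rec2 <- data.frame(length = c(60, 80), mass = c(5, 9),
                     colony = "x", year = 1, day = 1, sex = "female")
  rec2 <- rbind(rec2, rec2[1, ])
  f2 <- fit_allometry(rec2)
  expect_equal(expected_mass(c(60, 80), f2), c(5, 9), tolerance = 1e-10)
  # parameter recovery under log-scale noise, against the closed-form OLS oracle
  set.seed(9)
  n <- 500
  len <- stats::runif(n, 55, 95)
  mass <- exp(-6.5 + 2.2 * log(len) + stats::rnorm(n, 0, 0.1))
  rec3 <- data.frame(length = len, mass = mass)
  f3 <- fit_allometry(rec3)
  x <- log(len); y <- log(mass)
  b_ols <- stats::cov(x, y) / stats::var(x)
  expect_equal(f3$b, b_ols, tolerance = 1e-10)
  expect_equal(f3$a, mean(y) - b_ols * mean(x), tolerance = 1e-10)
  expect_equal(f3$b, 2.2, tolerance = 0.05 / 2.2)
  # degenerate designs are rejected
  expect_error(fit_allometry(rec[1:2, ]), "at least 3")
  expect_error(fit_allometry(data.frame(length = c(70, 70, 70),
                                        mass = c(5, 6, 7))), "singular")
})

test_that("BCI2 is observed over expected mass with the right identities", {
  rec <- data.frame(colony = "A", year = 2000, day = 30, sex = "female",
                    length = c(50, 60, 70, 80, 90))
  rec$mass <- exp(-7) * rec$length^2.5
  f <- fit_allometry(rec)
  cond <- add_condition(rec, f)
  # records on the fitted line have zero residual
  expect_equal(cond$bci2, rep(1, 5), tolerance = 1e-12)
  expect_equal(cond$bci1, rec$mass / rec$length)
  # plain ratio arithmetic
  f_ref <- f; f_ref$a <- f$a + log(10 / 9)  # inflate expectations by 10/9
  cond2 <- add_condition(rec, f_ref)
  expect_equal(cond2$bci2, rep(0.9, 5), tolerance = 1e-12)
  # bci2 > 1 iff positive log residual
  set.seed(3)
  rec$mass <- rec$mass * exp(stats::rnorm(5, 0, 0.2))
  cond3 <- add_condition(rec, fit_allometry(rec))
  expect_equal(cond3$bci2 > 1,
               stats::residuals(fit_allometry(rec)$lm) > 0,
               ignore_attr = TRUE)
})

test_that("geometric mean of BCI2 over the fitting set is one", {
  set.seed(21)
  n <- 400
  rec <- data.frame(colony = "A", year = 2000, day = 30, sex = "female",
                    length = stats::runif(n, 55, 95))
  rec$mass <- exp(-6.8 + 2.3 * log(rec$length) + stats::rnorm(n, 0, 0.15))
  cond <- add_condition(rec)
  expect_equal(exp(mean(log(cond$bci2))), 1, tolerance = 1e-8)
})

test_that("BCI2 ordering is invariant to the units of mass", {
  set.seed(22)
  rec <- data.frame(length = stats::runif(50, 55, 95))
  rec$mass <- exp(-6.8 + 2.3 * log(rec$length) + stats::rnorm(50, 0, 0.1))
  c1 <- add_condition(rec)
  rec_g <- rec; rec_g$mass <- rec$mass * 1000  # kg -> g
  c2 <- add_condition(rec_g)
  expect_equal(c1$bci2, c2$bci2, tolerance = 1e-10)
})

test_that("colony-year classification uses the strict mean-BCI2 rule", {
  cond <- data.frame(colony = c("a", "a", "b", "b"), year = 2001,
                     bci2 = c(1.1, 1.2, 0.8, 1.0))
  cls <- classify_condition(cond)
  expect_equal(cls$mean_bci2, c(1.15, 0.9))
  expect_equal(cls$status, c("better", "worse"))
  # a mean of exactly 1 is not better-than-expected
  tie <- classify_condition(data.frame(colony = "t", year = 1, bci2 = 1))
  expect_equal(tie$status, "worse")
})

test_that("a colony with deflated allometric intercept is worse in every year", {
  cfg <- default_sim_config(5)
  cfg$colonies <- lapply(cfg$colonies, function(cc) {
    cc$colony_offset_kg <- 0; cc$pups_measured <- 40L; cc
  })
  cfg$n_years <- 8L
  world <- simulate_colony_dataset(cfg)
  bio <- world$biometrics
  # deflate one colony's masses by 10% (equivalently its allometric intercept)
  bio$mass[bio$colony == "Taumaka"] <- 0.9 * bio$mass[bio$colony == "Taumaka"]
  cls <- classify_condition(add_condition(bio))
  expect_true(all(cls$status[cls$colony == "Taumaka"] == "worse"))
  # direct group-mean oracle agrees with the classification table
  ref <- tapply(add_condition(bio)$bci2,
                paste(bio$colony, bio$year), mean)
  expect_equal(as.vector(ref[paste(cls$colony, cls$year)] > 1),
               cls$status == "better")
})

test_that("implausible biometric records are rejected loudly, not silently", {
  rec <- data.frame(colony = "A", year = 2000, day = 30,
                    sex = c("female", "male", "female", "male"),
                    mass = c(6, 0.5, 25, 7), length = c(75, 70, 80, 30))
  expect_warning(out <- validate_pup_records(rec), "rejected")
  expect_equal(nrow(out), 1)
  expect_error(validate_pup_records(transform(rec, sex = "f")), "invalid sex")
})
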