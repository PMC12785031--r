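# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; no data files.

# A session whose per-replicate Petersen estimates equal `values` exactly:
# with M = 0 and Ri = 0, Pi = (0+1)(Ci+1)/(0+1) - 1 = Ci.
session_with_estimates <- function(values, colony = "fix", year = 2000L) {
  recapture_session(colony, year, marked = 0L,
                    total_counts = as.integer(values),
                    marked_counts = rep(0L, length(values)))
}

# Deterministic biometric records with additive sex/day/colony effects and
# optional Gaussian noise; length held constant so effects are exact.
make_condition_data <- function(n_per_cell = 5, years = 2000:2004,
                                colonies = c("A", "B"),
                                sex_effect = 0.69, day_effect = 0.04,
                                colony_offsets = c(A = 0, B = -0.5),
                                year_effects = NULL, noise_sd = 0,
                                seed = 1) {
  if (is.null(year_effects))
    year_effects <- stats::setNames(rep(0, length(years)), years)
  set.seed(seed)
  g <- expand.grid(rep = seq_len(n_per_cell), sex = c("female", "male"),
                   day = c(25L, 35L), colony = colonies, year = years,
                   stringsAsFactors = FALSE)
  g$length <- 75
  g$mass <- 6 + sex_effect * (g$sex == "male") + day_effect * (g$day - 30) +
    colony_offsets[g$colony] + year_effects[as.character(g$year)] +
    stats::rnorm(nrow(g), 0, noise_sd)
  g$bci1 <- g$mass / g$length
  g[, c("colony", "year", "day", "sex", "mass", "length", "bci1")]
}

# Small, fast simulation world for pipeline tests.
small_sim_config <- function(seed = 11L) {
  sim_config(
    seed = seed, start_year = 2001L, n_years = 12L,
    colonies = list(
      colony_config("North", baseline = 400, decline_rate = 0.03,
                    sin_amplitude = 0.1, sin_period = 8,
                    mortality_rate = 0.05, colony_offset_kg = -0.3,
                    pups_measured = 30L),
      colony_config("South", baseline = 600, decline_rate = 0.01,
                    sin_amplitude = 0.1, sin_period = 8,
                    mortality_rate = 0.1, colony_offset_kg = 0,
                    pups_measured = 30L)))
}
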