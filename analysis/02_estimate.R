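#!/usr/bin/env Rscript
# Stage 2 — mark-recapture abundance estimates and mortality summary.
#
# Each colony-year's five replicate counts feed the bias-corrected Petersen
# estimator; the session mean, replicate-spread SE and 95% CI go to
# abundance_estimates.csv.  Dead counts become percentages of total pups.

suppressPackageStartupMessages(library(pupwatch))

sessions <- read_recapture_sessions("results/data/recapture_sessions.csv")
dead <- read_dead_counts("results/data/dead_counts.csv")

ab <- estimate_abundance(sessions)
mort <- mortality_summary(dead, ab)
write_table(ab, "results/abundance_estimates.csv")
write_table(mort, "results/mortality.csv")

cat("Abundance estimated for", nrow(ab), "colony-years\n")
for (cl in unique(ab$colony)) {
  d <- ab[ab$colony == cl, ]
  last <- nrow(d)
  peak <- which.max(d$mean_estimate)
  cat(sprintf("  %-13s %d: %0.f (%.0f-%.0f);  peak %d: %.0f;  peak->%d: %+.1f%% (%.1f%%/yr)\n",
              cl, d$year[last], d$mean_estimate[last], d$ci_lower[last],
              d$ci_upper[last], d$year[peak], d$mean_estimate[peak],
              d$year[last],
              period_percent_change(d$mean_estimate[peak], d$mean_estimate[last]),
              annualized_percent_change(d$mean_estimate[peak],
                                        d$mean_estimate[last],
                                        d$year[last] - d$year[peak])))
  m <- mort[mort$colony == cl, ]
  cat(sprintf("                mean dead fraction of total pups: %.1f%%\n",
              mean(m$dead_fraction_pct)))
}
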