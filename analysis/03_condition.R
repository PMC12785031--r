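#!/usr/bin/env Rscript
# Stage 3 — body condition indices.
#
# BCI1 = mass/length.  BCI2 = observed mass / expected mass, with expected
# mass from one log-log mass-length regression pooled over every pup at
# every colony in every year; colony-years are classified better- or
# worse-than-expected by their mean BCI2.

suppressPackageStartupMessages(library(pupwatch))

bio <- read_biometrics("results/data/biometrics.csv")
allo <- fit_allometry(bio)
cond <- add_condition(bio, allo)
cls <- classify_condition(cond)

write_table(data.frame(a = allo$a, b = allo$b, n = allo$n,
                       residual_sd = allo$residual_sd),
            "results/allometry.csv")
write_table(cond, "results/condition.csv")
write_table(cls, "results/classification.csv")

print(allo)
cat(sprintf("Geometric mean BCI2 over the fitting set: %.6f\n",
            exp(mean(log(cond$bci2)))))
for (cl in unique(cls$colony)) {
  d <- cls[cls$colony == cl, ]
  cat(sprintf("  %-13s mean mass %.2f kg, mean BCI1 %.3f kg/cm; better-than-expected in %d of %d years\n",
              cl, mean(cond$mass[cond$colony == cl]),
              mean(cond$bci1[cond$colony == cl]),
              sum(d$status == "better"), nrow(d)))
}
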