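#!/usr/bin/env Rscript
# Stage 5 — abundance trends, turning points and significant periods.
#
# Penalized cubic B-spline smooths of estimate against year (second-order
# difference penalty, basis dimension 10, GCV), first-derivative 95%
# confidence bands on the linear-predictor scale, turning points where the
# derivative changes sign, and maximal runs of significant gradient.

suppressPackageStartupMessages(library(pupwatch))

ab <- utils::read.csv("results/abundance_estimates.csv", stringsAsFactors = FALSE)
res <- trend_by_colony(ab)

grids <- list(); tps <- list(); sps <- list(); sums <- list()
for (cl in names(res)) {
  r <- res[[cl]]
  print(r$fit)
  g <- cbind(colony = cl, r$fit$grid,
             r$derivatives[, c("derivative", "se", "ci_lower", "ci_upper",
                               "significant")])
  names(g) <- c("colony", "year", "fit", "se", "ci_lower", "ci_upper",
                "derivative", "d_se", "d_ci_lower", "d_ci_upper", "significant")
  grids[[cl]] <- g
  tp <- r$turning_points
  if (nrow(tp)) {
    tps[[cl]] <- cbind(colony = cl, tp)
    cat(sprintf("  turning point %g/%g (%s)%s\n", tp$year_before,
                tp$year_after, tp$direction,
                ifelse(tp$significant, " [significant]", "")), sep = "")
  } else cat("  no turning points\n")
  sp <- r$significant_periods
  if (nrow(sp)) {
    sps[[cl]] <- cbind(colony = cl, sp)
    cat(sprintf("  significant %s gradient %g-%g\n", sp$sign, sp$start_year,
                sp$end_year), sep = "")
  }
  sums[[cl]] <- data.frame(colony = cl, family = r$fit$family, edf = r$fit$edf,
                           deviance_explained = r$fit$deviance_explained,
                           n_surveys = length(r$fit$years))
}

write_table(do.call(rbind, unname(grids)), "results/trend.csv")
write_table(do.call(rbind, unname(tps)), "results/turning_points.csv")
write_table(do.call(rbind, unname(sps)), "results/significant_periods.csv")
write_table(do.call(rbind, unname(sums)), "results/trend_summaries.csv")
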