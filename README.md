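# pupwatch

Longitudinal monitoring analysis for otariid (fur seal) breeding colonies:
live pup abundance from replicated mark-recapture surveys, pup body
condition from mass-length biometrics, AICc-selected condition models with
day-of-season standardisation, and penalized-spline abundance trends with
turning-point inference — plus a fully seeded synthetic colony-data
generator with known ground truth for validating every stage.

Pup production is the standard abundance proxy for eared seals (pups are
confined to land until weaning), and pup condition tracks maternal foraging
success, so together they are sensitive indicators of change in the local
marine environment. The package is aimed at wildlife-monitoring analysts
who have replicate recapture counts, dead-pup tallies and pup biometric
tables per colony-year and want a tested, reproducible path from those
tables to abundance estimates, condition classifications, standardised
condition series and smooth trend inference.

## Methods at the core

* **Abundance.** Each recapture replicate feeds the bias-corrected
  (Chapman-modified) Petersen estimator
  `Pi = (M+1)(Ci+1)/(Ri+1) - 1`; the session estimate is the mean of the
  `Q` replicates with `SE = sqrt( sum(Pi - P)^2 / (Q(Q-1)) )` and a
  Student-t 95% interval (z optional). Percentage changes compound
  multiplicatively and annualise geometrically.
* **Condition.** `BCI1 = mass/length`; `BCI2 = ObsM/ExpM` with
  `log(ExpM) = a + b log(Length)` fitted by OLS over all pups at all
  colonies in all years; colony-years with mean BCI2 > 1 are
  better-than-expected.
* **Condition models.** Linear models of mass and BCI1 over Year, Sex,
  Colony, Day (+ pairwise interactions, 60-parameter cap) ranked by
  `AICc = -2l + 2k + 2k(k+1)/(n-k-1)`; per-colony series standardised to a
  reference day by fixing the pan-colony day slope via an exact response
  offset; Pearson correlation of standardised mass with inter-survey
  abundance change.
* **Trends.** Penalized cubic B-spline smooths of estimate vs year
  (second-difference penalty, GCV or REML; Gaussian/identity or gamma/log
  family), first-derivative 95% bands from the coefficient posterior,
  turning points at derivative sign changes, and maximal significant
  gradient periods.

See `vignettes/colony-monitoring.Rmd` for assumptions, parameter defaults
and numerical choices.

## Worked example

A 2025 survey marks 357 pups and performs five recapture counts:

```r
library(pupwatch)
sessions <- data.frame(
  colony = "Taumaka", year = 2025, marked = 357,
  replicate_id = 1:5,
  total_count  = c(289, 311, 302, 276, 295),
  marked_count = c(182, 190, 189, 172, 181))
estimate_abundance(sessions)
#>    colony year mean_estimate       se ci_lower ci_upper n_replicates
#> 1 Taumaka 2025      574.6979 3.352477   565.39 584.0059            5
```

About 575 live pups (95% CI 565-584): each replicate saw ~62% of the
colony, and the tight CI reflects how consistent the five marked-fraction
counts were. Follow-on arithmetic uses the same units the field reports
use — e.g. 37 dead pups against 248 live is
`dead_pup_fraction(37, 248)` = 13.0% of total pups; two period declines of
-36% and -38.3% compound to `compound_percent_changes(c(-36, -38.3))` =
-60.5% (a "61% total decline"); and a fall from 916 to 566 pups over seven
years is `annualized_percent_change(916, 566, 7)` = -6.6% per year.

The full workflow lives in `analysis/01_simulate.R` …
`analysis/06_report.R`: generate the default three-colony synthetic world,
estimate abundance, compute condition indices, select and standardise
condition models, fit trends, and render a summary report. Each script
prints what it found and writes its tables under `results/`;
`run_pipeline()` performs the same stages in one orchestrated, manifested
run.

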