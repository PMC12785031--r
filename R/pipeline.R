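# Pipeline orchestration: simulate -> estimate -> condition -> models ->
# trend, with a JSON run manifest and a human-readable summary report.
# Every stage writes its tables before the next starts; a failed stage
# halts downstream stages but preserves completed outputs.

#' Run the colony-monitoring pipeline
#'
#' Executes the enabled stages in order.  Inputs come either from a
#' simulation configuration (stage `"simulate"` writes the synthetic
#' tables) or from CSV paths supplied in `inputs`.  Each stage writes its
#' tables under `out_dir`; a manifest (`manifest.json`) records inputs,
#' outputs, the seed, package version and per-stage status.  Identical
#' configurations produce byte-identical numeric outputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_config()], required when `"simulate"` is enabled.
#' @param inputs Named list of CSV paths (`sessions`, `dead_counts`,
#'   `biometrics`) used when the simulate stage is disabled.
#' @param stages Character vector of stages to run, in pipeline order.
#' @param ci_level Confidence level for abundance CIs.
#' @param family Trend family: single string or named vector per colony.
#' @param reference_day Day-of-season for standardised estimates; default
#'   is the data-wide median measurement day.
#' @param basis_dim Trend basis dimension.
#' @param include_interactions Include pairwise interactions in the
#'   condition-model candidate set.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(out_dir, sim = NULL, inputs = list(),
                         stages = c("simulate", "estimate", "condition",
                                    "models", "trend"),
                         ci_level = 0.95, family = "gaussian_identity",
                         reference_day = NULL, basis_dim = 10,
                         include_interactions = TRUE) {
  stage_order <- c("simulate", "estimate", "condition", "models", "trend")
  stages <- stage_order[stage_order %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "pupwatch",
    version = as.character(utils::packageVersion("pupwatch")),
    seed = if (!is.null(sim)) sim$seed else NA,
    stages = list(), outputs = character())
  path <- function(f) file.path(out_dir, f)
  add_output <- function(df, f) {
    write_table(df, path(f))
    manifest$outputs <<- c(manifest$outputs, f)
  }
  halted <- FALSE
  run_stage <- function(name, fun) {
    if (halted || !(name %in% stages)) {
      manifest$stages[[name]] <<- if (halted) "halted" else "skipped"
      return(invisible())
    }
    res <- tryCatch({ fun(); "complete" },
                    error = function(e) {
                      halted <<- TRUE
                      paste("failed:", conditionMessage(e))
                    })
    manifest$stages[[name]] <<- res
  }

  dat <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    if (is.null(sim)) stop("simulate stage needs a sim_config")
    world <- simulate_colony_dataset(sim)
    dat$sessions <- world$sessions
    dat$dead <- world$dead_counts
    dat$bio <- world$biometrics
    add_output(world$sessions, "recapture_sessions.csv")
    add_output(world$dead_counts, "dead_counts.csv")
    add_output(world$biometrics, "biometrics.csv")
    add_output(world$ground_truth, "ground_truth.csv")
    yaml::write_yaml(sim_config_to_list(sim), path("sim_config.yaml"))
    manifest$outputs <<- c(manifest$outputs, "sim_config.yaml")
  })

  load_or <- function(slot, reader, key) {
    if (!is.null(dat[[slot]])) return(dat[[slot]])
    if (is.null(inputs[[key]])) stop("no ", key, " input available")
    reader(inputs[[key]])
  }

  run_stage("estimate", function() {
    sessions <- load_or("sessions", read_recapture_sessions, "sessions")
    dead <- load_or("dead", read_dead_counts, "dead_counts")
    ab <- estimate_abundance(sessions, ci_level = ci_level)
    dat$abundance <- ab
    add_output(ab, "abundance_estimates.csv")
    add_output(mortality_summary(dead, ab), "mortality.csv")
  })

  run_stage("condition", function() {
    bio <- validate_pup_records(load_or("bio", read_biometrics, "biometrics"))
    fit <- fit_allometry(bio)
    cond <- add_condition(bio, fit)
    dat$cond <- cond
    add_output(data.frame(a = fit$a, b = fit$b, n = fit$n,
                          residual_sd = fit$residual_sd),
               "allometry.csv")
    add_output(cond, "condition.csv")
    add_output(classify_condition(cond), "classification.csv")
  })

  run_stage("models", function() {
    cond <- dat$cond
    if (is.null(cond)) stop("condition stage outputs required for models")
    ref_day <- if (is.null(reference_day)) stats::median(cond$day) else reference_day
    rankings <- list(); coefs <- list(); std <- list(); chg <- list(); cors <- list()
    day_effects <- c(mass = 0, bci1 = 0)
    for (resp in c("mass", "bci1")) {
      sel <- select_model(
        candidate_specs(resp, cond, include_interactions = include_interactions),
        cond)
      rankings[[resp]] <- cbind(response = resp, sel$ranking)
      coefs[[resp]] <- cbind(response = resp, sel$best$coefficients)
      cf <- sel$best$coefficients
      if ("day" %in% cf$term) day_effects[resp] <- cf$estimate[cf$term == "day"]
      for (cl in sort(unique(cond$colony))) {
        ser <- standardise_by_day(cond[cond$colony == cl, , drop = FALSE],
                                  response = resp,
                                  fixed_day_effect = day_effects[resp],
                                  reference_day = ref_day)
        std[[paste(resp, cl)]] <- cbind(response = resp, as.data.frame(ser))
        ch <- inter_survey_change(ser)
        chg[[paste(resp, cl)]] <- data.frame(
          response = resp, colony = cl, interval = names(ch),
          percent_change = unname(ch), stringsAsFactors = FALSE)
        if (resp == "mass" && !is.null(dat$abundance)) {
          cor_res <- mass_abundance_correlation(
            ser, dat$abundance[dat$abundance$colony == cl, , drop = FALSE])
          cors[[cl]] <- data.frame(colony = cl, r = cor_res$r, p = cor_res$p,
                                   n = cor_res$n, stringsAsFactors = FALSE)
        }
      }
    }
    dat$std <- do.call(rbind, unname(std))
    add_output(do.call(rbind, unname(rankings)), "model_ranking.csv")
    add_output(do.call(rbind, unname(coefs)), "model_coefficients.csv")
    add_output(dat$std, "standardised_series.csv")
    add_output(do.call(rbind, unname(chg)), "inter_survey_changes.csv")
    if (length(cors))
      add_output(do.call(rbind, unname(cors)), "mass_abundance_correlations.csv")
    add_output(data.frame(response = names(day_effects),
                          day_effect = unname(day_effects),
                          reference_day = ref_day),
               "day_standardisation.csv")
  })

  run_stage("trend", function() {
    ab <- dat$abundance
    if (is.null(ab)) stop("estimate stage outputs required for trend")
    res <- trend_by_colony(ab, family = family, basis_dim = basis_dim)
    grids <- list(); tps <- list(); sps <- list(); sums <- list()
    for (cl in names(res)) {
      r <- res[[cl]]
      g <- cbind(colony = cl, r$fit$grid,
                 r$derivatives[, c("derivative", "se", "ci_lower", "ci_upper",
                                   "significant")])
      names(g) <- c("colony", "year", "fit", "se", "ci_lower", "ci_upper",
                    "derivative", "d_se", "d_ci_lower", "d_ci_upper",
                    "significant")
      grids[[cl]] <- g
      if (nrow(r$turning_points))
        tps[[cl]] <- cbind(colony = cl, r$turning_points)
      if (nrow(r$significant_periods))
        sps[[cl]] <- cbind(colony = cl, r$significant_periods)
      sums[[cl]] <- data.frame(colony = cl, family = r$fit$family,
                               edf = r$fit$edf,
                               deviance_explained = r$fit$deviance_explained,
                               n_surveys = length(r$fit$years))
    }
    add_output(do.call(rbind, unname(grids)), "trend.csv")
    add_output(if (length(tps)) do.call(rbind, unname(tps)) else
      data.frame(colony = character(), year_before = numeric(),
                 year_after = numeric(), direction = character(),
                 significant = logical()), "turning_points.csv")
    add_output(if (length(sps)) do.call(rbind, unname(sps)) else
      data.frame(colony = character(), start_year = numeric(),
                 end_year = numeric(), sign = character()),
      "significant_periods.csv")
    add_output(do.call(rbind, unname(sums)), "trend_summaries.csv")
  })

  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$outputs <- c(manifest$outputs, "manifest.json")
  invisible(manifest)
}

# Round-trippable plain-list view of a sim_config (for the YAML sidecar).
sim_config_to_list <- function(sim) {
  list(seed = sim$seed, start_year = sim$start_year, n_years = sim$n_years,
       biometrics = sim$biometrics,
       colonies = lapply(sim$colonies, function(cc) {
         cc <- unclass(cc)
         cc$drops <- as.list(cc$drops)
         cc
       }))
}

#' Rebuild a sim_config from its YAML sidecar
#'
#' @param path Path to a `sim_config.yaml` written by [run_pipeline()].
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_config(seed = x$seed, start_year = x$start_year, n_years = x$n_years,
             biometrics = x$biometrics,
             colonies = lapply(x$colonies, function(cc) {
               colony_config(cc$name, cc$baseline, cc$decline_rate,
                             cc$sin_amplitude, cc$sin_period,
                             unlist(cc$drops), cc$marking_fraction,
                             cc$q_replicates, cc$coverage, cc$mortality_rate,
                             cc$colony_offset_kg, cc$pups_measured,
                             unlist(cc$late_years), cc$late_shift_days)
             }))
}

#' Human-readable summary report of a pipeline run
#'
#' One document with the per-colony abundance table (estimates rounded to
#' integers, CI in parentheses), trend summaries (edf, deviance explained),
#' turning points with direction and significance, condition
#' classification tallies, and compound decline totals composed from the
#' run's own period changes.  Partial runs produce partial reports with
#' explicit gaps.
#'
#' @param out_dir Directory of a completed (or partial) [run_pipeline()] run.
#' @return Character vector of report lines, invisibly; also written to
#'   `report.txt` in `out_dir`.
#' @export
summary_report <- function(out_dir) {
  path <- function(f) file.path(out_dir, f)
  lines <- c("Colony monitoring summary report",
             strrep("=", 32), "")
  if (file.exists(path("abundance_estimates.csv"))) {
    ab <- utils::read.csv(path("abundance_estimates.csv"))
    lines <- c(lines, "Live pup abundance estimates (mean, 95% CI):")
    for (cl in sort(unique(ab$colony))) {
      lines <- c(lines, paste0("  ", cl, ":"))
      d <- ab[ab$colony == cl, ]
      lines <- c(lines, sprintf("    %d: %d (%d-%d)", d$year,
                                round(d$mean_estimate), round(d$ci_lower),
                                round(d$ci_upper)))
      # decline totals: maximum -> mid-study -> final survey, composed
      mx <- which.max(d$mean_estimate)
      mid <- which.min(abs(d$year - (min(d$year) + 25)))
      if (mx < mid && mid < nrow(d)) {
        p1 <- period_percent_change(d$mean_estimate[mx], d$mean_estimate[mid])
        p2 <- period_percent_change(d$mean_estimate[mid],
                                    d$mean_estimate[nrow(d)])
        lines <- c(lines, sprintf(
          "    decline %d-%d: %.1f%%; %d-%d: %.1f%%; compound total: %.0f%%",
          d$year[mx], d$year[mid], p1, d$year[mid], d$year[nrow(d)], p2,
          compound_percent_changes(c(p1, p2))))
      }
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "[abundance estimates not available]", "")
  if (file.exists(path("trend_summaries.csv"))) {
    ts <- utils::read.csv(path("trend_summaries.csv"))
    lines <- c(lines, "Trend smooths:",
               sprintf("  %s (%s): edf = %.2f, deviance explained = %.1f%%",
                       ts$colony, ts$family, ts$edf,
                       100 * ts$deviance_explained), "")
    tp <- utils::read.csv(path("turning_points.csv"))
    if (nrow(tp) == 0) {
      lines <- c(lines, "Turning points: none found", "")
    } else {
      lines <- c(lines, "Turning points:",
                 sprintf("  %s: %.4g/%.4g (%s)%s", tp$colony, tp$year_before,
                         tp$year_after, tp$direction,
                         ifelse(tp$significant, " [significant]", "")), "")
    }
  } else lines <- c(lines, "[trend results not available]", "")
  if (file.exists(path("classification.csv"))) {
    cls <- utils::read.csv(path("classification.csv"))
    agg <- stats::aggregate(status ~ colony, cls,
                            function(s) c(better = sum(s == "better"),
                                          total = length(s)))
    lines <- c(lines, "Condition (BCI2) classification:",
               sprintf("  %s: better-than-expected in %d of %d years",
                       agg$colony, agg$status[, "better"],
                       agg$status[, "total"]), "")
  } else lines <- c(lines, "[condition classification not available]", "")
  writeLines(lines, path("report.txt"))
  invisible(lines)
}
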