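#' Pipeline configuration
#'
#' Single place holding every knob of the end-to-end analysis, each
#' defaulting to the package's documented choice. A run is reproducible
#' from the manifest that serializes this configuration.
#'
#' @param truth a [simulation_truth()] (simulate input data) or NULL
#' @param input_dir directory of cohort csv tables (used when `truth` is
#'   NULL)
#' @param seed master analysis seed (matching tie-breaks, imputation,
#'   sampler)
#' @param policy_date TAF availability date
#' @param tdf_days cumulative TDF days-supplied threshold for eligibility
#' @param lookback_days baseline measurement lookback window
#' @param study_end administrative study end
#' @param ratio,caliper matching controls per switcher and score caliper
#' @param timepoints a priori ATT months
#' @param rope region of practical equivalence (eGFR units)
#' @param spline_df,chains,iter,warmup outcome-model settings
#' @param rhat_max split-R-hat tolerance for outcome-model convergence
#' @param mi_m,mi_cycles,mi_window_days SA3 settings
#' @param weight_truncation SA2 stabilized-weight truncation percentiles
#' @param analyses which analyses to run (subset of main, sa1, sa2, sa3)
#' @param apply_deviations inject treatment deviations into simulated data
#' @param out_dir output directory (NULL: nothing written)
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(truth = simulation_truth(),
                            input_dir = NULL,
                            seed = 1L,
                            policy_date = as.Date("2019-10-01"),
                            tdf_days = 183,
                            lookback_days = 365,
                            study_end = as.Date("2022-06-30"),
                            ratio = 4, caliper = Inf,
                            timepoints = c(0.5, 3, 6, 9, 12, 15, 18),
                            rope = c(-2, 2),
                            spline_df = 4, chains = 2, iter = 1000,
                            warmup = 500,
                            rhat_max = 1.1,
                            mi_m = 10, mi_cycles = 10, mi_window_days = 42,
                            weight_truncation = c(0.01, 0.99),
                            analyses = c("main", "sa1", "sa2", "sa3"),
                            apply_deviations = TRUE,
                            out_dir = NULL) {
  cfg <- list(truth = truth, input_dir = input_dir, seed = as.integer(seed),
              policy_date = as.Date(policy_date), tdf_days = tdf_days,
              lookback_days = lookback_days, study_end = as.Date(study_end),
              ratio = ratio, caliper = caliper, timepoints = timepoints,
              rope = rope, spline_df = spline_df, chains = chains,
              iter = iter, warmup = warmup, rhat_max = rhat_max, mi_m = mi_m,
              mi_cycles = mi_cycles, mi_window_days = mi_window_days,
              weight_truncation = weight_truncation, analyses = analyses,
              apply_deviations = apply_deviations, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$truth) && is.null(cfg$input_dir)) {
    stop("config must provide either simulation truth or an input directory")
  }
  if (!is.null(cfg$input_dir)) {
    needed <- file.path(cfg$input_dir,
                        paste0(c("persons", "dispensings", "labs", "weights",
                                 "comorbidities"), ".csv"))
    missing <- needed[!file.exists(needed)]
    if (length(missing)) {
      stop("missing required input table(s): ",
           paste(basename(missing), collapse = ", "))
    }
  }
  if (!all(cfg$analyses %in% c("main", "sa1", "sa2", "sa3"))) {
    stop("analyses must be a subset of main, sa1, sa2, sa3")
  }
  if (cfg$rope[1] >= cfg$rope[2]) stop("reversed ROPE bounds")
  if (cfg$ratio < 1) stop("ratio must be >= 1")
  invisible(cfg)
}

config_manifest <- function(cfg) {
  out <- cfg
  out$truth <- if (!is.null(cfg$truth)) truth_manifest(cfg$truth)
  out$policy_date <- as.character(cfg$policy_date)
  out$study_end <- as.character(cfg$study_end)
  unclass(out)
}

#' Run the full switching analysis pipeline
#'
#' simulate (or read) -> eGFR recalculation -> eligibility and covariate
#' assembly with random-forest imputation -> extended-Cox time-varying
#' propensity model -> sequential risk-set matching and index-date
#' assignment -> Bayesian counterfactual outcome model -> sensitivity
#' analyses -> combined ATT summary table, attrition counts, manifest and
#' log. When `cfg$out_dir` is set, all tables are written there as csv
#' (ISO-8601 dates), summaries also as JSON, and an observed-eGFR
#' trajectory figure is drawn if ggplot2 is available.
#'
#' @param cfg a [pipeline_config()]
#' @param verbose print log lines as they happen
#' @return list of class `pipeline_run` with all intermediate objects,
#'   `att` (combined summary), `counts` (attrition) and `log`
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = FALSE) {
  validate_config(cfg)
  log <- new_log()
  stage <- function(nm) log_msg(log, sprintf("== stage: %s ==", nm),
                                verbose = verbose)

  stage("data")
  if (!is.null(cfg$truth)) {
    cohort <- simulate_cohort(cfg$truth)
    if (cfg$apply_deviations) cohort <- inject_deviations(cohort, cfg$truth)
  } else {
    cohort <- read_cohort(cfg$input_dir)
  }
  log_count(log, "persons_input", nrow(cohort$persons))

  stage("renal_metrics")
  egfr <- egfr_from_labs(cohort$labs, cohort$persons)

  stage("eligibility")
  eligibility <- compute_switch_eligible_date(cohort$dispensings,
                                              cfg$policy_date, cfg$tdf_days)
  elig <- apply_exclusions(cohort$persons, cohort$dispensings, eligibility,
                           cfg$study_end, log = log)
  profiles <- build_covariate_profiles(cohort$persons, elig, egfr,
                                       cohort$weights, cohort$comorbidities,
                                       cfg$lookback_days)
  profiles <- impute_covariates_rf(profiles, seed = sub_seed(cfg$seed, 21L))
  log_count(log, "eligible_included", nrow(profiles))

  stage("tvps_matching")
  switch_dates <- observed_switch_dates(cohort$dispensings, profiles)
  cp <- build_risk_intervals(profiles, cohort$comorbidities, switch_dates,
                             cohort$persons, cfg$study_end)
  if (!sum(cp$event)) stop("pipeline stopped at matching: no switch events")
  tvps <- fit_tvps_model(cp, log = log)
  matched <- sequential_match(tvps, profiles, cohort$comorbidities,
                              switch_dates, cohort$persons,
                              ratio = cfg$ratio, caliper = cfg$caliper,
                              seed = cfg$seed, study_end = cfg$study_end,
                              log = log)
  if (!nrow(matched)) stop("pipeline stopped at matching: no matched sets")
  indexed <- assign_index_dates(matched, profiles, cohort$persons,
                                cfg$study_end, log = log)

  stage("outcome")
  dataset <- build_outcome_dataset(indexed, egfr, profiles, cohort$weights,
                                   cohort$comorbidities,
                                   max_months = max(cfg$timepoints),
                                   lookback_days = cfg$lookback_days,
                                   log = log)
  spec <- outcome_model_spec(spline_df = cfg$spline_df,
                             max_months = max(cfg$timepoints),
                             chains = cfg$chains, iter = cfg$iter,
                             warmup = cfg$warmup, rhat_max = cfg$rhat_max,
                             seed = sub_seed(cfg$seed, 22L))
  fits <- list()
  att_list <- list()
  if ("main" %in% cfg$analyses) {
    fits$main <- fit_outcome_model(dataset, spec, log = log)
    att_list$main <- compute_att(fits$main, cfg$timepoints, cfg$rope)
  }

  stage("sensitivity")
  weights_tab <- NULL
  if ("sa1" %in% cfg$analyses) {
    sa1_data <- censor_at_deviation(dataset, cohort$dispensings, log = log)
    fits$sa1 <- fit_outcome_model(sa1_data, spec, log = log)
    att_list$sa1 <- compute_att(fits$sa1, cfg$timepoints, cfg$rope)
  }
  if ("sa2" %in% cfg$analyses) {
    incl_tab <- inclusion_table(indexed, dataset, egfr, profiles,
                                cohort$weights, cohort$comorbidities,
                                cfg$lookback_days)
    weights_tab <- fit_missingness_weights(incl_tab,
                                           truncate = cfg$weight_truncation,
                                           log = log)
    fits$sa2 <- weighted_outcome_model(dataset, weights_tab, spec, log = log)
    att_list$sa2 <- compute_att(fits$sa2, cfg$timepoints, cfg$rope)
  }
  sa3 <- NULL
  if ("sa3" %in% cfg$analyses) {
    all_data <- build_outcome_dataset_all(indexed, egfr, profiles,
                                          cohort$weights,
                                          cohort$comorbidities,
                                          max_months = max(cfg$timepoints),
                                          lookback_days = cfg$lookback_days)
    sa3 <- mi_per_timepoint_regression(indexed, all_data, m = cfg$mi_m,
                                       cycles = cfg$mi_cycles,
                                       timepoints = cfg$timepoints,
                                       window_days = cfg$mi_window_days,
                                       seed = cfg$seed, log = log)
  }

  att <- combine_att(att_list, sa3)

  run <- list(cohort = cohort, egfr = egfr, eligibility = elig,
              profiles = profiles, tvps = tvps, matched = matched,
              indexed = indexed, dataset = dataset, fits = fits,
              att = att, att_draws = lapply(att_list, attr, "draws"),
              sa3 = sa3, weights = weights_tab,
              counts = counts_df(log), log = log$lines, config = cfg)
  class(run) <- "pipeline_run"
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

# first TAF dispense after eligibility, for included persons
observed_switch_dates <- function(dispensings, profiles) {
  taf <- dispensings[dispensings$drug == "TAF", , drop = FALSE]
  first_taf <- tapply(as.numeric(taf$date), taf$person_id, min)
  sw <- as_date(first_taf[as.character(profiles$person_id)])
  sw[!is.na(sw) & sw < profiles$switch_eligible_date] <- NA
  data.frame(person_id = profiles$person_id, switch_date = sw,
             stringsAsFactors = FALSE)
}

# person-level table with inclusion flag for the missingness model
inclusion_table <- function(indexed, dataset, egfr, profiles, weights,
                            comorbidities, lookback_days) {
  all_data <- build_outcome_dataset_all(indexed, egfr, profiles, weights,
                                        comorbidities,
                                        lookback_days = lookback_days)
  base <- all_data[!duplicated(all_data$person_id), , drop = FALSE]
  base$included <- base$person_id %in% unique(dataset$person_id)
  base
}

# outcome-dataset assembly without the complete-case exclusion: every
# matched person keeps a baseline row (months NA if no post-index labs)
build_outcome_dataset_all <- function(indexed, egfr, profiles, weights,
                                      comorbidities, max_months = 18,
                                      lookback_days = 365) {
  ds <- suppressWarnings(
    build_outcome_dataset(indexed, egfr, profiles, weights, comorbidities,
                          max_months, lookback_days, log = NULL))
  missing_ids <- setdiff(indexed$person_id, ds$person_id)
  if (!length(missing_ids)) return(ds)
  prof <- profiles[match(missing_ids, profiles$person_id), , drop = FALSE]
  idx <- indexed[match(missing_ids, indexed$person_id), , drop = FALSE]
  htn <- comorbidity_status_at(comorbidities, missing_ids,
                               idx$index_date)[, "hypertension"]
  extra <- data.frame(
    person_id = missing_ids, set_id = idx$set_id,
    arm = as.integer(idx$arm == "switcher"), index_date = idx$index_date,
    age = prof$age_at_tdf_init, male = prof$male,
    insurance = prof$insurance, race_ethnicity = prof$race_ethnicity,
    ever_smoker = prof$ever_smoker,
    weight_at_index = prof$weight_at_eligible,
    egfr_at_index = prof$egfr_at_eligible,
    egfr_at_eligible = prof$egfr_at_eligible,
    duration_tdf_to_eligible = prof$duration_tdf_to_eligible,
    hypertension_at_index = htn,
    date = as.Date(NA), months_since_index = NA_real_, egfr = NA_real_,
    stringsAsFactors = FALSE
  )
  out <- rbind(as.data.frame(ds), extra[names(ds)])
  class(out) <- class(ds)
  out
}

combine_att <- function(att_list, sa3 = NULL) {
  parts <- lapply(names(att_list), function(nm) {
    a <- as.data.frame(att_list[[nm]])
    a$analysis <- nm
    a
  })
  if (!is.null(sa3)) {
    parts <- c(parts, list(data.frame(
      timepoint = sa3$timepoint, median_diff = sa3$estimate,
      cri_lo = sa3$lo, cri_hi = sa3$hi, pdi = NA_real_,
      rope_fraction = NA_real_, n_draws = NA_integer_, analysis = "sa3")))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(run$cohort, file.path(dir, "input"))
  utils::write.csv(run$egfr, file.path(dir, "egfr.csv"), row.names = FALSE)
  utils::write.csv(run$eligibility, file.path(dir, "eligibility.csv"),
                   row.names = FALSE)
  utils::write.csv(run$profiles, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$matched),
                   file.path(dir, "matched_sets.csv"), row.names = FALSE)
  utils::write.csv(run$indexed, file.path(dir, "indexed_cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(run$att, file.path(dir, "att_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(run$counts, file.path(dir, "attrition.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(att = run$att, counts = run$counts,
         config = config_manifest(run$config)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, dataframe = "rows", na = "null")
  writeLines(run$log, file.path(dir, "log.txt"))
  plot_egfr_trajectories(run, file.path(dir, "fig_egfr_trajectories.png"))
  invisible(dir)
}

#' Observed eGFR trajectories by arm
#'
#' Scatter of observed eGFR against months since the index date for the
#' matched cohort, with a smoothed trend per arm (switchers vs
#' nonswitchers).
#'
#' @param run a `pipeline_run`
#' @param file optional png path; NULL draws on the current device
#' @return the ggplot object (or NULL if ggplot2 is unavailable)
#' @export
plot_egfr_trajectories <- function(run, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(invisible(NULL))
  d <- as.data.frame(run$dataset)
  d$arm_lab <- ifelse(d$arm == 1, "switcher", "nonswitcher")
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$months_since_index, y = .data$egfr,
    color = .data$arm_lab)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "Months since index date",
                  y = "eGFR (mL/min/1.73 m²)", color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600, res = 120)
    print(p)
    grDevices::dev.off()
    invisible(p)
  } else p
}

#' Attrition report
#'
#' Ordered person counts with reasons along the filter chain: input,
#' eligible, switch events observed, reclassified to nonswitcher, matched,
#' analyzable with post-index eGFR.
#'
#' @param run a `pipeline_run`, or a run directory containing
#'   `attrition.csv`
#' @return data.frame `stage`, `n`, `note`
#' @export
attrition_report <- function(run) {
  if (is.character(run)) {
    return(utils::read.csv(file.path(run, "attrition.csv"),
                           stringsAsFactors = FALSE))
  }
  stopifnot(inherits(run, "pipeline_run"))
  run$counts
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("renalswitch pipeline run\n")
  print(x$counts)
  cat("\nATT summary:\n")
  print(x$att, digits = 3)
  invisible(x)
}
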