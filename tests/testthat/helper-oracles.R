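# Independent oracles and tiny fixture builders shared across tests.

# Literal scalar transcription of the published CKD-EPI 2021 creatinine
# equation, kept deliberately separate from the vectorized implementation.
egfr_scalar_oracle <- function(scr, age, female) {
  if (female) {
    kappa <- 0.7
    alpha <- -0.241
    sexfac <- 1.012
  } else {
    kappa <- 0.9
    alpha <- -0.302
    sexfac <- 1.0
  }
  r <- scr / kappa
  term1 <- if (r < 1) r^alpha else 1
  term2 <- if (r > 1) r^(-1.200) else 1
  142 * term1 * term2 * 0.9938^age * sexfac
}

# Brute-force date-ordered greedy matcher: plain loops over data.frames,
# used as the oracle for sequential_match on small cohorts. `scores` is a
# named numeric vector of time-constant risk scores.
brute_force_match <- function(scores, eligible_date, switch_date,
                              disenroll_date, ratio = 4,
                              study_end = as.Date("2022-06-30")) {
  ids <- names(scores)
  ev <- data.frame(id = ids[!is.na(switch_date)],
                   date = switch_date[!is.na(switch_date)],
                   stringsAsFactors = FALSE)
  ev <- ev[ev$date <= study_end, , drop = FALSE]
  ev <- ev[order(ev$date), , drop = FALSE]
  used <- character(0)
  sets <- list()
  reclassified <- character(0)
  for (r in seq_len(nrow(ev))) {
    me <- ev$id[r]
    d <- ev$date[r]
    if (me %in% used) {
      reclassified <- c(reclassified, me)
      next
    }
    cand <- character(0)
    for (j in ids) {
      if (j == me || j %in% used) next
      if (eligible_date[j] > d) next
      if (!is.na(switch_date[j]) && switch_date[j] <= d) next
      if (!is.na(disenroll_date[j]) && disenroll_date[j] <= d) next
      cand <- c(cand, j)
    }
    used <- c(used, me)
    if (!length(cand)) next
    dist <- abs(scores[cand] - scores[me])
    cand <- cand[order(dist)]
    sel <- cand[seq_len(min(ratio, length(cand)))]
    used <- c(used, sel)
    sets[[length(sets) + 1]] <- list(switcher = me, controls = sel,
                                     date = d)
  }
  list(sets = sets, reclassified = reclassified)
}

# Minimal profile/switch tables for driving sequential_match with
# hand-assigned scores (score function closure over `scores`).
toy_match_inputs <- function(scores, eligible_date, switch_date,
                             disenroll_date = NULL) {
  ids <- as.integer(names(scores))
  if (is.null(disenroll_date)) {
    disenroll_date <- rep(as.Date(NA), length(ids))
    names(disenroll_date) <- names(scores)
  }
  profiles <- data.frame(person_id = ids,
                         switch_eligible_date = unname(eligible_date))
  persons <- data.frame(person_id = ids,
                        disenrollment_date = unname(disenroll_date))
  switch_dates <- data.frame(person_id = ids,
                             switch_date = unname(switch_date))
  score_fun <- function(profiles, comorbidities, pids, date) {
    unname(scores[as.character(pids)])
  }
  list(profiles = profiles, persons = persons,
       switch_dates = switch_dates, score_fun = score_fun,
       comorbidities = data.frame(person_id = integer(0),
                                  condition = character(0),
                                  onset_date = as.Date(character(0))))
}

# Random toy cohort (n <= 10) for oracle-equivalence sweeps. Scores drawn
# with ties impossible (continuous); distinct switch dates so the greedy
# order is unambiguous and the oracle comparison is exact.
random_toy_cohort <- function(n, seed) {
  set.seed(seed)
  ids <- seq_len(n)
  origin <- as.Date("2020-01-01")
  eligible <- origin + sample(0:200, n, replace = TRUE)
  is_switcher <- runif(n) < 0.45
  switch_date <- rep(as.Date(NA), n)
  k <- sum(is_switcher)
  if (k > 0) {
    offs <- sample(10:600, k)           # distinct switch dates
    switch_date[is_switcher] <- eligible[is_switcher] + offs
  }
  disenroll <- rep(as.Date(NA), n)
  drop_out <- runif(n) < 0.2
  disenroll[drop_out] <- eligible[drop_out] + sample(50:500, sum(drop_out),
                                                     replace = TRUE)
  # a person cannot switch after disenrollment
  bad <- !is.na(switch_date) & !is.na(disenroll) & switch_date >= disenroll
  switch_date[bad] <- NA
  scores <- stats::rnorm(n)
  names(scores) <- ids
  names(eligible) <- ids
  names(switch_date) <- ids
  names(disenroll) <- ids
  list(scores = scores, eligible = eligible, switch_date = switch_date,
       disenroll = disenroll)
}

# Small deterministic outcome dataset with a constant additive arm effect;
# used for outcome-model unit tests without the full pipeline.
toy_outcome_dataset <- function(n_sets = 20, controls_per_set = 2,
                                effect = 3, resid_sd = 0, seed = 1,
                                n_visits = 5) {
  set.seed(seed)
  rows <- list()
  pid <- 0
  for (s in seq_len(n_sets)) {
    for (r in seq_len(1 + controls_per_set)) {
      pid <- pid + 1
      arm <- as.integer(r == 1)
      base <- rnorm(1, 95, 10)
      mo <- sort(runif(n_visits, 0.2, 17.5))
      rows[[pid]] <- data.frame(
        person_id = pid, set_id = s, arm = arm,
        index_date = as.Date("2020-06-01"),
        age = runif(1, 25, 60), male = runif(1) < 0.95,
        insurance = factor(sample(c("commercial", "Medicaid", "Medicare",
                                    "other"), 1),
                           levels = c("commercial", "Medicaid", "Medicare",
                                      "other")),
        race_ethnicity = factor(sample(c("Asian NH", "Black NH", "Hispanic",
                                         "White NH", "Other NH"), 1),
                                levels = c("Asian NH", "Black NH", "Hispanic",
                                           "White NH", "Other NH")),
        ever_smoker = runif(1) < 0.3,
        weight_at_index = rnorm(1, 85, 10),
        egfr_at_index = base,
        egfr_at_eligible = base + rnorm(1, 0, 2),
        duration_tdf_to_eligible = runif(1, 183, 1200),
        hypertension_at_index = runif(1) < 0.1,
        date = as.Date("2020-06-01") + round(mo * 30.4375),
        months_since_index = mo,
        egfr = base + arm * effect + rnorm(n_visits, 0, resid_sd)
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("outcome_dataset", "data.frame")
  out
}

# Simulate + eligibility + TV-PS + matching only (no outcome model);
# returns what the matching-oriented checks need.
matching_only_run <- function(seed, n = 300, ...) {
  tr <- simulation_truth(n_persons = n, seed = seed, ...)
  co <- inject_deviations(simulate_cohort(tr), tr)
  eg <- egfr_from_labs(co$labs, co$persons)
  elig_dates <- compute_switch_eligible_date(co$dispensings)
  elig <- apply_exclusions(co$persons, co$dispensings, elig_dates)
  prof <- build_covariate_profiles(co$persons, elig, eg, co$weights,
                                   co$comorbidities)
  prof <- impute_covariates_rf(prof, seed = seed + 1000L)
  sw <- observed_switch_dates_for_test(co$dispensings, prof)
  cp <- build_risk_intervals(prof, co$comorbidities, sw, co$persons)
  tvps <- suppressWarnings(fit_tvps_model(cp))
  matched <- sequential_match(tvps, prof, co$comorbidities, sw, co$persons,
                              ratio = 4, seed = seed)
  indexed <- assign_index_dates(matched, prof, co$persons)
  list(cohort = co, profiles = prof, switch_dates = sw, tvps = tvps,
       matched = matched, indexed = indexed, truth = tr)
}

# Standardized mean differences of the TV-PS covariates, pre-matching
# (eventual switchers vs the rest of the eligible cohort) and post-matching
# (matched switchers vs matched controls); factors are summarized by the
# mean absolute SMD over their level indicators.
covariate_smds <- function(mr) {
  prof <- mr$profiles
  pre_g <- !is.na(mr$switch_dates$switch_date[
    match(prof$person_id, mr$switch_dates$person_id)])
  post_ids <- mr$indexed$person_id
  post_g <- mr$indexed$arm == "switcher"
  numeric_covs <- c(age_at_tdf_init = "age_at_tdf_init",
                    weight = "weight_at_eligible",
                    egfr = "egfr_at_eligible",
                    year = "year_eligibility_met",
                    male = "male", smoker = "ever_smoker",
                    diabetes = "diabetes_at_eligible",
                    dyslipidemia = "dyslipidemia_at_eligible",
                    hypertension = "hypertension_at_eligible")
  one_group <- function(rows, g) {
    out <- vapply(numeric_covs, function(cv)
      smd(as.numeric(prof[[cv]][rows]), g), numeric(1))
    for (fc in c("insurance", "race_ethnicity")) {
      lv <- levels(prof[[fc]])
      out[[fc]] <- mean(vapply(lv, function(l)
        smd(prof[[fc]][rows] == l, g), numeric(1)))
    }
    unlist(out)
  }
  pre <- one_group(seq_len(nrow(prof)), pre_g)
  post <- one_group(match(post_ids, prof$person_id), post_g)
  list(pre = pre, post = post)
}

# Internal accessor used by matching tests.
observed_switch_dates_for_test <- function(dispensings, profiles) {
  renalswitch:::observed_switch_dates(dispensings, profiles)
}

# Quick small-cohort pipeline run used by several test files.
small_run <- function(seed = 1, n = 300, iter = 300, warmup = 200,
                      analyses = "main", effect = piecewise_effect(c(0, 3),
                                                                   c(0, 3)),
                      ...) {
  tr <- simulation_truth(n_persons = n, seed = seed, true_effect = effect,
                         ...)
  cfg <- pipeline_config(truth = tr, seed = seed, iter = iter,
                         warmup = warmup, analyses = analyses,
                         rhat_max = Inf)   # structural tests: chains too
                                           # short for a meaningful R-hat
  suppressWarnings(run_pipeline(cfg))
}
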