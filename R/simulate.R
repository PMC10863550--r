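#' Generate a synthetic EHR cohort with known ground truth
#'
#' Simulates an EHR-like PrEP cohort with the statistical structure the
#' analysis pipeline assumes: a confounded TDF-to-TAF switch process (older
#' age, lower baseline eGFR and prevalent comorbidity raise the switch
#' hazard), a latent eGFR trajectory with negative drift on TDF shifted by
#' the configured true switch effect, irregular Poisson-process lab visits,
#' covariate-dependent (MAR) lab missingness, sparse weight measurements,
#' age-dependent comorbidity onsets and health-plan disenrollment. Latent
#' eGFR is inverted through the CKD-EPI 2021 equation so the emitted labs
#' are serum creatinine, as in a real EHR.
#'
#' The returned object carries the latent state (visit times, residuals,
#' per-lab applied effect) as an attribute so that [inject_deviations()] can
#' rewrite exposure histories consistently; identical seeds give identical
#' tables.
#'
#' @param truth a [simulation_truth()] object
#' @return an object of class `ehr_cohort`: list of data.frames `persons`,
#'   `dispensings`, `labs`, `weights`, `comorbidities`, plus `manifest`
#' @export
simulate_cohort <- function(truth) {
  validate_truth(truth)
  frame <- draw_person_frame(truth)
  cohort <- emit_tables(frame, truth)
  cohort$manifest <- truth_manifest(truth)
  cohort
}

# Person-level latent frame: everything random is drawn here (or in
# inject_deviations), emission is deterministic given the frame.
draw_person_frame <- function(truth) {
  n <- truth$n_persons
  policy <- as.Date("2019-10-01")

  set.seed(sub_seed(truth$seed, 1L))
  race <- factor(sample(RACE_LEVELS, n, TRUE, prob = truth$race_p),
                 levels = RACE_LEVELS)
  # White NH users skew older, Hispanic younger: a realistic demographic
  # gradient that makes race a genuine (indirect) confounder of switching.
  age_shift <- c("Asian NH" = 0, "Black NH" = 0, "Hispanic" = -3,
                 "White NH" = 3, "Other NH" = 0)[as.character(race)]
  age <- pmax(18, stats::rnorm(n, 38 + age_shift, 11))
  sex <- factor(sample(SEX_LEVELS, n, TRUE,
                       prob = truth$sex_p[SEX_LEVELS]), levels = SEX_LEVELS)
  # Insurance: Medicare/Medicaid odds rise with age.
  ins <- vapply(seq_len(n), function(i) {
    p <- truth$insurance_p
    tilt <- exp(0.08 * (age[i] - 38))
    p["Medicare"] <- p["Medicare"] * tilt
    p["Medicaid"] <- p["Medicaid"] * sqrt(tilt)
    sample(INSURANCE_LEVELS, 1, prob = p / sum(p))
  }, character(1))
  insurance <- factor(ins, levels = INSURANCE_LEVELS)
  smoker <- stats::runif(n) < stats::plogis(
    stats::qlogis(truth$smoking_p) + 0.04 * (age - 38))
  first_tdf <- as_date(round(stats::runif(
    n, as.numeric(truth$enrollment_window[1]),
    as.numeric(truth$enrollment_window[2]))))
  ckd_flag <- stats::runif(n) < truth$baseline_ckd_p
  weight0 <- stats::rnorm(n, truth$weight_mean_sd[1] + 0.15 * (age - 38),
                          truth$weight_mean_sd[2])
  egfr0 <- stats::rnorm(n,
                        truth$baseline_egfr_mean_sd[1] - 4.5 * (age - 38) / 10,
                        truth$baseline_egfr_mean_sd[2])
  egfr0 <- pmin(pmax(egfr0, 30), 150)
  egfr0[ckd_flag] <- pmin(egfr0[ckd_flag], 55)

  set.seed(sub_seed(truth$seed, 2L))
  dis_t <- stats::rexp(n, truth$disenroll_rate)
  disenroll <- first_tdf + round(dis_t * 365.25)
  disenroll[disenroll > truth$study_end] <- NA
  end_fu <- as_date(pmin(
    ifelse(is.na(disenroll), as.numeric(truth$study_end),
           as.numeric(disenroll)),
    as.numeric(truth$study_end)))

  # Comorbidity onsets: age-dependent exponential hazards running from age
  # 18; onsets before EHR entry are recorded at the first TDF dispense
  # (prevalent-at-entry convention).
  set.seed(sub_seed(truth$seed, 3L))
  onsets <- lapply(COMORBIDITIES, function(cond) {
    h <- truth$comorbidity_rates[cond] * 2^((age - 38) / 20)
    t_onset <- stats::rexp(n, h)            # years after age 18
    onset_age <- 18 + t_onset
    onset_date <- first_tdf + round((onset_age - age) * 365.25)
    onset_date[onset_age < age] <- first_tdf[onset_age < age]
    onset_date[onset_date > end_fu] <- NA
    as_date(onset_date)
  })
  names(onsets) <- COMORBIDITIES
  first_onset <- do.call(pmin, c(onsets, list(na.rm = TRUE)))

  # Confounded switch process: piecewise-constant hazard (comorbidity step),
  # at risk from max(policy date, first TDF + 30d) to end of follow-up.
  set.seed(sub_seed(truth$seed, 4L))
  cs <- truth$confounding_strength
  lp <- cs["age"] * (age - 38) / 10 + cs["egfr"] * (egfr0 - 100) / 10
  risk_start <- pmax(policy, first_tdf + 30)
  wave_end <- policy + round(truth$uptake_wave["duration_years"] * 365.25)
  wave_mult <- truth$uptake_wave["multiplier"]
  switch_date <- rep(as.Date(NA), n)
  u <- stats::rexp(n)                        # unit-exponential draws
  for (i in seq_len(n)) {
    if (risk_start[i] >= end_fu[i]) next
    # piecewise-constant hazard: segments change at the first comorbidity
    # onset (multiplier exp(cs_comorbidity)) and at the end of the early
    # uptake wave (multiplier drops from wave_mult to 1)
    h_base <- truth$baseline_switch_hazard * exp(lp[i])
    t_on <- first_onset[i]
    brk <- sort(unique(c(
      as.numeric(wave_end), if (!is.na(t_on)) as.numeric(t_on))))
    brk <- brk[brk > as.numeric(risk_start[i]) & brk < as.numeric(end_fu[i])]
    starts <- c(as.numeric(risk_start[i]), brk)
    stops <- c(brk, as.numeric(end_fu[i]))
    rem <- u[i]
    for (s2 in seq_along(starts)) {
      h <- h_base *
        (if (starts[s2] < as.numeric(wave_end)) wave_mult else 1) *
        (if (!is.na(t_on) && starts[s2] >= as.numeric(t_on))
          exp(cs["comorbidity"]) else 1)
      d_yrs <- (stops[s2] - starts[s2]) / 365.25
      if (rem < h * d_yrs) {
        switch_date[i] <- as_date(starts[s2] + round(365.25 * rem / h))
        break
      }
      rem <- rem - h * d_yrs
    }
  }
  switch_date[!is.na(switch_date) & switch_date >= end_fu] <- NA

  # Lab visits: person-level Poisson process; one guaranteed screening visit
  # at TDF initiation. Observation indicators use a uniform draw against a
  # covariate-only (MAR) logistic model at emission time.
  set.seed(sub_seed(truth$seed, 5L))
  visits <- vector("list", n)
  for (i in seq_len(n)) {
    yrs <- as.numeric(end_fu[i] - first_tdf[i]) / 365.25
    k <- stats::rpois(1, truth$visit_rate * max(yrs, 0))
    vt <- sort(round(stats::runif(k, 0, max(as.numeric(end_fu[i] - first_tdf[i]), 0))))
    vt <- unique(c(0, vt))
    visits[[i]] <- data.frame(
      person_id = i,
      date = first_tdf[i] + vt,
      u_obs = stats::runif(length(vt)),
      resid = stats::rnorm(length(vt), 0, truth$residual_sd),
      u_weight = stats::runif(length(vt)),
      w_noise = stats::rnorm(length(vt), 0, 1.5)
    )
  }
  visit_df <- do.call(rbind, visits)

  set.seed(sub_seed(truth$seed, 6L))
  gap_u <- stats::runif(n)                   # refill-gap propensity per person

  list(
    persons = data.frame(
      person_id = seq_len(n),
      age_at_tdf_init = age,
      sex = sex,
      race_ethnicity = race,
      insurance = insurance,
      ever_smoker = smoker,
      first_tdf_dispense = first_tdf,
      disenrollment_date = as_date(disenroll),
      baseline_ckd_flag = ckd_flag,
      stringsAsFactors = FALSE
    ),
    egfr0 = egfr0, weight0 = weight0, end_fu = end_fu,
    onsets = onsets, switch_date = switch_date,
    switch_back = rep(as.Date(NA), n),
    visit_df = visit_df, gap_u = gap_u
  )
}

# Deterministic emission of the five tables from the latent frame.
emit_tables <- function(frame, truth) {
  persons <- frame$persons
  n <- nrow(persons)
  policy <- as.Date("2019-10-01")

  # dispensings: 30-day TDF fills until switch/censor, TAF fills after the
  # switch, TDF again after any switch-back. A minority of persons have
  # occasional refill gaps (gaps do not reset eligibility accrual).
  disp <- vector("list", n)
  for (i in seq_len(n)) {
    start <- persons$first_tdf_dispense[i]
    end <- frame$end_fu[i]
    sw <- frame$switch_date[i]
    sb <- frame$switch_back[i]
    gap <- if (frame$gap_u[i] < 0.15) 20L else 0L   # habitual late refiller
    fills <- function(drug, from, to) {
      if (is.na(from) || from >= to) return(NULL)
      dates <- seq(from, to - 1, by = 30 + gap)
      data.frame(person_id = i, date = dates, drug = drug,
                 days_supplied = 30L, stringsAsFactors = FALSE)
    }
    tdf_end <- min(end, if (!is.na(sw)) sw else end)
    out <- list(fills("TDF", start, tdf_end))
    if (!is.na(sw)) {
      taf_end <- min(end, if (!is.na(sb)) sb else end)
      out <- c(out, list(fills("TAF", sw, taf_end)))
      if (!is.na(sb)) out <- c(out, list(fills("TDF", sb, end)))
    }
    disp[[i]] <- do.call(rbind, out)
  }
  dispensings <- do.call(rbind, disp)
  rownames(dispensings) <- NULL

  # labs: latent eGFR -> creatinine at each observed visit
  v <- frame$visit_df
  i <- v$person_id
  yrs_since_tdf <- as.numeric(v$date - persons$first_tdf_dispense[i]) / 365.25
  sw <- frame$switch_date[i]
  sb <- frame$switch_back[i]
  on_taf <- !is.na(sw) & v$date >= sw & (is.na(sb) | v$date < sb)
  months_on_taf <- ifelse(on_taf,
                          as.numeric(v$date - sw) / DAYS_PER_MONTH, 0)
  effect <- ifelse(on_taf, truth$true_effect(months_on_taf), 0)
  latent_egfr <- frame$egfr0[i] + truth$egfr_slope_per_year * yrs_since_tdf +
    effect + v$resid
  latent_egfr <- pmin(pmax(latent_egfr, 8), 155)
  # MAR observation model: covariates only (age, baseline eGFR, elapsed time)
  mm <- truth$missingness_model
  eta <- mm["intercept"] + mm["age"] * (persons$age_at_tdf_init[i] - 38) / 10 +
    mm["egfr"] * (frame$egfr0[i] - 100) / 10 +
    mm["months"] * yrs_since_tdf * 12
  p_obs <- stats::plogis(eta)
  observed <- v$u_obs < p_obs | yrs_since_tdf == 0   # screening lab always kept
  age_at_lab <- pmax(persons$age_at_tdf_init[i] + yrs_since_tdf, 18)
  scr <- invert_egfr(latent_egfr[observed], age_at_lab[observed],
                     as.character(persons$sex[i])[observed])
  labs <- data.frame(
    person_id = v$person_id[observed],
    date = v$date[observed],
    serum_creatinine = round(scr, 4),
    stringsAsFactors = FALSE
  )

  # weights: measured at initiation and at ~35% of visits
  wsel <- v$u_weight < 0.35 | yrs_since_tdf == 0
  weights <- data.frame(
    person_id = v$person_id[wsel],
    date = v$date[wsel],
    kg = round(frame$weight0[v$person_id[wsel]] + v$w_noise[wsel], 1),
    stringsAsFactors = FALSE
  )

  comorb <- do.call(rbind, lapply(COMORBIDITIES, function(cond) {
    d <- frame$onsets[[cond]]
    ok <- !is.na(d)
    if (!any(ok)) return(NULL)
    data.frame(person_id = which(ok), condition = cond, onset_date = d[ok],
               stringsAsFactors = FALSE)
  }))
  comorb <- comorb[order(comorb$person_id, comorb$condition), ]
  rownames(comorb) <- NULL

  structure(
    list(persons = persons, dispensings = dispensings, labs = labs,
         weights = weights, comorbidities = comorb, manifest = NULL),
    latent = frame,
    class = "ehr_cohort"
  )
}

#' Inject treatment deviations into a simulated cohort
#'
#' Adds the two kinds of protocol deviation the sensitivity analyses must
#' handle: switchers who revert to TDF (switch-back), and additional late
#' TAF initiation among never-switchers (so some persons can serve as a
#' matched nonswitcher and later switch, exercising the reclassification
#' rule). Exposure histories, dispensings and the affected eGFR labs are
#' rewritten consistently: the true effect applies only while on TAF.
#' With both deviation rates zero the cohort is returned unchanged.
#'
#' @param cohort an `ehr_cohort` from [simulate_cohort()]
#' @param truth the [simulation_truth()] used to generate it
#' @return an updated `ehr_cohort`
#' @export
inject_deviations <- function(cohort, truth) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  rates <- truth$deviation_rates
  if (all(rates == 0)) return(cohort)
  frame <- attr(cohort, "latent")
  n <- nrow(frame$persons)
  set.seed(sub_seed(truth$seed, 7L))

  sw <- frame$switch_date
  if (rates["switch_back"] > 0) {
    has_sw <- !is.na(sw)
    tb <- stats::rexp(n, rates["switch_back"])
    back <- sw + round(tb * 365.25)
    back[!has_sw | back >= frame$end_fu] <- NA
    frame$switch_back <- as_date(back)
  }
  if (rates["late_switch"] > 0) {
    never <- is.na(sw)
    tl <- stats::rexp(n, rates["late_switch"])
    s0 <- pmax(as.Date("2019-10-01"), frame$persons$first_tdf_dispense + 30)
    late <- s0 + round(tl * 365.25)
    ok <- never & late < frame$end_fu & s0 < frame$end_fu
    frame$switch_date[ok] <- late[ok]
  }
  out <- emit_tables(frame, truth)
  out$manifest <- cohort$manifest
  out
}

#' Write a cohort's tables and manifest to a directory
#'
#' Emits `persons.csv`, `dispensings.csv`, `labs.csv`, `weights.csv`,
#' `comorbidities.csv` (ISO-8601 dates, header row) and `manifest.json`.
#'
#' @param cohort an `ehr_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("persons", "dispensings", "labs", "weights", "comorbidities")) {
    utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(cohort$manifest)) {
    jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read cohort tables from a directory
#'
#' Counterpart of [write_cohort()]; parses dates and restores factor levels.
#'
#' @param dir directory containing the five cohort csv files
#' @return an `ehr_cohort` (without latent state)
#' @export
read_cohort <- function(dir) {
  rd <- function(nm) utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                     stringsAsFactors = FALSE)
  persons <- rd("persons")
  persons$sex <- factor(persons$sex, levels = SEX_LEVELS)
  persons$race_ethnicity <- factor(persons$race_ethnicity, levels = RACE_LEVELS)
  persons$insurance <- factor(persons$insurance, levels = INSURANCE_LEVELS)
  for (col in c("first_tdf_dispense", "disenrollment_date")) {
    persons[[col]] <- as.Date(persons[[col]])
  }
  dispensings <- rd("dispensings"); dispensings$date <- as.Date(dispensings$date)
  labs <- rd("labs"); labs$date <- as.Date(labs$date)
  weights <- rd("weights"); weights$date <- as.Date(weights$date)
  comorbidities <- rd("comorbidities")
  comorbidities$onset_date <- as.Date(comorbidities$onset_date)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  }
  structure(list(persons = persons, dispensings = dispensings, labs = labs,
                 weights = weights, comorbidities = comorbidities,
                 manifest = manifest),
            class = "ehr_cohort")
}
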