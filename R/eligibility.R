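#' Switch-eligible dates from dispensing history
#'
#' A person becomes switch-eligible on the later of (a) the day after they
#' have accumulated `tdf_days` (default 183, i.e. six months) of TDF days
#' supplied — gaps between fills do not reset the count — and (b) the policy
#' date on which TAF became available for PrEP (2019-10-01). Absent if the
#' supply threshold is never reached.
#'
#' @param dispensings data.frame `person_id`, `date`, `drug`, `days_supplied`
#' @param policy_date availability date of the alternative regimen
#' @param tdf_days cumulative days-supplied threshold
#' @return data.frame `person_id`, `tdf_days_reached`, `switch_eligible_date`
#' @export
compute_switch_eligible_date <- function(dispensings,
                                         policy_date = as.Date("2019-10-01"),
                                         tdf_days = 183) {
  stopifnot(all(c("person_id", "date", "drug", "days_supplied") %in%
                  names(dispensings)))
  if (any(dispensings$days_supplied <= 0)) {
    stop("days_supplied must be positive")
  }
  tdf <- dispensings[dispensings$drug == "TDF", , drop = FALSE]
  ids <- sort(unique(dispensings$person_id))
  reach <- rep(as.Date(NA), length(ids))
  if (nrow(tdf)) {
    tdf <- tdf[order(tdf$person_id, tdf$date), ]
    for (k in seq_along(ids)) {
      rows <- tdf[tdf$person_id == ids[k], , drop = FALSE]
      if (!nrow(rows)) next
      cum <- cumsum(rows$days_supplied)
      j <- which(cum >= tdf_days)[1]
      if (is.na(j)) next
      prev <- if (j == 1) 0 else cum[j - 1]
      reach[k] <- rows$date[j] + (tdf_days - prev)
    }
  }
  eligible <- as_date(pmax(as.numeric(reach), as.numeric(policy_date)))
  eligible[is.na(reach)] <- NA
  data.frame(person_id = ids, tdf_days_reached = reach,
             switch_eligible_date = eligible, stringsAsFactors = FALSE)
}

#' Apply cohort exclusions
#'
#' Labels every person with exactly one exclusion reason:
#' `under_6mo_tdf_before_taf` (first TAF dispensed before the TDF supply
#' threshold was met), `baseline_ckd_or_lab_abnormality` (precomputed
#' baseline chronic-kidney-disease / abnormal-lab flag), `disenrolled`
#' (left the health plan — or never met the eligibility threshold inside
#' the study window — before becoming switch-eligible), or `none`
#' (included).
#'
#' @param persons persons table
#' @param dispensings dispensings table
#' @param eligibility output of [compute_switch_eligible_date()]
#' @param study_end administrative study end date
#' @param log optional pipeline log
#' @return data.frame `person_id`, `switch_eligible_date`, `included`,
#'   `exclusion_reason`
#' @export
apply_exclusions <- function(persons, dispensings, eligibility,
                             study_end = as.Date("2022-06-30"), log = NULL) {
  m <- merge(persons[, c("person_id", "disenrollment_date",
                         "baseline_ckd_flag")],
             eligibility, by = "person_id", all.x = TRUE)
  taf <- dispensings[dispensings$drug == "TAF", , drop = FALSE]
  first_taf <- tapply(as.numeric(taf$date), taf$person_id, min)
  m$first_taf <- as_date(first_taf[as.character(m$person_id)])

  reason <- rep("none", nrow(m))
  elig_ok <- !is.na(m$switch_eligible_date) &
    m$switch_eligible_date <= study_end &
    (is.na(m$disenrollment_date) |
       m$disenrollment_date > m$switch_eligible_date)
  # precedence: early TAF, then baseline CKD, then failure to stay
  # enrolled/eligible inside the window
  reason[!elig_ok] <- "disenrolled"
  reason[m$baseline_ckd_flag] <- "baseline_ckd_or_lab_abnormality"
  early_taf <- !is.na(m$first_taf) &
    (is.na(m$tdf_days_reached) | m$first_taf < m$tdf_days_reached)
  reason[early_taf] <- "under_6mo_tdf_before_taf"

  out <- data.frame(
    person_id = m$person_id,
    switch_eligible_date = m$switch_eligible_date,
    included = reason == "none",
    exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
  out$switch_eligible_date[!out$included] <- NA
  if (!is.null(log)) {
    tab <- table(out$exclusion_reason)
    for (r in names(tab)) log_msg(log, sprintf("exclusion %s: %d", r, tab[[r]]))
    log_count(log, "included_switch_eligible", sum(out$included))
  }
  out
}

#' Comorbidity status at a date
#'
#' Absorbing indicator: a condition is present at `date` iff its onset is on
#' or before `date`.
#'
#' @param comorbidities table `person_id`, `condition`, `onset_date`
#' @param person_ids persons to evaluate
#' @param date evaluation date (scalar or one per person)
#' @return logical matrix persons x conditions
#' @export
comorbidity_status_at <- function(comorbidities, person_ids, date) {
  date <- rep_len(as.Date(date), length(person_ids))
  out <- matrix(FALSE, length(person_ids), length(COMORBIDITIES),
                dimnames = list(NULL, COMORBIDITIES))
  for (cond in COMORBIDITIES) {
    sub <- comorbidities[comorbidities$condition == cond, , drop = FALSE]
    onset <- rep(as.Date(NA), length(person_ids))
    idx <- match(person_ids, sub$person_id)
    onset[!is.na(idx)] <- sub$onset_date[idx[!is.na(idx)]]
    out[, cond] <- !is.na(onset) & onset <= date
  }
  out
}

#' Assemble covariate profiles at the switch-eligible date
#'
#' Builds the time-invariant covariate set of the switch-propensity model:
#' demographics, insurance, smoking, year eligibility was met, and weight and
#' eGFR "at" the eligible date, taken as the most recent measurement on or
#' before that date within `lookback_days` (missing otherwise, to be filled
#' by [impute_covariates_rf()]). Time-varying comorbidity status is carried
#' separately through onset dates (see [comorbidity_status_at()]).
#'
#' @param persons persons table
#' @param eligibility output of [apply_exclusions()] (included rows are used)
#' @param egfr eGFR table from [egfr_from_labs()]
#' @param weights weights table
#' @param comorbidities comorbidity onsets table
#' @param lookback_days measurement lookback window
#' @return data.frame, one row per included person
#' @export
build_covariate_profiles <- function(persons, eligibility, egfr, weights,
                                     comorbidities, lookback_days = 365) {
  inc <- eligibility[eligibility$included, , drop = FALSE]
  p <- persons[match(inc$person_id, persons$person_id), , drop = FALSE]
  ed <- inc$switch_eligible_date

  egfr_s <- split(egfr[, c("date", "egfr")], egfr$person_id)
  wt_s <- split(weights[, c("date", "kg")], weights$person_id)
  at_date <- function(splt, valcol, id, at) {
    s <- splt[[as.character(id)]]
    if (is.null(s)) return(NA_real_)
    last_value_before(s$date, s[[valcol]], at, lookback_days)
  }
  egfr_at <- vapply(seq_len(nrow(inc)), function(k)
    at_date(egfr_s, "egfr", inc$person_id[k], ed[k]), numeric(1))
  wt_at <- vapply(seq_len(nrow(inc)), function(k)
    at_date(wt_s, "kg", inc$person_id[k], ed[k]), numeric(1))
  com <- comorbidity_status_at(comorbidities, inc$person_id, ed)

  data.frame(
    person_id = inc$person_id,
    switch_eligible_date = ed,
    age_at_tdf_init = p$age_at_tdf_init,
    sex = p$sex,
    male = p$sex == "male",
    race_ethnicity = p$race_ethnicity,
    insurance = p$insurance,
    ever_smoker = p$ever_smoker,
    year_eligibility_met = as.integer(format(ed, "%Y")),
    weight_at_eligible = wt_at,
    egfr_at_eligible = egfr_at,
    duration_tdf_to_eligible = as.numeric(ed - p$first_tdf_dispense),
    diabetes_at_eligible = com[, "diabetes"],
    dyslipidemia_at_eligible = com[, "dyslipidemia"],
    hypertension_at_eligible = com[, "hypertension"],
    stringsAsFactors = FALSE
  )
}

#' Single random-forest imputation of covariates
#'
#' Fills missing covariate cells with one random-forest imputation:
#' missing cells are initialized at the observed median (numeric) or mode
#' (categorical), then columns are revisited in order of increasing
#' missingness for a fixed number of sweeps, each fitting a random forest of
#' the target column on all other covariates over its observed rows and
#' predicting the missing ones. Originally observed cells are never changed;
#' the imputed-cell mask is attached as attribute `"imputed_mask"`.
#'
#' @param covariates data.frame; id/date columns are passed through untouched
#' @param seed integer seed (single imputation is deterministic given it)
#' @param exclude columns never imputed nor used as predictors
#' @param sweeps number of refinement passes over the incomplete columns
#' @param ntree trees per forest
#' @return completed data.frame with attribute `imputed_mask`
#' @export
impute_covariates_rf <- function(covariates, seed = 1L,
                                 exclude = c("person_id",
                                             "switch_eligible_date"),
                                 sweeps = 3, ntree = 100) {
  dat <- covariates
  work_cols <- setdiff(names(dat), exclude)
  work <- dat[work_cols]
  for (j in names(work)) {
    if (is.character(work[[j]])) work[[j]] <- factor(work[[j]])
    if (all(is.na(work[[j]]))) {
      stop(sprintf("configuration error: covariate '%s' is entirely missing", j))
    }
  }
  mask <- is.na(work)
  if (!any(mask)) {
    attr(dat, "imputed_mask") <- mask
    return(dat)
  }
  set.seed(seed)
  # initialize
  for (j in names(work)) {
    miss <- is.na(work[[j]])
    if (!any(miss)) next
    obs <- work[[j]][!miss]
    fill <- if (is.numeric(obs)) stats::median(obs)
    else if (is.logical(obs)) (mean(obs) >= 0.5)
    else names(which.max(table(obs)))
    work[[j]][miss] <- fill
  }
  incomplete <- names(work)[colSums(mask) > 0]
  incomplete <- incomplete[order(colSums(mask)[incomplete])]
  for (s in seq_len(sweeps)) {
    for (j in incomplete) {
      miss <- mask[, j]
      y <- work[[j]]
      x <- work[setdiff(names(work), j)]
      yfit <- if (is.logical(y)) factor(y) else y
      fit <- randomForest::randomForest(x = x[!miss, , drop = FALSE],
                                        y = yfit[!miss], ntree = ntree)
      pred <- stats::predict(fit, x[miss, , drop = FALSE])
      if (is.logical(y)) pred <- as.logical(as.character(pred))
      work[[j]][miss] <- pred
    }
  }
  dat[work_cols] <- work
  attr(dat, "imputed_mask") <- mask
  dat
}
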