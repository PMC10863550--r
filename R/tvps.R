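#' Counting-process layout for the switch-hazard model
#'
#' One or more (tstart, tstop] intervals per included person on the
#' time-since-eligibility scale, split wherever a comorbidity onset changes
#' a time-varying covariate; the final interval carries the switch event
#' indicator. Persons are censored at disenrollment or the study end.
#'
#' @param profiles covariate profiles from [build_covariate_profiles()]
#'   (after imputation)
#' @param comorbidities comorbidity onsets table
#' @param switch_dates data.frame `person_id`, `switch_date` (NA = never)
#' @param persons persons table
#' @param study_end study end date
#' @return data.frame in counting-process layout
#' @export
build_risk_intervals <- function(profiles, comorbidities, switch_dates,
                                 persons, study_end = as.Date("2022-06-30")) {
  sw <- switch_dates$switch_date[match(profiles$person_id,
                                       switch_dates$person_id)]
  dis <- persons$disenrollment_date[match(profiles$person_id,
                                          persons$person_id)]
  rows <- vector("list", nrow(profiles))
  for (k in seq_len(nrow(profiles))) {
    origin <- profiles$switch_eligible_date[k]
    end <- min(study_end, if (!is.na(dis[k])) dis[k] else study_end,
               if (!is.na(sw[k])) sw[k] else study_end)
    event <- !is.na(sw[k]) && sw[k] <= end & sw[k] >= origin
    t_end <- max(as.numeric(end - origin), 0.5)  # same-day switch: half-day
    onset <- comorbidities[comorbidities$person_id == profiles$person_id[k], ,
                           drop = FALSE]
    cuts <- sort(unique(as.numeric(onset$onset_date - origin)))
    cuts <- cuts[cuts > 0 & cuts < t_end]
    starts <- c(0, cuts)
    stops <- c(cuts, t_end)
    mid_dates <- origin + starts
    com <- comorbidity_status_at(onset, rep(profiles$person_id[k],
                                            length(starts)), mid_dates)
    rows[[k]] <- data.frame(
      person_id = profiles$person_id[k],
      tstart = starts, tstop = stops,
      event = c(rep(FALSE, length(starts) - 1), event),
      diabetes = com[, "diabetes"],
      dyslipidemia = com[, "dyslipidemia"],
      hypertension = com[, "hypertension"],
      stringsAsFactors = FALSE
    )
  }
  cp <- do.call(rbind, rows)
  ti <- profiles[match(cp$person_id, profiles$person_id),
                 c("age_at_tdf_init", "male", "race_ethnicity", "insurance",
                   "ever_smoker", "year_eligibility_met",
                   "weight_at_eligible", "egfr_at_eligible")]
  out <- cbind(cp, ti)
  rownames(out) <- NULL
  out
}

TVPS_COVARIATES <- c("age_at_tdf_init", "race_ethnicity", "male",
                     "ever_smoker", "insurance", "year_eligibility_met",
                     "weight_at_eligible", "egfr_at_eligible",
                     "diabetes", "dyslipidemia", "hypertension")

#' Fit the time-varying propensity-score (extended Cox) model
#'
#' Extended Cox model of the hazard of switching TDF to TAF on the
#' time-since-eligibility scale, with time-invariant covariates (age, race
#' and ethnicity, male, ever smoking, insurance, year eligibility met,
#' weight and eGFR at the switch-eligible date) and time-varying comorbidity
#' status (diabetes, dyslipidemia, hypertension). The fitted linear
#' predictor, evaluated with covariate values current at a given date, is
#' the risk score used for matching; the baseline hazard cancels out of
#' score differences.
#'
#' @param cp counting-process data from [build_risk_intervals()]
#' @param covariates covariate names to include (defaults to the full list)
#' @param log optional pipeline log
#' @return an object of class `tvps_model`
#' @export
fit_tvps_model <- function(cp, covariates = TVPS_COVARIATES, log = NULL) {
  if (sum(cp$event) == 0) {
    stop("no switch events: the switch-hazard model is unidentifiable")
  }
  keep <- character(0)
  for (v in covariates) {
    x <- cp[[v]]
    nlev <- if (is.factor(x)) sum(table(droplevels(x)) > 0) else
      length(unique(x[!is.na(x)]))
    if (nlev < 2) {
      warning(sprintf("covariate '%s' has zero variance; dropped from the TV-PS model", v))
      log_msg(log, sprintf("tvps: dropped zero-variance covariate '%s'", v))
    } else keep <- c(keep, v)
  }
  if (!length(keep)) stop("no usable covariates for the TV-PS model")
  fml <- stats::as.formula(paste(
    "survival::Surv(tstart, tstop, event) ~", paste(keep, collapse = " + ")))
  fit <- survival::coxph(fml, data = cp, ties = "efron",
                         model = FALSE, x = FALSE, y = FALSE)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("TV-PS model did not converge / separation for: %s",
                 paste(bad, collapse = ", ")))
  }
  conv <- list(iter = fit$iter, loglik = fit$loglik,
               score_test = fit$score)
  log_msg(log, sprintf("tvps: %d events, %d covariates, loglik %.2f",
                       sum(cp$event), length(keep), fit$loglik[2]))
  structure(list(fit = fit, covariates = keep,
                 xlevels = fit$xlevels, convergence = conv),
            class = "tvps_model")
}

#' @export
print.tvps_model <- function(x, ...) {
  cat("Time-varying propensity score model (extended Cox)\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' Risk scores at a calendar date
#'
#' Linear predictor of the TV-PS model for the given persons with
#' time-varying comorbidity status evaluated at `date`. Scores use only
#' information dated on or before `date` (comorbidity onsets after it do not
#' contribute), so matching never conditions on the future.
#'
#' @param model a `tvps_model`
#' @param profiles covariate profiles (imputed)
#' @param comorbidities comorbidity onsets table
#' @param person_ids persons to score
#' @param date evaluation date
#' @return numeric vector of scores (log-hazard scale, centered by coxph)
#' @export
tvps_score <- function(model, profiles, comorbidities, person_ids, date) {
  idx <- match(person_ids, profiles$person_id)
  if (anyNA(idx)) stop("unknown person_id in tvps_score")
  nd <- profiles[idx, , drop = FALSE]
  com <- comorbidity_status_at(comorbidities, person_ids, date)
  nd$diabetes <- com[, "diabetes"]
  nd$dyslipidemia <- com[, "dyslipidemia"]
  nd$hypertension <- com[, "hypertension"]
  tt <- stats::delete.response(stats::terms(model$fit))
  mm <- stats::model.matrix(tt, data = nd, xlev = model$xlevels)
  beta <- stats::coef(model$fit)
  as.numeric(mm[, names(beta), drop = FALSE] %*% beta)
}
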