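#' Censor follow-up at the first treatment deviation (SA1)
#'
#' Restricts the outcome dataset to the time each person was adherent to
#' their index-date exposure: eGFR rows dated after a switcher's first TDF
#' re-dispense, or after a nonswitcher's first TAF dispense, are removed.
#' Dispensing gaps alone are not deviations. Never adds rows; with no
#' deviations the dataset is returned unchanged.
#'
#' @param dataset an [build_outcome_dataset()] result
#' @param dispensings dispensings table
#' @param log optional pipeline log
#' @return censored `outcome_dataset`; attribute `"deviation_dates"` maps
#'   person to first deviation date
#' @export
censor_at_deviation <- function(dataset, dispensings, log = NULL) {
  idx_date <- dataset$index_date[!duplicated(dataset$person_id)]
  names(idx_date) <- dataset$person_id[!duplicated(dataset$person_id)]
  arm <- dataset$arm[!duplicated(dataset$person_id)]
  names(arm) <- names(idx_date)

  dev <- rep(as.Date(NA), length(idx_date))
  names(dev) <- names(idx_date)
  for (pid in names(idx_date)) {
    d <- dispensings[dispensings$person_id == as.integer(pid), , drop = FALSE]
    bad_drug <- if (arm[pid] == 1) "TDF" else "TAF"
    hit <- d$date[d$drug == bad_drug & d$date > idx_date[pid]]
    if (length(hit)) dev[pid] <- min(hit)
  }
  n_dev <- sum(!is.na(dev))
  log_msg(log, sprintf("sa1: %d persons with a treatment deviation", n_dev))
  keep <- rep(TRUE, nrow(dataset))
  for (pid in names(dev)[!is.na(dev)]) {
    keep[dataset$person_id == as.integer(pid) &
           dataset$date > dev[pid]] <- FALSE
  }
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  log_count(log, "sa1_rows", nrow(out))
  attr(out, "deviation_dates") <- dev[!is.na(dev)]
  class(out) <- class(dataset)
  out
}

#' Inverse-probability-of-missingness weights (SA2)
#'
#' Logistic regression of inclusion in the complete-case analysis (having
#' at least one post-index eGFR) on the baseline covariates, giving
#' stabilized weights marginal P(inclusion) / fitted P(inclusion | x) for
#' the included persons. Extreme weights are truncated at configurable
#' percentiles of the included persons' weights.
#'
#' @param cohort data.frame with one row per matched person: `person_id`,
#'   `included` (logical) and the baseline covariate columns
#' @param covariates covariate names for the inclusion model
#' @param truncate lower/upper truncation percentiles (NULL to disable)
#' @param log optional pipeline log
#' @return data.frame `person_id`, `included`, `p_include`,
#'   `stabilized_weight` (NA for non-included persons)
#' @export
fit_missingness_weights <- function(cohort,
                                    covariates = c("arm", BASELINE_TERMS),
                                    truncate = c(0.01, 0.99), log = NULL) {
  covariates <- intersect(covariates, names(cohort))
  fml <- stats::as.formula(paste("included ~",
                                 paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, data = cohort,
                                     family = stats::binomial()))
  p <- stats::fitted(fit)
  # perfect separation: the model classifies inclusion exactly, or an
  # included person has essentially zero fitted inclusion probability
  # (their weight would explode). Fitted probabilities near 1 are benign —
  # the stabilized weight just approaches the marginal rate.
  if (fit$deviance < 1e-6 || any(p[cohort$included] < 1e-8)) {
    stop("perfect separation in the missingness-weight model")
  }
  extreme <- p > 1 - 1e-8
  if (any(extreme)) {
    # quasi-separation on a small subgroup (e.g. a rare factor level)
    p <- pmin(p, 1 - 1e-8)
    log_msg(log, sprintf(
      "sa2: %d fitted inclusion probabilities at the upper boundary; clamped",
      sum(extreme)))
  }
  marg <- mean(cohort$included)
  w <- ifelse(cohort$included, marg / p, NA_real_)
  if (!is.null(truncate)) {
    q <- stats::quantile(w, truncate, na.rm = TRUE)
    n_trunc <- sum(w < q[1] | w > q[2], na.rm = TRUE)
    if (n_trunc > 0) {
      log_msg(log, sprintf("sa2: truncated %d weights to [%.3f, %.3f]",
                           n_trunc, q[1], q[2]))
    }
    w <- pmin(pmax(w, q[1]), q[2])
  }
  log_msg(log, sprintf("sa2: mean stabilized weight %.3f among included",
                       mean(w, na.rm = TRUE)))
  data.frame(person_id = cohort$person_id, included = cohort$included,
             p_include = p, stabilized_weight = w, stringsAsFactors = FALSE)
}

#' Missingness-weighted Bayesian outcome model (SA2)
#'
#' The main Bayesian longitudinal model with each person's likelihood
#' contribution scaled by their stabilized
#' inverse-probability-of-missingness weight; ATT summarization is
#' unchanged. With all weights equal to 1 this reproduces the main
#' analysis exactly under a paired seed.
#'
#' @param dataset an [build_outcome_dataset()] result
#' @param weights output of [fit_missingness_weights()]
#' @param spec an [outcome_model_spec()]
#' @param log optional pipeline log
#' @return an `outcome_fit`
#' @export
weighted_outcome_model <- function(dataset, weights,
                                   spec = outcome_model_spec(), log = NULL) {
  wtab <- weights[!is.na(weights$stabilized_weight),
                  c("person_id", "stabilized_weight")]
  fit_outcome_model(dataset, spec, obs_weights = wtab, log = log)
}

#' Rubin's rules pooling
#'
#' Combines per-imputation estimates: pooled estimate is the mean, total
#' variance is within + (1 + 1/m) x between, and the confidence interval
#' uses the Barnard-Rubin small-sample degrees of freedom.
#'
#' @param estimates per-imputation point estimates
#' @param variances per-imputation squared standard errors
#' @param conf confidence level
#' @return list: `estimate`, `se`, `lo`, `hi`, `within`, `between`,
#'   `total_var`, `df`, `m`
#' @export
rubin_pool <- function(estimates, variances, conf = 0.95) {
  m <- length(estimates)
  stopifnot(m >= 1, length(variances) == m)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- if (m > 1) stats::var(estimates) else 0
  t_var <- ubar + (1 + 1 / m) * b
  df <- if (b > 0 && m > 1) {
    (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2
  } else Inf
  a <- 1 - (1 - conf) / 2
  crit <- if (is.finite(df)) stats::qt(a, df) else stats::qnorm(a)
  list(estimate = qbar, se = sqrt(t_var),
       lo = qbar - crit * sqrt(t_var), hi = qbar + crit * sqrt(t_var),
       within = ubar, between = b, total_var = t_var, df = df, m = m)
}

# One cycle of chained-equation imputation over the columns of `dat` that
# have missing cells (mask). Continuous columns use predictive mean
# matching (5 donors), logical columns a logistic draw. Factor columns must
# be complete.
mice_cycle <- function(dat, mask, donors = 5) {
  for (j in colnames(mask)[colSums(mask) > 0]) {
    miss <- mask[, j]
    rhs <- setdiff(colnames(dat), j)
    fml <- stats::as.formula(paste("`", j, "` ~ ", paste0("`", rhs, "`",
                                                          collapse = " + "),
                                   sep = ""))
    if (is.logical(dat[[j]])) {
      fit <- suppressWarnings(stats::glm(fml, data = dat[!miss, , drop = FALSE],
                                         family = stats::binomial()))
      pr <- stats::predict(fit, dat[miss, , drop = FALSE], type = "response")
      dat[[j]][miss] <- stats::runif(sum(miss)) < pr
    } else {
      fit <- stats::lm(fml, data = dat[!miss, , drop = FALSE])
      # Bayesian-flavored PMM: perturb coefficients, then match each
      # missing cell to a donor among nearest observed predictions
      beta <- stats::coef(fit)
      V <- stats::vcov(fit)
      ok <- !is.na(beta)
      bstar <- beta
      bstar[ok] <- beta[ok] + as.numeric(
        crossprod(chol(V[ok, ok] + diag(1e-10, sum(ok))),
                  stats::rnorm(sum(ok))))
      mm_all <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                                    dat)
      pred <- as.numeric(mm_all[, names(beta)[ok], drop = FALSE] %*% bstar[ok])
      obs_idx <- which(!miss)
      for (i in which(miss)) {
        dist <- abs(pred[obs_idx] - pred[i])
        cand <- obs_idx[order(dist)[seq_len(min(donors, length(obs_idx)))]]
        dat[[j]][i] <- dat[[j]][cand[sample.int(length(cand), 1)]]
      }
    }
  }
  dat
}

#' Multiple imputation with per-timepoint regressions (SA3)
#'
#' Bins each person's follow-up eGFR to the nearest a priori timepoint
#' within a +/-6-week window (closest observation wins; seeded tie-break),
#' builds a wide person x timepoint layout, imputes missing outcomes and
#' covariates with chained equations (predictive mean matching for
#' continuous, logistic for binary; `cycles` sweeps), and for each
#' imputation and timepoint fits an ordinary linear regression of eGFR on
#' switch status and the baseline covariates. The switch coefficients are
#' pooled across imputations by Rubin's rules.
#'
#' @param indexed indexed cohort from [assign_index_dates()] (all matched
#'   persons, including those without post-index eGFR)
#' @param dataset_all long eGFR data for the matched persons: the result of
#'   [build_outcome_dataset()] run on the same cohort (its complete-case
#'   exclusions are irrelevant here; rows are re-binned), or any data.frame
#'   with the same columns
#' @param m number of imputations
#' @param cycles chained-equation sweeps per imputation
#' @param timepoints a priori months
#' @param window_days half-width of the binning window
#' @param seed seed for imputation noise and tie-breaks
#' @param log optional pipeline log
#' @return data.frame of class `pooled_estimates`: per timepoint the pooled
#'   switch-vs-nonswitch difference, 95% CI, and variance components
#' @export
mi_per_timepoint_regression <- function(indexed, dataset_all, m = 10,
                                        cycles = 10,
                                        timepoints = c(0.5, 3, 6, 9, 12, 15, 18),
                                        window_days = 42, seed = 1L,
                                        log = NULL) {
  set.seed(sub_seed(seed, 31L))
  not_covered <- setdiff(indexed$person_id, dataset_all$person_id)
  if (length(not_covered)) {
    stop(sprintf("%d matched persons missing from the long eGFR data",
                 length(not_covered)))
  }
  base <- dataset_all[!duplicated(dataset_all$person_id),
                      c("person_id", "set_id", "arm", "age", "male",
                        "insurance", "race_ethnicity", "ever_smoker",
                        "weight_at_index", "egfr_at_index",
                        "egfr_at_eligible", "duration_tdf_to_eligible",
                        "hypertension_at_index")]
  window_months <- window_days / DAYS_PER_MONTH
  wide <- base
  for (tp in timepoints) {
    col <- paste0("egfr_m", tp)
    wide[[col]] <- NA_real_
    for (r in seq_len(nrow(wide))) {
      rows <- dataset_all[dataset_all$person_id == wide$person_id[r], ,
                          drop = FALSE]
      dist <- abs(rows$months_since_index - tp)
      ok <- !is.na(dist) & dist <= window_months
      if (any(ok)) {
        cand <- which(ok)
        best <- cand[order(dist[cand], stats::runif(length(cand)))][1]
        wide[[col]][r] <- rows$egfr[best]
      }
    }
  }
  out_cols <- paste0("egfr_m", timepoints)
  n_missing_out <- colSums(is.na(wide[out_cols]))
  log_msg(log, sprintf("sa3: missing outcomes per timepoint: %s",
                       paste(n_missing_out, collapse = "/")))

  imp_frame <- wide[, setdiff(names(wide), c("person_id", "set_id")),
                    drop = FALSE]
  mask <- is.na(imp_frame)
  covar_rhs <- c("arm", "age", "male", "insurance", "race_ethnicity",
                 "ever_smoker", "weight_at_index", "egfr_at_index",
                 "egfr_at_eligible", "duration_tdf_to_eligible",
                 "hypertension_at_index")

  results <- array(NA_real_, c(m, length(timepoints), 2),
                   dimnames = list(NULL, out_cols, c("est", "var")))
  for (imp in seq_len(m)) {
    dat <- imp_frame
    # initialize missing cells from the observed marginal
    for (j in colnames(mask)[colSums(mask) > 0]) {
      miss <- mask[, j]
      obs <- dat[[j]][!miss]
      if (!length(obs)) {
        stop(sprintf("sa3: no observed values at all for '%s'", j))
      }
      dat[[j]][miss] <- sample(obs, sum(miss), replace = TRUE)
    }
    for (cy in seq_len(cycles)) dat <- mice_cycle(dat, mask)
    for (k in seq_along(timepoints)) {
      fml <- stats::as.formula(paste(out_cols[k], "~",
                                     paste(covar_rhs, collapse = " + ")))
      fit <- stats::lm(fml, data = dat)
      sm <- summary(fit)$coefficients
      if (!"arm" %in% rownames(sm)) next
      results[imp, k, "est"] <- sm["arm", "Estimate"]
      results[imp, k, "var"] <- sm["arm", "Std. Error"]^2
    }
  }
  pooled <- lapply(seq_along(timepoints), function(k) {
    est <- results[, k, "est"]; v <- results[, k, "var"]
    if (all(is.na(est))) {
      return(data.frame(timepoint = timepoints[k], estimate = NA_real_,
                        lo = NA_real_, hi = NA_real_, within = NA_real_,
                        between = NA_real_, total_var = NA_real_, m = m,
                        available = FALSE))
    }
    pp <- rubin_pool(est[!is.na(est)], v[!is.na(est)])
    data.frame(timepoint = timepoints[k], estimate = pp$estimate,
               lo = pp$lo, hi = pp$hi, within = pp$within,
               between = pp$between, total_var = pp$total_var, m = pp$m,
               available = TRUE)
  })
  res <- do.call(rbind, pooled)
  class(res) <- c("pooled_estimates", "data.frame")
  res
}
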