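#' Assemble the longitudinal outcome dataset
#'
#' Long-format eGFR follow-up for the matched, indexed cohort: one row per
#' eGFR measurement from the index date (month 0 inclusive) to `max_months`.
#' Persons with no eGFR strictly after their index date are excluded (the
#' complete-case rule of the main analysis); sets left without both arms are
#' dropped. Baseline covariates follow the outcome-model specification:
#' age, male, insurance, race and ethnicity, smoking, weight and eGFR at
#' the index date, eGFR at the switch-eligible date, days from first TDF
#' dispense to the switch-eligible date, and hypertension status at index.
#' Weight/eGFR "at" a date is the most recent value on or before it within
#' `lookback_days`, falling back to the (imputed) eligible-date value.
#'
#' @param indexed indexed cohort from [assign_index_dates()]
#' @param egfr eGFR table from [egfr_from_labs()]
#' @param profiles imputed covariate profiles
#' @param weights weights table
#' @param comorbidities comorbidity onsets table
#' @param max_months follow-up cap in months (30.4375 days each)
#' @param lookback_days baseline measurement lookback
#' @param log optional pipeline log
#' @return data.frame of class `outcome_dataset`
#' @export
build_outcome_dataset <- function(indexed, egfr, profiles, weights,
                                  comorbidities, max_months = 18,
                                  lookback_days = 365, log = NULL) {
  prof <- profiles[match(indexed$person_id, profiles$person_id), ,
                   drop = FALSE]
  egfr_s <- split(egfr[, c("date", "egfr")], egfr$person_id)
  wt_s <- split(weights[, c("date", "kg")], weights$person_id)

  base <- indexed
  base$egfr_at_index <- NA_real_
  base$weight_at_index <- NA_real_
  rows <- vector("list", nrow(indexed))
  for (k in seq_len(nrow(indexed))) {
    pid <- indexed$person_id[k]
    idx <- indexed$index_date[k]
    e <- egfr_s[[as.character(pid)]]
    # prefer a measurement within the lookback window; otherwise take the
    # most recent earlier one (a stale but real value beats an imputed one)
    base$egfr_at_index[k] <- if (is.null(e)) NA_real_ else {
      v <- last_value_before(e$date, e$egfr, idx, lookback_days)
      if (is.na(v)) last_value_before(e$date, e$egfr, idx, Inf) else v
    }
    wtab <- wt_s[[as.character(pid)]]
    base$weight_at_index[k] <- if (is.null(wtab)) NA_real_ else {
      v <- last_value_before(wtab$date, wtab$kg, idx, lookback_days)
      if (is.na(v)) last_value_before(wtab$date, wtab$kg, idx, Inf) else v
    }
    if (!is.null(e)) {
      m <- as.numeric(e$date - idx) / DAYS_PER_MONTH
      keep <- m >= 0 & m <= max_months
      if (any(keep)) {
        rows[[k]] <- data.frame(person_id = pid, date = e$date[keep],
                                months_since_index = m[keep],
                                egfr = e$egfr[keep])
      }
    }
  }
  long <- do.call(rbind, rows)
  if (is.null(long) || !nrow(long)) stop("empty outcome dataset")

  # complete-case rule: at least one eGFR strictly after the index date
  has_fu <- tapply(long$months_since_index, long$person_id, function(m)
    any(m > 0))
  fu_ids <- as.integer(names(has_fu))[has_fu]
  dropped <- setdiff(indexed$person_id, fu_ids)
  log_msg(log, sprintf(
    "outcome: excluded %d persons with no follow-up eGFR after index",
    length(dropped)))

  base$egfr_at_index[is.na(base$egfr_at_index)] <-
    prof$egfr_at_eligible[is.na(base$egfr_at_index)]
  base$weight_at_index[is.na(base$weight_at_index)] <-
    prof$weight_at_eligible[is.na(base$weight_at_index)]
  htn <- comorbidity_status_at(comorbidities, indexed$person_id,
                               indexed$index_date)[, "hypertension"]

  covs <- data.frame(
    person_id = indexed$person_id,
    set_id = indexed$set_id,
    arm = as.integer(indexed$arm == "switcher"),
    index_date = indexed$index_date,
    age = prof$age_at_tdf_init,
    male = prof$male,
    insurance = prof$insurance,
    race_ethnicity = prof$race_ethnicity,
    ever_smoker = prof$ever_smoker,
    weight_at_index = base$weight_at_index,
    egfr_at_index = base$egfr_at_index,
    egfr_at_eligible = prof$egfr_at_eligible,
    duration_tdf_to_eligible = prof$duration_tdf_to_eligible,
    hypertension_at_index = htn,
    stringsAsFactors = FALSE
  )
  covs <- covs[covs$person_id %in% fu_ids, , drop = FALSE]
  # both arms must remain represented within a set
  arms_per_set <- tapply(covs$arm, covs$set_id, function(a)
    length(unique(a)))
  good_sets <- as.integer(names(arms_per_set))[arms_per_set == 2]
  lost <- setdiff(covs$set_id, good_sets)
  if (length(lost)) {
    log_msg(log, sprintf(
      "outcome: dropped %d sets missing an arm after follow-up exclusions",
      length(lost)))
  }
  covs <- covs[covs$set_id %in% good_sets, , drop = FALSE]

  out <- merge(covs, long, by = "person_id")
  out <- out[order(out$set_id, out$person_id, out$months_since_index), ]
  rownames(out) <- NULL
  log_count(log, "analyzable_switchers",
            length(unique(out$person_id[out$arm == 1])))
  log_count(log, "analyzable_nonswitchers",
            length(unique(out$person_id[out$arm == 0])))
  log_count(log, "outcome_rows", nrow(out))
  class(out) <- c("outcome_dataset", "data.frame")
  out
}

#' Outcome-model specification
#'
#' Fixed effects: switch status, age, male, insurance, race and ethnicity,
#' smoking, weight at index, eGFR at the switch-eligible date, duration from
#' first TDF dispense to the switch-eligible date, hypertension at index,
#' eGFR at index, and a natural cubic spline in months since index (boundary
#' knots at 0 and `max_months`); pairwise interactions among switch status,
#' eGFR at index, and every spline column. Random intercepts for person and
#' matched set. Priors are Gaussian(0, `sd_beta`^2) on standardized-scale
#' coefficients and half-Student-t(3, `halft_scale`) on the three SDs.
#'
#' @param spline_df spline degrees of freedom (internal knots at quantiles
#'   of the observed follow-up times)
#' @param max_months boundary of the time basis
#' @param interactions include the pairwise interaction block
#' @param chains,iter,warmup sampler settings (post-warmup draws per chain)
#' @param seed sampler seed
#' @param sd_beta,halft_scale prior scales (standardized response scale)
#' @param rhat_max largest split-R-hat tolerated before erroring
#' @return list of class `outcome_model_spec`
#' @export
outcome_model_spec <- function(spline_df = 4, max_months = 18,
                               interactions = TRUE, chains = 2, iter = 1000,
                               warmup = 500, seed = 1L, sd_beta = 10,
                               halft_scale = 1, rhat_max = 1.1) {
  structure(list(spline_df = spline_df, max_months = max_months,
                 interactions = interactions, chains = chains, iter = iter,
                 warmup = warmup, seed = seed, sd_beta = sd_beta,
                 halft_scale = halft_scale, rhat_max = rhat_max),
            class = "outcome_model_spec")
}

BASELINE_TERMS <- c("age", "male", "insurance", "race_ethnicity",
                    "ever_smoker", "weight_at_index", "egfr_at_eligible",
                    "duration_tdf_to_eligible", "hypertension_at_index",
                    "egfr_at_index")

# Fixed-effects design matrix on the original scale. `info` (from a fit)
# freezes spline knots and factor levels so new data are expanded
# identically; without it both are derived from `data`.
build_outcome_design <- function(data, spec, info = NULL) {
  if (is.null(info)) {
    m <- data$months_since_index
    kq <- if (spec$spline_df > 1) {
      stats::quantile(m, probs = seq_len(spec$spline_df - 1) /
                        spec$spline_df, names = FALSE)
    } else numeric(0)
    info <- list(
      knots = kq,
      boundary = c(0, spec$max_months),
      xlev = list(insurance = levels(factor(data$insurance)),
                  race_ethnicity = levels(factor(data$race_ethnicity)))
    )
  }
  B <- splines::ns(data$months_since_index, knots = info$knots,
                   Boundary.knots = info$boundary)
  colnames(B) <- paste0("time", seq_len(ncol(B)))
  fml <- stats::as.formula(paste("~", paste(c("arm", BASELINE_TERMS),
                                            collapse = " + ")))
  dd <- data
  dd$insurance <- factor(dd$insurance, levels = info$xlev$insurance)
  dd$race_ethnicity <- factor(dd$race_ethnicity,
                              levels = info$xlev$race_ethnicity)
  X0 <- stats::model.matrix(fml, dd)
  X <- cbind(X0, B)
  if (isTRUE(spec$interactions)) {
    inter <- cbind(
      arm_x_egfr_at_index = dd$arm * dd$egfr_at_index,
      dd$arm * B,
      dd$egfr_at_index * B
    )
    colnames(inter) <- c("arm_x_egfr_at_index",
                         paste0("arm_x_time", seq_len(ncol(B))),
                         paste0("egfr_at_index_x_time", seq_len(ncol(B))))
    X <- cbind(X, inter)
  }
  list(X = X, info = info)
}

#' Fit the Bayesian longitudinal outcome model
#'
#' Gaussian mixed model for eGFR over follow-up with random intercepts for
#' person and matched set, sampled by a blocked conjugate Gibbs sampler
#' (response and continuous predictors are standardized internally; draws
#' are stored on the standardized scale together with the transform).
#' Rank-deficient designs are repaired by dropping aliased columns with a
#' warning naming them; convergence is checked with split-R-hat and
#' effective sample size, and the fit errors rather than returning silently
#' if R-hat exceeds `spec$rhat_max`.
#'
#' @param dataset an [build_outcome_dataset()] result
#' @param spec an [outcome_model_spec()]
#' @param obs_weights optional per-person likelihood weights
#'   (data.frame `person_id`, `stabilized_weight`), used by the
#'   missingness-weighted sensitivity analysis
#' @param log optional pipeline log
#' @return object of class `outcome_fit`
#' @export
fit_outcome_model <- function(dataset, spec = outcome_model_spec(),
                              obs_weights = NULL, log = NULL) {
  if (!nrow(dataset)) stop("empty outcome dataset")
  des <- build_outcome_design(dataset, spec)
  X <- des$X

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning(sprintf("rank-deficient outcome design; dropping aliased terms: %s",
                    paste(aliased, collapse = ", ")))
    log_msg(log, sprintf("outcome: dropped aliased terms %s",
                         paste(aliased, collapse = ", ")))
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
  }

  # standardize: response and every non-intercept column with spread
  y <- dataset$egfr
  my <- mean(y); sy <- stats::sd(y)
  if (!is.finite(sy) || sy == 0) sy <- 1
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  names(ctr) <- names(scl) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    if (colnames(X)[j] == "(Intercept)") next
    s <- stats::sd(X[, j])
    if (is.finite(s) && s > 0) {
      ctr[j] <- mean(X[, j]); scl[j] <- s
    }
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ys <- (y - my) / sy

  w <- NULL
  if (!is.null(obs_weights)) {
    idx <- match(dataset$person_id, obs_weights$person_id)
    if (anyNA(idx)) stop("missing stabilized weight for a modeled person")
    w <- obs_weights$stabilized_weight[idx]
  }

  draws <- blmm_gibbs(ys, Xs, person = dataset$person_id,
                      set = dataset$set_id, weights = w,
                      chains = spec$chains, iter = spec$iter,
                      warmup = spec$warmup, seed = spec$seed,
                      sd_beta = spec$sd_beta,
                      halft_scale = spec$halft_scale)

  beta_by_chain <- lapply(draws$chains, `[[`, "beta")
  rhat <- vapply(seq_len(ncol(Xs)), function(j)
    split_rhat(vapply(beta_by_chain, function(b) b[, j],
                      numeric(spec$iter))), numeric(1))
  names(rhat) <- colnames(Xs)
  ess <- vapply(seq_len(ncol(Xs)), function(j)
    ess_basic(vapply(beta_by_chain, function(b) b[, j],
                     numeric(spec$iter))), numeric(1))
  names(ess) <- colnames(Xs)
  max_rhat <- max(rhat, na.rm = TRUE)
  log_msg(log, sprintf("outcome: max split-Rhat %.4f, min ESS %.0f",
                       max_rhat, min(ess)))
  if (is.finite(max_rhat) && max_rhat > spec$rhat_max) {
    stop(sprintf("outcome model failed to converge (max split-Rhat %.3f > %.3f)",
                 max_rhat, spec$rhat_max))
  }

  beta <- do.call(rbind, beta_by_chain)
  sigma <- do.call(rbind, lapply(draws$chains, `[[`, "sigma")) * sy

  structure(list(
    beta_std = beta, sigma = sigma,
    transform = list(my = my, sy = sy, ctr = ctr, scl = scl),
    design_info = des$info, spec = spec,
    kept_columns = colnames(Xs),
    diagnostics = list(rhat = rhat, ess = ess, max_rhat = max_rhat),
    data_columns = names(dataset),
    switcher_baseline = unique(dataset[dataset$arm == 1,
                                       c("person_id", "set_id", "arm", "age",
                                         "male", "insurance", "race_ethnicity",
                                         "ever_smoker", "weight_at_index",
                                         "egfr_at_index", "egfr_at_eligible",
                                         "duration_tdf_to_eligible",
                                         "hypertension_at_index")]),
    time_range = range(dataset$months_since_index),
    n_obs = nrow(dataset),
    n_persons = length(unique(dataset$person_id))
  ), class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian longitudinal eGFR model: %d obs, %d persons, %d draws\n",
    x$n_obs, x$n_persons, nrow(x$beta_std)))
  cat(sprintf("max split-Rhat %.4f\n", x$diagnostics$max_rhat))
  invisible(x)
}

# Posterior draws of mean eGFR for covariate rows `newdata` at fixed
# months/arm, random effects marginalized at zero. Returns draws x rows.
predict_egfr_draws <- function(fit, newdata) {
  des <- build_outcome_design(newdata, fit$spec, info = fit$design_info)
  X <- des$X[, fit$kept_columns, drop = FALSE]
  tr <- fit$transform
  Xs <- sweep(sweep(X, 2, tr$ctr[fit$kept_columns]), 2,
              tr$scl[fit$kept_columns], "/")
  tr$my + tr$sy * (fit$beta_std %*% t(Xs))
}

#' Counterfactual ATT summaries at the a priori timepoints
#'
#' For each posterior draw and timepoint, predicts mean eGFR for every
#' matched switcher's baseline covariate row under the switching
#' (`arm = 1`) and non-switching (`arm = 0`) scenarios with random effects
#' marginalized at zero, averages each scenario over switchers, and takes
#' the difference — the average treatment effect on the treated. Draws are
#' summarized as the posterior median, 95\% credible interval, probability
#' of direction, and the fraction inside the region of practical
#' equivalence.
#'
#' @param fit an [fit_outcome_model()] object
#' @param timepoints months after the index date (a priori list)
#' @param rope region of practical equivalence, eGFR units
#' @return data.frame of class `att_summary`; attribute `"draws"` holds the
#'   timepoint-wise ATT draw matrix
#' @export
compute_att <- function(fit, timepoints = c(0.5, 3, 6, 9, 12, 15, 18),
                        rope = c(-2, 2)) {
  sb <- fit$switcher_baseline
  if (!nrow(sb)) stop("no switchers in the fitted dataset")
  outside <- timepoints < fit$time_range[1] | timepoints > fit$time_range[2]
  if (any(outside)) {
    warning(sprintf(
      "timepoint(s) %s outside the observed time support; model extrapolation",
      paste(timepoints[outside], collapse = ", ")))
  }
  att_draws <- matrix(NA_real_, nrow(fit$beta_std), length(timepoints),
                      dimnames = list(NULL, paste0("m", timepoints)))
  for (k in seq_along(timepoints)) {
    nd1 <- sb; nd1$months_since_index <- timepoints[k]; nd1$arm <- 1L
    nd0 <- nd1; nd0$arm <- 0L
    p1 <- predict_egfr_draws(fit, nd1)
    p0 <- predict_egfr_draws(fit, nd0)
    att_draws[, k] <- rowMeans(p1) - rowMeans(p0)
  }
  res <- data.frame(
    timepoint = timepoints,
    median_diff = apply(att_draws, 2, stats::median),
    cri_lo = apply(att_draws, 2, stats::quantile, 0.025),
    cri_hi = apply(att_draws, 2, stats::quantile, 0.975),
    pdi = apply(att_draws, 2, probability_of_direction),
    rope_fraction = apply(att_draws, 2, rope_fraction, bounds = rope),
    n_draws = nrow(att_draws),
    row.names = NULL
  )
  attr(res, "draws") <- att_draws
  class(res) <- c("att_summary", "data.frame")
  res
}

#' Probability of direction
#'
#' Fraction of posterior draws of a difference that are positive (here:
#' favoring a higher eGFR under switching).
#'
#' @param draws numeric vector of posterior draws
#' @return fraction in `[0, 1]`
#' @export
probability_of_direction <- function(draws) {
  if (!length(draws)) stop("empty draw set")
  mean(draws > 0)
}

#' Fraction of draws inside the region of practical equivalence
#'
#' The ROPE for eGFR differences is set a priori at +/-2 eGFR units:
#' differences inside it are considered practically equivalent to no
#' effect.
#'
#' @param draws numeric vector of posterior draws
#' @param bounds lower/upper ROPE bounds (inclusive)
#' @return fraction in `[0, 1]`
#' @export
rope_fraction <- function(draws, bounds = c(-2, 2)) {
  if (!length(draws)) stop("empty draw set")
  if (bounds[1] >= bounds[2]) stop("reversed ROPE bounds")
  mean(draws >= bounds[1] & draws <= bounds[2])
}
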