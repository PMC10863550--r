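test_that("adherence censoring removes exactly the post-deviation rows", {
  ds <- toy_outcome_dataset(n_sets = 4, controls_per_set = 1, effect = 0,
                            resid_sd = 1, seed = 21, n_visits = 6)
  idx <- as.Date("2020-06-01")
  # no deviations: identity
  disp0 <- data.frame(person_id = unique(ds$person_id), date = idx - 30,
                      drug = "TDF", days_supplied = 30L)
  out0 <- censor_at_deviation(ds, disp0)
  expect_equal(nrow(out0), nrow(ds))

  # nonswitcher (person 2) starts TAF at month 7: later rows removed
  m7 <- idx + round(7 * 30.4375)
  m4 <- idx + round(4 * 30.4375)
  disp <- rbind(disp0,
                data.frame(person_id = 2, date = m7, drug = "TAF",
                           days_supplied = 30L),
                # switcher (person 1) back on TDF at month 4
                data.frame(person_id = 1, date = m4, drug = "TDF",
                           days_supplied = 30L))
  out <- censor_at_deviation(ds, disp)
  expect_true(all(out$date[out$person_id == 2] <= m7))
  expect_true(all(out$date[out$person_id == 1] <= m4))
  dropped2 <- ds$person_id == 2 & ds$date > m7
  expect_equal(sum(out$person_id == 2),
               sum(ds$person_id == 2) - sum(dropped2))
  # SA1 never adds rows: subset of the main dataset
  expect_true(nrow(out) <= nrow(ds))
  key <- function(d) paste(d$person_id, d$date, d$egfr)
  expect_true(all(key(out) %in% key(ds)))
  # untreated persons untouched
  expect_equal(sum(out$person_id == 3), sum(ds$person_id == 3))
})

test_that("missingness weights equal the closed-form ratio on a saturated binary covariate", {
  # inclusion depends only on sex: P(incl|male)=3/4, P(incl|female)=1/4
  cohort <- data.frame(
    person_id = 1:8,
    included = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    male = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  w <- fit_missingness_weights(cohort, covariates = "male",
                               truncate = NULL)
  marg <- 4 / 8
  expect_equal(w$stabilized_weight[cohort$included & cohort$male],
               rep(marg / (3 / 4), 3), tolerance = 1e-6)
  expect_equal(w$stabilized_weight[cohort$included & !cohort$male],
               marg / (1 / 4), tolerance = 1e-6)
  expect_true(all(is.na(w$stabilized_weight[!cohort$included])))
})

test_that("MCAR inclusion gives weights near one with mean one", {
  set.seed(31)
  n <- 500
  cohort <- data.frame(
    person_id = seq_len(n),
    included = runif(n) < 0.7,
    age = rnorm(n, 40, 10), male = runif(n) < 0.9,
    weight_at_index = rnorm(n, 85, 15))
  w <- fit_missingness_weights(cohort,
                               covariates = c("age", "male",
                                              "weight_at_index"),
                               truncate = NULL)
  ww <- w$stabilized_weight[w$included]
  expect_lt(max(abs(ww - 1)), 0.2)
  expect_lt(abs(mean(ww) - 1), 0.05)
  expect_true(all(ww > 0))
})

test_that("perfect separation in the inclusion model errors", {
  cohort <- data.frame(person_id = 1:40,
                       included = rep(c(TRUE, FALSE), each = 20),
                       x = rep(c(1, 0), each = 20))
  expect_error(suppressWarnings(
    fit_missingness_weights(cohort, covariates = "x", truncate = NULL)),
    "separation")
})

test_that("unit weights reproduce the unweighted fit; rescaled weights leave the ATT unchanged", {
  ds <- toy_outcome_dataset(n_sets = 15, controls_per_set = 2, effect = 2,
                            resid_sd = 1, seed = 41)
  spec <- outcome_model_spec(chains = 1, iter = 200, warmup = 150, seed = 42)
  ids <- unique(ds$person_id)
  w1 <- data.frame(person_id = ids, included = TRUE, p_include = 1,
                   stabilized_weight = 1)
  fit_main <- fit_outcome_model(ds, spec)
  fit_w1 <- weighted_outcome_model(ds, w1, spec)
  expect_equal(fit_w1$beta_std, fit_main$beta_std)   # identical RNG path

  set.seed(43)
  w_rand <- w1
  w_rand$stabilized_weight <- runif(length(ids), 0.5, 2)
  w_doubled <- w_rand
  w_doubled$stabilized_weight <- 2 * w_rand$stabilized_weight
  a1 <- compute_att(weighted_outcome_model(ds, w_rand, spec),
                    timepoints = c(6, 12))
  a2 <- compute_att(weighted_outcome_model(ds, w_doubled, spec),
                    timepoints = c(6, 12))
  # doubling all weights rescales the implied residual variance only;
  # point estimates move within Monte-Carlo error
  expect_equal(a1$median_diff, a2$median_diff, tolerance = 0.2)

  w_missing <- w1[-1, ]
  expect_error(weighted_outcome_model(ds, w_missing, spec),
               "missing stabilized weight")
})

test_that("Rubin pooling reproduces the closed-form identity on a 3-imputation toy", {
  est <- c(1.0, 1.4, 0.9)
  v <- c(0.20, 0.25, 0.15)
  pp <- rubin_pool(est, v)
  expect_equal(pp$estimate, mean(est))
  expect_equal(pp$within, mean(v))
  expect_equal(pp$between, stats::var(est))
  expect_equal(pp$total_var, mean(v) + (1 + 1 / 3) * stats::var(est))
  expect_equal(pp$df, 2 * (1 + mean(v) / ((1 + 1 / 3) * stats::var(est)))^2)
  expect_true(pp$lo < pp$estimate & pp$estimate < pp$hi)
})

test_that("MI with no missing data degenerates to the complete-data regression", {
  ds <- toy_outcome_dataset(n_sets = 12, controls_per_set = 2, effect = 3,
                            resid_sd = 1, seed = 51, n_visits = 8)
  # place one observation exactly at each a priori timepoint
  tps <- c(0.5, 3, 6, 9, 12, 15, 18)
  rows <- list()
  for (pid in unique(ds$person_id)) {
    sub <- ds[ds$person_id == pid, ][seq_along(tps), ]
    sub$months_since_index <- tps
    sub$date <- sub$index_date + round(tps * 30.4375)
    rows[[length(rows) + 1]] <- sub
  }
  full <- do.call(rbind, rows)
  class(full) <- c("outcome_dataset", "data.frame")
  indexed <- data.frame(person_id = unique(full$person_id),
                        arm = ifelse(full$arm[!duplicated(full$person_id)] == 1,
                                     "switcher", "nonswitcher"),
                        set_id = full$set_id[!duplicated(full$person_id)],
                        eligible_date = as.Date("2020-01-01"),
                        index_date = as.Date("2020-06-01"))
  pooled <- mi_per_timepoint_regression(indexed, full, m = 2, cycles = 2,
                                        seed = 52)
  expect_true(all(pooled$available))
  expect_equal(pooled$between, rep(0, length(tps)))
  # matches a directly fitted complete-data regression at month 6
  wide_cov <- full[!duplicated(full$person_id), ]
  wide_cov$y <- full$egfr[full$months_since_index == 6]
  ref <- stats::lm(y ~ arm + age + male + insurance + race_ethnicity +
                     ever_smoker + weight_at_index + egfr_at_index +
                     egfr_at_eligible + duration_tdf_to_eligible +
                     hypertension_at_index, data = wide_cov)
  expect_equal(pooled$estimate[pooled$timepoint == 6],
               unname(stats::coef(ref)["arm"]), tolerance = 1e-8)
})

test_that("MI recovers a constant effect under outcome missingness", {
  ds <- toy_outcome_dataset(n_sets = 40, controls_per_set = 2, effect = 3,
                            resid_sd = 2, seed = 61, n_visits = 7)
  tps <- c(3, 6, 9, 12)
  rows <- list()
  set.seed(62)
  for (pid in unique(ds$person_id)) {
    sub <- ds[ds$person_id == pid, ][seq_along(tps), ]
    sub$months_since_index <- tps
    sub$date <- sub$index_date + round(tps * 30.4375)
    # MAR-ish thinning: drop ~30% of outcome rows
    keep <- runif(length(tps)) > 0.3
    rows[[length(rows) + 1]] <- sub[keep, , drop = FALSE]
  }
  long <- do.call(rbind, rows)
  class(long) <- c("outcome_dataset", "data.frame")
  indexed <- data.frame(person_id = unique(ds$person_id),
                        arm = ifelse(ds$arm[!duplicated(ds$person_id)] == 1,
                                     "switcher", "nonswitcher"),
                        set_id = ds$set_id[!duplicated(ds$person_id)],
                        eligible_date = as.Date("2020-01-01"),
                        index_date = as.Date("2020-06-01"))
  # ensure every person keeps a row so baseline covariates exist
  long <- rbind(long, ds[!duplicated(ds$person_id), ])
  class(long) <- c("outcome_dataset", "data.frame")
  pooled <- mi_per_timepoint_regression(indexed, long, m = 5, cycles = 5,
                                        timepoints = tps, seed = 63)
  ok <- pooled$available
  expect_true(any(ok))
  expect_true(all(pooled$lo[ok] <= 3 & pooled$hi[ok] >= 3))
})
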