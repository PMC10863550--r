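test_that("one switcher with an identical-covariate candidate matches at distance zero", {
  scores <- c(`1` = 0.5, `2` = 0.5, `3` = 2.0)
  eligible <- as.Date(rep("2020-01-01", 3))
  switch_date <- as.Date(c("2020-06-01", NA, NA))
  names(eligible) <- names(switch_date) <- names(scores)
  toy <- toy_match_inputs(scores, eligible, switch_date)
  res <- sequential_match(toy$score_fun, toy$profiles, toy$comorbidities,
                          toy$switch_dates, toy$persons, ratio = 1, seed = 1)
  expect_equal(nrow(res), 1)
  expect_equal(res$switcher_id, 1L)
  expect_equal(res$control_id, 2L)
  expect_equal(res$score_distance, 0)
})

test_that("five-person toy cohort matches the brute-force oracle", {
  scores <- c(`1` = 0.0, `2` = 0.1, `3` = 0.8, `4` = -0.3, `5` = 0.05)
  eligible <- as.Date(c("2020-01-01", "2020-01-01", "2020-02-01",
                        "2020-06-01", "2020-01-01"))
  switch_date <- as.Date(c("2020-03-01", NA, "2020-09-01", NA, NA))
  names(eligible) <- names(switch_date) <- names(scores)
  toy <- toy_match_inputs(scores, eligible, switch_date)
  res <- sequential_match(toy$score_fun, toy$profiles, toy$comorbidities,
                          toy$switch_dates, toy$persons, ratio = 2, seed = 1)
  oracle <- brute_force_match(scores, eligible, switch_date,
                              rep(as.Date(NA), 5), ratio = 2)
  # person 1 switches first: nearest two of {2,3,5} by score are 5 and 2.
  # person 3 switches later from the leftover pool {4}.
  expect_equal(length(oracle$sets), 2)
  expect_equal(sort(res$control_id[res$switcher_id == 1]),
               sort(as.integer(oracle$sets[[1]]$controls)))
  expect_equal(sort(res$control_id[res$switcher_id == 3]),
               sort(as.integer(oracle$sets[[2]]$controls)))
})

test_that("sequential matching equals the oracle on random small cohorts", {
  for (seed in 1:50) {
    toyc <- random_toy_cohort(n = sample(4:10, 1), seed = seed)
    toy <- toy_match_inputs(toyc$scores, toyc$eligible, toyc$switch_date,
                            toyc$disenroll)
    res <- sequential_match(toy$score_fun, toy$profiles, toy$comorbidities,
                            toy$switch_dates, toy$persons, ratio = 4,
                            seed = seed)
    oracle <- brute_force_match(toyc$scores, toyc$eligible,
                                toyc$switch_date, toyc$disenroll, ratio = 4)
    got <- lapply(split(res, res$set_id), function(g)
      list(sw = g$switcher_id[1], ct = sort(g$control_id)))
    want <- lapply(oracle$sets, function(s)
      list(sw = as.integer(s$switcher), ct = sort(as.integer(s$controls))))
    expect_equal(unname(got), unname(want), info = paste("seed", seed))
    expect_setequal(attr(res, "reclassified"),
                    as.integer(oracle$reclassified))
  }
})

test_that("a control consumed before their own switch stays a nonswitcher", {
  # B is nearest to A at A's switch; B switches later and must not form a set
  scores <- c(A = 0, B = 0.01, C = 1, D = 1.05)
  eligible <- as.Date(rep("2020-01-01", 4))
  switch_date <- as.Date(c("2020-03-01", "2020-08-01", NA, NA))
  names(eligible) <- names(switch_date) <- c("1", "2", "3", "4")
  names(scores) <- c("1", "2", "3", "4")
  toy <- toy_match_inputs(scores, eligible, switch_date)
  res <- sequential_match(toy$score_fun, toy$profiles, toy$comorbidities,
                          toy$switch_dates, toy$persons, ratio = 1, seed = 1)
  expect_equal(res$switcher_id, 1L)
  expect_equal(res$control_id, 2L)
  expect_equal(attr(res, "reclassified"), 2L)
  expect_false(2L %in% res$switcher_id)
})

test_that("risk sets respect eligibility, prior switching, and enrollment at the event date", {
  scores <- c(`1` = 0, `2` = 0.01, `3` = 0.02, `4` = 0.03, `5` = 0.04)
  eligible <- as.Date(c("2020-01-01", "2020-06-01", "2020-01-01",
                        "2020-01-01", "2020-01-01"))
  switch_date <- as.Date(c("2020-03-01", NA, "2020-02-01", NA, NA))
  disenroll <- as.Date(c(NA, NA, NA, "2020-02-15", NA))
  names(eligible) <- names(switch_date) <- names(disenroll) <- names(scores)
  toy <- toy_match_inputs(scores, eligible, switch_date, disenroll)
  res <- sequential_match(toy$score_fun, toy$profiles, toy$comorbidities,
                          toy$switch_dates, toy$persons, ratio = 4, seed = 1)
  # person 3 switches first (Feb): candidates exclude 2 (not yet eligible)
  # but include 4 (still enrolled on Feb 1) and 1 (switches later); with
  # ratio 4 all three are consumed, so person 1's own later event is
  # reclassified rather than matched
  ctl3 <- res$control_id[res$switcher_id == 3]
  expect_setequal(ctl3, c(1, 4, 5))
  expect_true(1L %in% attr(res, "reclassified"))
  expect_false(1L %in% res$switcher_id)
})

test_that("matching never conditions on post-event data", {
  run <- matching_only_run(seed = 5, n = 250)
  co <- run$cohort
  profiles <- run$profiles
  matched1 <- run$matched
  # perturb comorbidity onsets dated after the last switch event; control
  # selection must be unchanged because scores only use data on or before
  # each event date
  onsets2 <- co$comorbidities
  last_event <- max(matched1$switch_date)
  late <- onsets2$onset_date > last_event
  onsets2$onset_date[late] <- onsets2$onset_date[late] + 400
  # also hand some risk-set members a brand-new onset dated after the last
  # event (appended after existing rows so earlier onsets keep precedence)
  extra_ids <- setdiff(profiles$person_id, onsets2$person_id)[1:15]
  extra_ids <- extra_ids[!is.na(extra_ids)]
  expect_gt(length(extra_ids), 0)
  onsets2 <- rbind(onsets2,
                   data.frame(person_id = extra_ids,
                              condition = "hypertension",
                              onset_date = last_event + 30))
  sw2 <- observed_switch_dates_for_test(co$dispensings, profiles)
  matched2 <- sequential_match(run$tvps, profiles, onsets2, sw2, co$persons,
                               ratio = 4, seed = 5)
  for (col in c("set_id", "switcher_id", "control_id", "score_distance")) {
    expect_equal(matched1[[col]], matched2[[col]])
  }
})

test_that("index dates preserve the eligibility-to-switch interval and boundary rules", {
  scores <- c(`1` = 0, `2` = 0.1, `3` = 0.2)
  eligible <- as.Date(c("2020-01-01", "2020-02-01", "2020-06-01"))
  switch_date <- as.Date(c("2020-04-10", NA, NA))
  names(eligible) <- names(switch_date) <- names(scores)
  toy <- toy_match_inputs(scores, eligible, switch_date)
  res <- sequential_match(toy$score_fun, toy$profiles, toy$comorbidities,
                          toy$switch_dates, toy$persons, ratio = 4, seed = 1)
  idx <- assign_index_dates(res, toy$profiles, toy$persons)
  # interval is 100 days; control eligible 2020-02-01 -> index 2020-05-11
  expect_equal(idx$index_date[idx$person_id == 2], as.Date("2020-05-11"))
  expect_equal(idx$index_date[idx$person_id == 1], as.Date("2020-04-10"))
  ctl <- idx[idx$arm == "nonswitcher", ]
  sw <- idx[idx$arm == "switcher", ]
  expect_equal(as.numeric(ctl$index_date - ctl$eligible_date),
               rep(100, nrow(ctl)))

  # zero interval: control index equals its own eligible date
  eligible0 <- as.Date(c("2020-01-01", "2020-01-01", "2020-06-01"))
  switch_date0 <- as.Date(c("2020-01-01", NA, NA))
  names(eligible0) <- names(switch_date0) <- names(scores)
  toy0 <- toy_match_inputs(scores, eligible0, switch_date0)
  res0 <- sequential_match(toy0$score_fun, toy0$profiles,
                           toy0$comorbidities, toy0$switch_dates,
                           toy0$persons, ratio = 4, seed = 1)
  idx0 <- assign_index_dates(res0, toy0$profiles, toy0$persons)
  expect_equal(idx0$index_date[idx0$person_id == 2], as.Date("2020-01-01"))

  # a control whose assigned index lands after study end is dropped
  eligible_late <- as.Date(c("2020-01-01", "2020-01-05", "2022-01-01"))
  switch_late <- as.Date(c("2022-05-01", NA, NA))   # 851-day interval
  names(eligible_late) <- names(switch_late) <- names(scores)
  toyl <- toy_match_inputs(scores, eligible_late, switch_late)
  resl <- sequential_match(toyl$score_fun, toyl$profiles,
                           toyl$comorbidities, toyl$switch_dates,
                           toyl$persons, ratio = 4, seed = 1)
  expect_setequal(resl$control_id, c(2, 3))
  idxl <- assign_index_dates(resl, toyl$profiles, toyl$persons,
                             study_end = as.Date("2022-06-30"))
  expect_false(3L %in% idxl$person_id)  # 2022-01-01 + 851d > study end
  expect_true(2L %in% idxl$person_id)   # 2020-01-05 + 851d fits
})

test_that("tvps model drops zero-variance covariates and errors without events", {
  run <- matching_only_run(seed = 9, n = 200)
  cp <- build_risk_intervals(run$profiles, run$cohort$comorbidities,
                             run$switch_dates, run$cohort$persons)
  cp$constant_cov <- 1
  expect_warning(
    fit_tvps_model(cp, covariates = c("age_at_tdf_init", "egfr_at_eligible",
                                      "constant_cov")),
    "zero variance")
  cp0 <- cp
  cp0$event <- FALSE
  expect_error(fit_tvps_model(cp0), "no switch events")
})

test_that("fitted switch-hazard coefficient signs recover the generator truth", {
  signs <- vapply(1:10, function(s) {
    run <- matching_only_run(seed = s, n = 350)
    stats::coef(run$tvps$fit)["egfr_at_eligible"]
  }, numeric(1))
  # low baseline eGFR raises the switch hazard: negative coefficient
  expect_gte(sum(signs < 0), 9)
})
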