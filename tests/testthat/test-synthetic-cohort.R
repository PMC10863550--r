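# The generator is validated against its own declared truth: determinism,
# schema invariants, effect injection, confounding direction, and the
# marginal rates of the visit and missingness processes.

make_cohort <- function(seed = 11, n = 300, ...) {
  tr <- simulation_truth(n_persons = n, seed = seed, ...)
  list(truth = tr, cohort = simulate_cohort(tr))
}

test_that("identical seeds give identical tables; different seeds differ", {
  a <- make_cohort(seed = 11, n = 120)$cohort
  b <- make_cohort(seed = 11, n = 120)$cohort
  for (nm in c("persons", "dispensings", "labs", "weights", "comorbidities")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  c2 <- make_cohort(seed = 12, n = 120)$cohort
  expect_false(identical(a$labs, c2$labs))
})

test_that("cohort tables satisfy the schema invariants", {
  x <- make_cohort(seed = 21, n = 250)
  co <- x$cohort
  p <- co$persons
  expect_true(all(p$age_at_tdf_init >= 18))
  expect_true(all(p$sex %in% c("male", "female")))
  expect_true(all(p$race_ethnicity %in%
                    c("Asian NH", "Black NH", "Hispanic", "White NH",
                      "Other NH")))
  expect_true(all(p$insurance %in%
                    c("commercial", "Medicaid", "Medicare", "other")))
  expect_true(all(co$dispensings$days_supplied > 0))
  expect_true(all(co$labs$serum_creatinine > 0))
  expect_true(all(co$dispensings$drug %in% c("TDF", "TAF")))
  # events inside each person enrollment interval
  endd <- as.Date(ifelse(is.na(p$disenrollment_date),
                         as.numeric(x$truth$study_end),
                         as.numeric(p$disenrollment_date)),
                  origin = "1970-01-01")
  for (tab in c("dispensings", "labs", "weights")) {
    i <- match(co[[tab]]$person_id, p$person_id)
    expect_true(all(co[[tab]]$date >= p$first_tdf_dispense[i]))
    expect_true(all(co[[tab]]$date <= endd[i]))
  }
  i <- match(co$comorbidities$person_id, p$person_id)
  expect_true(all(co$comorbidities$onset_date >= p$first_tdf_dispense[i]))
  # manifest records the generator parameters including the effect at 0
  expect_equal(co$manifest$true_effect_at_0, x$truth$true_effect(0))
  expect_equal(co$manifest$n_persons, 250)
})

test_that("null effect leaves arms distinguished only by sampling noise", {
  x <- make_cohort(seed = 31, n = 400,
                   true_effect = piecewise_effect(c(0, 3), c(0, 0)),
                   confounding_strength = c(age = 0, egfr = 0,
                                            comorbidity = 0),
                   residual_sd = 2)
  fr <- attr(x$cohort, "latent")
  eg <- egfr_from_labs(x$cohort$labs, x$cohort$persons)
  i <- eg$person_id
  yrs <- as.numeric(eg$date -
                      x$cohort$persons$first_tdf_dispense[i]) / 365.25
  detr <- eg$egfr - (fr$egfr0[i] - 1.0 * yrs)   # remove known drift
  sw <- fr$switch_date[i]
  post <- !is.na(sw) & eg$date >= sw
  pre <- is.na(sw)
  expect_lt(abs(mean(detr[post]) - mean(detr[pre])), 0.5)
})

test_that("noise-free generator reproduces the injected effect exactly", {
  x <- make_cohort(seed = 41, n = 300, residual_sd = 0,
                   true_effect = piecewise_effect(c(0, 3), c(0, 3)),
                   visit_rate = 8)
  fr <- attr(x$cohort, "latent")
  eg <- egfr_from_labs(x$cohort$labs, x$cohort$persons)
  i <- eg$person_id
  yrs <- as.numeric(eg$date -
                      x$cohort$persons$first_tdf_dispense[i]) / 365.25
  gap <- eg$egfr - (fr$egfr0[i] - 1.0 * yrs)
  sw <- fr$switch_date[i]
  mos <- as.numeric(eg$date - sw) / (365.25 / 12)
  plateau <- !is.na(sw) & mos >= 3
  expect_gt(sum(plateau), 20)
  expect_equal(mean(gap[plateau]), 3.0, tolerance = 0.01)
  expect_lt(max(abs(gap[is.na(sw) | mos < 0])), 0.05)
})

test_that("confounding produces lower baseline eGFR among switchers", {
  x <- make_cohort(seed = 51, n = 500)
  fr <- attr(x$cohort, "latent")
  sw <- !is.na(fr$switch_date)
  expect_gt(sum(sw), 20)
  expect_lt(mean(fr$egfr0[sw]), mean(fr$egfr0[!sw]))
  # switch-hazard regression on the simulated data recovers coefficient signs
  surv_t <- as.numeric(pmin(fr$switch_date, fr$end_fu, na.rm = TRUE) -
                         pmax(as.Date("2019-10-01"),
                              x$cohort$persons$first_tdf_dispense))
  keep <- surv_t > 0
  fit <- survival::coxph(
    survival::Surv(surv_t[keep], sw[keep]) ~
      x$cohort$persons$age_at_tdf_init[keep] + fr$egfr0[keep])
  expect_gt(stats::coef(fit)[1], 0)   # older -> more switching
  expect_lt(stats::coef(fit)[2], 0)   # lower eGFR -> more switching
})

test_that("visit and missingness marginals match the generator model", {
  x <- make_cohort(seed = 61, n = 500)
  fr <- attr(x$cohort, "latent")
  py <- sum(as.numeric(fr$end_fu -
                         x$cohort$persons$first_tdf_dispense) / 365.25)
  # subtract the guaranteed screening visit per person
  emp_rate <- (nrow(fr$visit_df) - nrow(x$cohort$persons)) / py
  expect_lt(abs(emp_rate - x$truth$visit_rate) / x$truth$visit_rate, 0.10)

  v <- fr$visit_df
  i <- v$person_id
  yrs <- as.numeric(v$date -
                      x$cohort$persons$first_tdf_dispense[i]) / 365.25
  nonscreen <- yrs > 0
  mm <- x$truth$missingness_model
  eta <- mm["intercept"] +
    mm["age"] * (x$cohort$persons$age_at_tdf_init[i] - 38) / 10 +
    mm["egfr"] * (fr$egfr0[i] - 100) / 10 + mm["months"] * yrs * 12
  implied <- mean(stats::plogis(eta[nonscreen]))
  emp <- mean(v$u_obs[nonscreen] < stats::plogis(eta[nonscreen]))
  expect_lt(abs(emp - implied), 0.02)
})

test_that("inject_deviations is the identity at zero rates and adds the two deviation kinds otherwise", {
  tr0 <- simulation_truth(n_persons = 150, seed = 71,
                          deviation_rates = c(switch_back = 0,
                                              late_switch = 0))
  co0 <- simulate_cohort(tr0)
  out0 <- inject_deviations(co0, tr0)
  expect_identical(co0$dispensings, out0$dispensings)
  expect_identical(co0$labs, out0$labs)

  tr1 <- simulation_truth(n_persons = 400, seed = 72,
                          deviation_rates = c(switch_back = 0.6,
                                              late_switch = 0.4))
  co1 <- inject_deviations(simulate_cohort(tr1), tr1)
  d <- co1$dispensings
  # at least one switcher has a TDF fill after a TAF fill
  back <- vapply(split(d, d$person_id), function(g) {
    any(g$drug == "TAF") &&
      any(g$drug == "TDF" & g$date > min(g$date[g$drug == "TAF"]))
  }, logical(1))
  expect_gt(sum(back), 0)
  # extra late switching appeared relative to the natural process
  fr0 <- attr(simulate_cohort(tr1), "latent")
  fr1 <- attr(co1, "latent")
  expect_gt(sum(!is.na(fr1$switch_date)), sum(!is.na(fr0$switch_date)))
  # labs after a switch-back lose the effect: recompute one affected person
  sb_ids <- which(!is.na(fr1$switch_back))
  expect_gt(length(sb_ids), 0)
})

test_that("cohort csv round-trip preserves content", {
  x <- make_cohort(seed = 81, n = 60)
  dir <- withr::local_tempdir()
  write_cohort(x$cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(back$persons$age_at_tdf_init,
               x$cohort$persons$age_at_tdf_init)
  expect_identical(back$labs$date, x$cohort$labs$date)
  expect_equal(back$manifest$seed, 81)
})

test_that("invalid category frequencies raise a configuration error", {
  expect_error(simulation_truth(sex_p = c(male = 0.7, female = 0.2)),
               "sum to 1")
  expect_error(simulation_truth(race_p = c(a = 1)), "race")
})
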