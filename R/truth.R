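#' Piecewise-linear switch-effect trajectory
#'
#' Builds the ground-truth function mapping months since switch to the eGFR
#' shift caused by switching. The default study condition ramps linearly from
#' 0 at switch to +3 eGFR units at month 3 and stays at +3 thereafter, so the
#' true ATT at every a priori timepoint from month 3 onward is exactly +3.
#'
#' @param knots months since switch at which the effect is specified
#' @param values effect in eGFR units at each knot; constant extrapolation
#'   beyond the last knot, 0 before the first
#' @return a vectorized function of months since switch
#' @export
piecewise_effect <- function(knots = c(0, 3), values = c(0, 3)) {
  stopifnot(length(knots) == length(values), !is.unsorted(knots))
  force(knots); force(values)
  function(m) {
    out <- stats::approx(knots, values, xout = pmax(m, knots[1]),
                         rule = 2)$y
    out[m < knots[1]] <- 0
    out
  }
}

#' Ground-truth parameters for the synthetic EHR cohort
#'
#' Defines every parameter of the data-generating process: cohort size,
#' demographics, the latent eGFR model, the confounded switch process, lab
#' visit timing, covariate-dependent (MAR) lab missingness, and treatment
#' deviation rates. The defaults are the package's fixed reference study
#' conditions: a PrEP-style cohort in which older age, lower baseline eGFR
#' and comorbidity all raise the hazard of switching TDF to TAF, eGFR drifts
#' slowly downward on TDF, and switching shifts eGFR by `true_effect`.
#'
#' @param n_persons cohort size
#' @param seed master seed; all generator randomness derives from it
#' @param enrollment_window two dates: first TDF dispensings are drawn
#'   uniformly over this window
#' @param study_end administrative end of follow-up
#' @param true_effect function months-since-switch -> eGFR units (see
#'   [piecewise_effect()])
#' @param confounding_strength named log-hazard-ratio coefficients of the
#'   switch hazard: `age` (per 10 years), `egfr` (per 10 mL/min/1.73m^2 of
#'   baseline eGFR; negative means low eGFR switches more), `comorbidity`
#'   (any prevalent comorbidity)
#' @param baseline_switch_hazard per-year hazard of switching for a
#'   reference person once TAF is available
#' @param uptake_wave `c(duration_years, multiplier)`: the switch hazard is
#'   multiplied by `multiplier` during the first `duration_years` after the
#'   policy date (uptake of a newly approved regimen peaks early, then
#'   settles)
#' @param baseline_egfr_mean_sd mean/SD of baseline eGFR before the age
#'   gradient (eGFR declines ~4.5 units per decade of age here)
#' @param egfr_slope_per_year latent eGFR drift on TDF, units/year (negative)
#' @param residual_sd lab-to-lab residual SD of observed eGFR
#' @param visit_rate lab visits per person-year (Poisson process)
#' @param missingness_model logistic coefficients for P(lab observed):
#'   `intercept`, `age` (per 10 y), `egfr` (per 10 units of baseline eGFR),
#'   `months` (per month since first TDF dispense)
#' @param deviation_rates per-year hazards: `switch_back` (switcher returns
#'   to TDF), `late_switch` (extra TAF initiation among never-switchers,
#'   beyond the confounded switch process)
#' @param sex_p,race_p,insurance_p,smoking_p category frequencies (must sum
#'   to 1 where applicable)
#' @param baseline_ckd_p probability of the baseline CKD / abnormal-lab
#'   exclusion flag
#' @param disenroll_rate per-year hazard of health-plan disenrollment
#' @param comorbidity_rates per-year onset hazards at the reference age for
#'   diabetes, dyslipidemia, hypertension (each doubles per +20 years of age)
#' @param weight_mean_sd mean/SD of body weight (kg)
#' @return an object of class `simulation_truth`
#' @export
simulation_truth <- function(
    n_persons = 600,
    seed = 1L,
    enrollment_window = as.Date(c("2016-01-01", "2021-06-30")),
    study_end = as.Date("2022-06-30"),
    true_effect = piecewise_effect(c(0, 3), c(0, 3)),
    confounding_strength = c(age = 0.45, egfr = -0.35, comorbidity = 0.4),
    baseline_switch_hazard = 0.05,
    uptake_wave = c(duration_years = 1, multiplier = 2.5),
    baseline_egfr_mean_sd = c(105, 13),
    egfr_slope_per_year = -1.0,
    residual_sd = 4,
    visit_rate = 5,
    missingness_model = c(intercept = 1.2, age = 0.15, egfr = -0.15,
                          months = -0.012),
    deviation_rates = c(switch_back = 0.05, late_switch = 0.02),
    sex_p = c(male = 0.98, female = 0.02),
    race_p = c("Asian NH" = 0.11, "Black NH" = 0.05, "Hispanic" = 0.33,
               "White NH" = 0.41, "Other NH" = 0.10),
    insurance_p = c(commercial = 0.80, Medicaid = 0.05, Medicare = 0.03,
                    other = 0.12),
    smoking_p = 0.25,
    baseline_ckd_p = 0.04,
    disenroll_rate = 0.05,
    comorbidity_rates = c(diabetes = 0.012, dyslipidemia = 0.008,
                          hypertension = 0.006),
    weight_mean_sd = c(85, 16)) {
  truth <- list(
    n_persons = as.integer(n_persons),
    seed = as.integer(seed),
    enrollment_window = as.Date(enrollment_window),
    study_end = as.Date(study_end),
    true_effect = true_effect,
    confounding_strength = confounding_strength,
    baseline_switch_hazard = baseline_switch_hazard,
    uptake_wave = uptake_wave,
    baseline_egfr_mean_sd = baseline_egfr_mean_sd,
    egfr_slope_per_year = egfr_slope_per_year,
    residual_sd = residual_sd,
    visit_rate = visit_rate,
    missingness_model = missingness_model,
    deviation_rates = deviation_rates,
    sex_p = sex_p,
    race_p = race_p,
    insurance_p = insurance_p,
    smoking_p = smoking_p,
    baseline_ckd_p = baseline_ckd_p,
    disenroll_rate = disenroll_rate,
    comorbidity_rates = comorbidity_rates,
    weight_mean_sd = weight_mean_sd
  )
  class(truth) <- "simulation_truth"
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (truth$n_persons < 1) stop("n_persons must be >= 1")
  for (nm in c("sex_p", "race_p", "insurance_p")) {
    p <- truth[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("configuration error: %s frequencies must be nonnegative and sum to 1", nm))
    }
  }
  if (!identical(names(truth$race_p), RACE_LEVELS)) {
    stop("configuration error: race_p must be named exactly by the race/ethnicity categories")
  }
  if (!identical(names(truth$insurance_p), INSURANCE_LEVELS)) {
    stop("configuration error: insurance_p must be named exactly by the insurance categories")
  }
  if (!is.function(truth$true_effect)) stop("true_effect must be a function")
  if (truth$residual_sd < 0 || truth$visit_rate <= 0) {
    stop("residual_sd must be >= 0 and visit_rate > 0")
  }
  if (any(truth$deviation_rates < 0)) stop("deviation_rates must be >= 0")
  invisible(truth)
}

#' Serialize the generator truth into a manifest list
#'
#' Every generator parameter, including the true effect evaluated on a month
#' grid (the function itself cannot be serialized to JSON), is recorded so a
#' simulated cohort is fully reproducible from its manifest.
#'
#' @param truth a [simulation_truth()] object
#' @return a plain list suitable for `jsonlite::write_json`
#' @export
truth_manifest <- function(truth) {
  grid <- seq(0, 24, by = 0.5)
  list(
    n_persons = truth$n_persons,
    seed = truth$seed,
    enrollment_window = as.character(truth$enrollment_window),
    study_end = as.character(truth$study_end),
    true_effect_months = grid,
    true_effect_values = truth$true_effect(grid),
    true_effect_at_0 = truth$true_effect(0),
    confounding_strength = as.list(truth$confounding_strength),
    baseline_switch_hazard = truth$baseline_switch_hazard,
    uptake_wave = as.list(truth$uptake_wave),
    baseline_egfr_mean_sd = truth$baseline_egfr_mean_sd,
    egfr_slope_per_year = truth$egfr_slope_per_year,
    residual_sd = truth$residual_sd,
    visit_rate = truth$visit_rate,
    missingness_model = as.list(truth$missingness_model),
    deviation_rates = as.list(truth$deviation_rates),
    sex_p = as.list(truth$sex_p),
    race_p = as.list(truth$race_p),
    insurance_p = as.list(truth$insurance_p),
    smoking_p = truth$smoking_p,
    baseline_ckd_p = truth$baseline_ckd_p,
    disenroll_rate = truth$disenroll_rate,
    comorbidity_rates = as.list(truth$comorbidity_rates),
    weight_mean_sd = truth$weight_mean_sd
  )
}
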