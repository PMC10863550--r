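#' CKD-EPI 2021 creatinine eGFR
#'
#' Race-free Chronic Kidney Disease Epidemiology Collaboration (CKD-EPI)
#' 2021 estimating equation for glomerular filtration rate from serum
#' creatinine, age and sex:
#'
#' \deqn{eGFR = 142 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot
#'       \max(Scr/\kappa, 1)^{-1.200} \cdot 0.9938^{age} \cdot
#'       1.012\,[\mathrm{if\ female}]}
#'
#' with \eqn{\kappa = 0.7} (female) / \eqn{0.9} (male) and
#' \eqn{\alpha = -0.241} (female) / \eqn{-0.302} (male). All eGFR outcomes in
#' this package are computed with this equation; values are returned at full
#' precision (no clinical rounding).
#'
#' @param scr serum creatinine, mg/dL (vector)
#' @param age age in years, >= 18 (vector, recycled)
#' @param sex `"male"` or `"female"` (vector, recycled)
#' @return eGFR in mL/min/1.73 m^2
#' @examples
#' egfr_ckdepi_2021(0.9, 40, "male")
#' @export
egfr_ckdepi_2021 <- function(scr, age, sex) {
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(as.numeric(scr), n)
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(as.character(sex), n)
  if (anyNA(scr) || any(scr <= 0)) {
    stop("serum creatinine must be positive")
  }
  if (anyNA(age) || any(age < 18)) {
    stop("age must be >= 18 (adult equation)")
  }
  if (!all(sex %in% SEX_LEVELS)) {
    stop("sex must be 'male' or 'female'")
  }
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  r <- scr / kappa
  142 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.200) * 0.9938^age *
    ifelse(female, 1.012, 1)
}

#' Invert the CKD-EPI 2021 equation
#'
#' Serum creatinine that yields a target eGFR for a given age and sex, found
#' by monotone root-finding (the equation is strictly decreasing in
#' creatinine). Used by the cohort simulator, which draws latent eGFR
#' trajectories and emits creatinine lab values, so that the analysis
#' pipeline consumes creatinine exactly as it would from a real EHR.
#'
#' @param target_egfr desired eGFR, mL/min/1.73 m^2 (vector)
#' @param age age in years (vector, recycled)
#' @param sex `"male"` or `"female"` (vector, recycled)
#' @param scr_range plausible creatinine search interval, mg/dL; targets whose
#'   creatinine falls outside this interval are a domain error
#' @param tol absolute tolerance on the recovered eGFR
#' @return serum creatinine, mg/dL
#' @examples
#' invert_egfr(110.7, 40, "male")
#' @export
invert_egfr <- function(target_egfr, age, sex, scr_range = c(0.1, 20),
                        tol = 1e-8) {
  n <- max(length(target_egfr), length(age), length(sex))
  target_egfr <- rep_len(as.numeric(target_egfr), n)
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(as.character(sex), n)
  if (anyNA(target_egfr) || any(target_egfr <= 0)) {
    stop("target eGFR must be positive")
  }
  lo <- egfr_ckdepi_2021(rep(scr_range[2], n), age, sex)
  hi <- egfr_ckdepi_2021(rep(scr_range[1], n), age, sex)
  if (any(target_egfr > hi | target_egfr < lo)) {
    stop(sprintf(
      "target eGFR outside attainable range for given age/sex (creatinine in [%g, %g])",
      scr_range[1], scr_range[2]))
  }
  vapply(seq_len(n), function(i) {
    stats::uniroot(
      function(s) egfr_ckdepi_2021(s, age[i], sex[i]) - target_egfr[i],
      interval = scr_range, tol = tol
    )$root
  }, numeric(1))
}

#' Compute an eGFR table from creatinine labs
#'
#' Vectorized application of [egfr_ckdepi_2021()] over a lab table, joining
#' age and sex from the person table. Age is taken as age at TDF initiation
#' plus elapsed time to the lab date, so eGFR reflects attained age.
#'
#' @param labs data.frame with `person_id`, `date`, `serum_creatinine`
#' @param persons data.frame with `person_id`, `age_at_tdf_init`, `sex`,
#'   `first_tdf_dispense`
#' @return data.frame `person_id`, `date`, `egfr`
#' @export
egfr_from_labs <- function(labs, persons) {
  stopifnot(all(c("person_id", "date", "serum_creatinine") %in% names(labs)))
  idx <- match(labs$person_id, persons$person_id)
  if (anyNA(idx)) stop("labs reference unknown person_id values")
  age <- persons$age_at_tdf_init[idx] +
    as.numeric(labs$date - persons$first_tdf_dispense[idx]) / 365.25
  age <- pmax(age, 18)
  data.frame(
    person_id = labs$person_id,
    date = labs$date,
    egfr = egfr_ckdepi_2021(labs$serum_creatinine, age, persons$sex[idx]),
    stringsAsFactors = FALSE
  )
}
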