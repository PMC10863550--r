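---
title: "Estimating renal effects of TDF-to-TAF switching: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating renal effects of TDF-to-TAF switching: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

People using oral HIV preexposure prophylaxis (PrEP) with tenofovir
disoproxil fumarate (TDF) may switch to tenofovir alafenamide (TAF), which
produces lower plasma tenofovir levels and is expected to be gentler on the
kidney. Whether switching actually improves estimated glomerular filtration
rate (eGFR) in routine care is an observational question with two classic
hazards:

* **Confounding by indication** — clinicians preferentially switch older
  patients and patients with declining renal function, so switchers start
  from a lower eGFR than people who stay on TDF.
* **Immortal time bias** — a "nonswitcher" has no natural time zero. If
  follow-up for never-switchers starts at eligibility while switchers'
  starts at their switch, the comparison is misaligned; person-time before
  a switch must not be credited to either arm incorrectly.

`renalswitch` implements a pipeline that addresses both: time-varying
propensity-score (TV-PS) **risk-set matching** assigns every matched
nonswitcher an index date mirroring their switcher's
eligibility-to-switch interval, and a **Bayesian longitudinal model**
estimates the counterfactual contrast "what would the switchers' eGFR have
been had they not switched" — the average treatment effect on the treated
(ATT).

## Pipeline overview

1. **eGFR** — all creatinine labs are converted with the race-free CKD-EPI
   2021 equation (`egfr_ckdepi_2021()`); nothing is rounded before
   modeling, since no downstream step needs clinical rounding and full
   precision avoids a tie-breaking layer.
2. **Eligibility** (`compute_switch_eligible_date()`,
   `apply_exclusions()`) — a person becomes switch-eligible at the later
   of 183 cumulative days of TDF supplied ("six months of pills received";
   gaps between fills accumulate rather than reset) and 2019-10-01, the
   date TAF became available for PrEP. Exclusions: TAF initiation before
   the 6-month mark, baseline chronic kidney disease or lab abnormality
   (consumed as a precomputed flag; code-list phenotyping is out of
   scope), and failure to remain enrolled and reach eligibility inside the
   study window (2019-10-01 to 2022-06-30) — the last group is labeled
   `disenrolled`.
3. **Covariates** (`build_covariate_profiles()`,
   `impute_covariates_rf()`) — weight and eGFR "at" a date mean the most
   recent measurement within a 365-day lookback (a common EHR convention;
   the window is a config knob). Remaining gaps are filled by a single
   random-forest imputation (iterated column-by-column, observed cells
   never altered, mask retained).
4. **TV-PS matching** (`fit_tvps_model()`, `sequential_match()`,
   `assign_index_dates()`) — an extended Cox model on the
   time-since-eligibility scale with time-invariant covariates (age, race
   and ethnicity, male, smoking, insurance, year eligibility met, weight
   and eGFR at the eligible date) and time-varying comorbidity status
   (diabetes, dyslipidemia, hypertension). Switch events are processed in
   calendar order; at each event, persons still eligible, enrolled,
   TDF-only and unconsumed form the risk set, and up to four nearest
   candidates by |linear-predictor difference| become controls, without
   replacement. The model is fitted once and scored at each event date:
   one model plus an iterative matching loop keeps the procedure
   deterministic. The matching distance is the Cox linear predictor
   (log-hazard scale) with no caliper by default, both config-exposed;
   same-day events and distance ties are broken by a seeded draw. A person
   consumed as a control who later switches is dropped from the switcher
   stream and stays a nonswitcher for the rest of the analysis; partial
   sets (fewer than four controls) are retained. Controls inherit their
   switcher's eligibility-to-switch interval as an offset from their own
   eligible date, which is what neutralizes immortal time; controls whose
   assigned index date falls beyond disenrollment or the study end are
   dropped.
5. **Outcome model** (`fit_outcome_model()`, `compute_att()`) — a Gaussian
   mixed model for eGFR from index (month 0) to month 18, with fixed
   effects: switch status, age, male, insurance, race and ethnicity,
   smoking, weight at index, eGFR at the switch-eligible date, days from
   first TDF dispense to eligibility, hypertension at index, eGFR at index,
   and a natural cubic spline in months since index (4 df by default,
   boundary knots at 0 and 18, internal knots at follow-up-time quantiles,
   frozen at fit time); pairwise interactions among switch status, eGFR at
   index, and each spline column. Both "eGFR at the switch-eligible date"
   and "eGFR at index" enter despite their collinearity risk; an aliasing
   check drops named columns only if the design is genuinely
   rank-deficient. Random intercepts for person and matched set.
6. **Sensitivity analyses** — SA1 censors each person's rows after their
   first treatment deviation (switcher re-dispenses TDF, nonswitcher
   dispenses TAF; supply gaps alone are not deviations). SA2 reweights the
   main model by stabilized inverse-probability-of-missingness weights
   from a logistic model of "has any post-index eGFR" on the outcome
   model's baseline covariates, truncated at the 1st/99th percentiles. SA3
   bins outcomes to the nearest a priori timepoint within ±6 weeks (closest
   observation wins, seeded tie-break), imputes missing outcomes and
   covariates with chained equations in a wide person-by-timepoint layout
   (predictive mean matching for continuous, logistic draws for binary;
   m = 10 imputations, 10 cycles), fits one linear regression per
   timepoint, and pools switch coefficients by Rubin's rules. The wide
   layout honors "one regression per timepoint"; the ±6-week window and MI
   settings are config knobs.

## The Bayesian engine

No general-purpose MCMC backend is part of the pipeline: the outcome model
is conditionally conjugate, so the package fits it with a blocked Gibbs
sampler written for exactly this structure (`blmm_gibbs()`):

* fixed and random effects are drawn **jointly** from their multivariate
  normal full conditional via a sparse Cholesky factorization (person and
  set incidence blocks are sparse; the symbolic factorization is computed
  once), which removes the fixed-random autocorrelation that plagues
  one-at-a-time samplers — split-R-hat is essentially 1 after a few dozen
  sweeps;
* the response and all non-constant design columns are standardized
  internally; coefficients get Gaussian(0, 10²) priors on that scale
  (effectively flat but proper);
* the three standard deviations (person, set, residual) get
  half-Student-t(3, 1) priors via the Huang–Wand inverse-gamma mixture,
  keeping every update conjugate.

Defaults are 2 chains × 1000 kept draws after 500 warmup sweeps — sized so
a full pipeline run takes well under a minute on one core — with
split-R-hat and effective-sample-size diagnostics computed on every fit; a
fit that exceeds the R-hat tolerance raises an error rather than returning
silently.

**ATT computation.** For each posterior draw and timepoint *m* in
{0.5, 3, 6, 9, 12, 15, 18} months, the model predicts mean eGFR for every
matched switcher's baseline covariate row under switch = 1 and switch = 0,
with random effects marginalized at zero (the estimand is a population
contrast; person and pair deviations cancel in expectation), averages each
scenario over switchers, and differences them. Draws are summarized as the
median, 95% credible interval, probability of direction (fraction of draws
favoring higher eGFR under switching), and the fraction inside the region
of practical equivalence, ±2 eGFR units. Counterfactuals are computed for
switchers only; the design does not support inference for nonswitchers'
untaken switches.

## The synthetic cohort and what it does (and does not) show

The EHR data behind the original analysis cannot be redistributed, so the
package ships a generator (`simulation_truth()`, `simulate_cohort()`)
whose defaults are the package's fixed reference study conditions:

* 600 persons; first TDF dispense uniform over 2016-01 to 2021-06; study
  end 2022-06-30; ~86% remain eligible after exclusions.
* Demographics mirror a Southern-California PrEP population: 98% male,
  race/ethnicity mix with White non-Hispanic users skewing older and
  Hispanic users younger, insurance mostly commercial with
  Medicare/Medicaid odds rising with age, 25% ever-smokers (odds also
  rising with age). These gradients make demographic covariates genuine
  (indirect) confounders, as in the observed imbalance tables of EHR
  switching studies.
* Latent eGFR: baseline mean 105 at the reference age minus 4.5 units per
  decade of age (SD 13), drifting −1 unit/year on TDF; lab-to-lab residual
  SD of 4 eGFR units, at the low end of reported short-term within-person
  variability so that parameter-recovery checks at this cohort size retain
  useful precision. Latent eGFR is inverted through CKD-EPI 2021 to emit
  serum creatinine, so the pipeline consumes creatinine exactly as from a
  real EHR.
* Switching: proportional-hazards uptake from 2019-10-01 with log-hazard
  increments of +0.45 per decade of age, −0.35 per 10 units of baseline
  eGFR, +0.4 for prevalent comorbidity; baseline hazard 0.05/year with a
  2.5× wave during the first year of availability (uptake of a newly
  approved regimen peaks early). This yields roughly 95–105 observed switch
  events per 600 persons with switchers' baseline eGFR visibly below
  nonswitchers', and — because matching consumes five persons per set from
  a pool of ~520 — a substantial minority of eventual switchers are
  consumed as controls first, exercising the reclassification rule far
  more often than a large cohort would.
* Lab visits: person-level Poisson process at 5 visits/year (quarterly
  PrEP monitoring plus interval creatinine draws from other care); a
  screening lab at TDF initiation is always observed. Each later lab is
  observed with probability `plogis(1.2 + 0.15·age10 − 0.15·egfr10 −
  0.012·months)` — missing at random given baseline covariates, with
  attrition over time; roughly a third of modeled persons have an eGFR
  within six weeks of month 18, mirroring the sparsity that makes the
  month-18 estimate unstable.
* Deviations: switchers revert to TDF at 0.05/year; never-switchers gain
  extra late TAF initiation at 0.02/year on top of the natural confounded
  process. The true effect applies only while on TAF.
* True effect: piecewise-linear, by default ramping 0 → +3 eGFR units over
  months 0–3 after the switch and constant thereafter, so the true ATT at
  every a priori timepoint from month 3 on is exactly +3.

All generator randomness derives from one master seed through documented
sub-streams; identical seeds give byte-identical tables, and the full
parameter set (with the effect function evaluated on a month grid) is
recorded in the output manifest.

Passing recovery and calibration checks on these cohorts demonstrates that
the estimator correctly undoes the confounding and missingness mechanisms
*it was built for*: log-linear switch hazards in measured covariates,
MAR lab observation, absorbing comorbidities, a common secular eGFR
trend. Real EHR data can violate all of these (unmeasured confounding,
informative visit timing, assay changes, intermittent PrEP use), and no
simulation result here speaks to those violations.

## Numerical and design decisions

* Dates are ISO-8601 throughout; months are days/30.4375.
* The "six months of pills" threshold is 183 cumulative days supplied;
  the eligible date is the day after the 183rd supplied day.
* Same-day switch events are processed in seeded-random order;
  equal-distance control ties are broken by a seeded draw.
* A switcher facing an empty risk set is discarded with a logged reason;
  sets that lose all controls at index-date assignment drop their switcher
  too (a set must contribute both arms).
* Persons with no eGFR strictly after the index date are excluded from the
  complete-case analyses; a lab exactly at the index date is retained as
  month 0.
* For "eGFR/weight at index", a measurement within the 365-day lookback is
  preferred; failing that, the most recent earlier measurement is used (a
  stale real value beats an imputed one), and only then the imputed
  eligible-date value.
* The null calibration and parameter-recovery checks summarize the ATT at
  months 6–12 (recovery) and month 9 (calibration) — the plateau of the
  default effect trajectory and the series' central timepoint.
* Problem sizes in the test suite: toy cohorts of 4–10 persons for exact
  oracle comparisons; 250–500 persons for structural checks; the reference
  600-person design with 2 × 1000 draws for recovery, calibration and
  balance, 10 seeds each.

## Known limitations

* The sampler covers exactly the model the pipeline needs (Gaussian
  response, two random-intercept blocks, per-person likelihood weights);
  it is not a general mixed-model engine.
* Matching at this cohort scale consumes much of the risk pool, so
  reclassification is common and late sets can match at larger score
  distances than a large-cohort application would see.
* SA3's chained-equation imputer supports continuous (predictive mean
  matching) and binary (logistic) variables; categorical covariates must
  be complete, which the generator guarantees.
* The weighted analysis treats stabilized weights as fixed likelihood
  scale factors; uncertainty in the weight model itself is not propagated
  (standard practice, but an approximation).
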