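# renalswitch

Estimating the renal-function effect of switching HIV preexposure
prophylaxis (PrEP) from tenofovir disoproxil fumarate (TDF) to tenofovir
alafenamide (TAF) using electronic-health-record-style data.

Comparing switchers to people who stay on TDF is a minefield: clinicians
preferentially switch older patients with lower kidney function
(confounding by indication), and "nonswitchers" have no natural follow-up
time zero (immortal time bias). `renalswitch` implements a pipeline that
addresses both and quantifies the effect as a counterfactual contrast:

1. **CKD-EPI 2021 eGFR** — every serum creatinine is converted with the
   race-free equation
   `eGFR = 142 · min(Scr/κ,1)^α · max(Scr/κ,1)^−1.200 · 0.9938^age ·
   1.012[female]`.
2. **Switch eligibility** — a person enters the cohort at the later of 183
   cumulative days of TDF supplied and 2019-10-01 (TAF availability);
   early TAF starters, baseline CKD, and people leaving the window are
   excluded. Covariate gaps are filled by single random-forest imputation.
3. **Time-varying propensity-score risk-set matching** — an extended Cox
   model of the switch hazard (age, race/ethnicity, sex, smoking,
   insurance, eligibility year, weight and eGFR at eligibility;
   time-varying diabetes/dyslipidemia/hypertension) is scored at each
   switch date; up to 4 nearest still-untreated, unconsumed persons become
   matched nonswitchers, without replacement. Each control's index date is
   their own eligible date plus the switcher's eligibility-to-switch
   interval, eliminating immortal time; a control who later switches stays
   a nonswitcher.
4. **Bayesian counterfactual outcome model** — a longitudinal Gaussian
   mixed model for eGFR over 18 months (natural-cubic-spline time, random
   intercepts for person and matched set, switch × time and switch ×
   baseline-eGFR interactions), fitted by a blocked conjugate Gibbs
   sampler. For each posterior draw the model predicts every switcher's
   eGFR under switch and no-switch scenarios; the averaged difference is
   the average treatment effect on the treated (ATT), reported at months
   0.5–18 with 95% credible intervals, probability of direction (PDI),
   and the fraction of draws inside the ±2-eGFR-unit region of practical
   equivalence (ROPE).
5. **Sensitivity analyses** — SA1: censoring at treatment deviation;
   SA2: stabilized inverse-probability-of-missingness weights; SA3:
   multiple imputation with one linear regression per timepoint, pooled by
   Rubin's rules.

Because real EHR data of this kind cannot be redistributed, the package
includes a synthetic cohort generator with known ground truth (confounded
switch timing, MAR lab missingness, treatment deviations, a configurable
true effect trajectory), so the full pipeline is testable end to end. See
`vignettes/counterfactual-switching.Rmd` for the model details and every
design decision.

## Worked example

```r
library(renalswitch)

truth <- simulation_truth(n_persons = 600, seed = 1)   # true ATT: +3 from month 3
cfg <- pipeline_config(truth = truth, seed = 1, analyses = c("main", "sa1"))
run <- run_pipeline(cfg)

attrition_report(run)
#>                                 stage    n
#> 1                       persons_input  600
#> 2            included_switch_eligible  515
#> 4              switch_events_observed  109
#> 5  switchers_reclassified_as_controls   49
#> 7                        matched_sets   60
#> 8                    matched_controls  240
#> 11               analyzable_switchers   57
#> 12            analyzable_nonswitchers  205

subset(run$att, analysis == "main" & timepoint %in% c(6, 9, 12))
#>   timepoint median_diff cri_lo cri_hi   pdi rope_fraction n_draws analysis
#> 3         6        2.48  1.050   4.04 1.000         0.239    2000     main
#> 4         9        2.63  1.065   4.32 1.000         0.234    2000     main
#> 5        12        2.39  0.653   3.98 0.997         0.327    2000     main
```

Reading the output: of 600 simulated persons, 515 meet eligibility; 109
switch during follow-up, of whom 49 had already been consumed as matched
controls and therefore remain nonswitchers; 60 matched sets survive, with
57 switchers and 205 controls contributing post-index eGFR. The posterior
median ATT at months 6–12 sits near the generator's true +3 eGFR units
(mildly attenuated by controls who switch later in follow-up, as in real
cohorts), the credible intervals exclude 0, PDI ≈ 1 says essentially all
posterior mass favors higher eGFR under switching, and ROPE fractions of
0.23–0.33 say roughly a quarter to a third of draws still lie inside the
±2-unit "practically no difference" region. Other seeds vary within
sampling noise.

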