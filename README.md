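# capload

Capacity–load modelling of childhood blood pressure.

Life-course epidemiology keeps meeting the same puzzle: birth weight often
shows no *marginal* association with childhood blood pressure (BP), while
postnatal growth shows a strong positive one — yet adjusting for current
body size flips the birth-weight effect negative and erases the growth
effect. The capacity–load model explains both at once. Birth weight indexes
**metabolic capacity** (homeostatic organ reserve, e.g. nephron number);
childhood height, lean mass relative to height (LMr/H) and fat mass
relative to lean mass (FMr/LM) index **metabolic load**. BP rises with load
and falls with capacity, conditionally on each other; marginally, the
negative direct capacity path and the positive path mediated through larger
childhood size cancel.

`capload` is an R package for running that analysis on a birth-cohort
table, and for verifying every stage of it on synthetic cohorts with known
structure:

* **LMS reference z-scoring** — `lms_zscore()`, `lms_value()`,
  `bp_centile_cutoff()`: the Cole LMS transform
  `z = ((x/M)^L − 1)/(L·S)` with age-interpolated parameters, its exact
  inverse, and raw-scale reference centile thresholds; references travel in
  a documented CSV dialect (`read_lms_reference()`).
* **Hadi forward-search outlier screening** — `hadi_outliers()`,
  `remove_outliers()`: deterministic multivariate screening applied to each
  bivariate scatter before residualisation (compiled forward search).
* **Standardised unexplained residuals** — `standardized_residual()`,
  `conditional_velocity()`, `build_predictor_set()`: sex-stratified SRR
  predictors (Wr/H, LMr/H, FMr/H, FMr/LM) and conditional weight/height
  velocities (CWV, CHV), with a cumulative exclusion ledger.
* **Model suites** — `capload()`, `run_suite()`: per-sex linear Models 1–3
  (current load; early growth; joint) for systolic, diastolic and
  pulse-pressure z-scores, plus pooled logistic models for the odds of BP
  at or above the reference 95th centile. `capload()` returns a classed
  object with `print`, `summary`, `coef`, `confint`, `predict`,
  `residuals`, `nobs` and `plot` methods.
* **Structural cohort simulator** — `generator_config()`,
  `calibrate_default_config()`, `generate_cohort()`,
  `implied_coefficients()`: a DAG generator that plants the capacity–load
  signal, back-constructs a raw-scale cohort through the reference tables,
  injects gross outliers and missingness, and comes with a closed-form
  oracle for the regression coefficients any subset model should recover.

## Worked example

Generate a calibrated synthetic cohort, derive the predictor set, and
contrast the growth-only and fully adjusted systolic models:

```r
library(capload)
cfg <- calibrate_default_config(n = c(male = 1500, female = 1500))
coh <- generate_cohort(cfg, seed = 1)
d   <- build_predictor_set(coh, cfg$reference)
capload(d, outcome = "sbp_z", models = c("model2", "model3"))
```

```
Capacity-load linear suite for sbp_z (growth path: weight)
== model2 ==
linear model: sbp_z ~ bw_z + cwv
-- male (n = 1315, r2 = 0.16)
   (Intercept)   -0.02 (-0.07; 0.03)
   bw_z          -0.02 (-0.07; 0.03)
   cwv            0.41 (0.36; 0.46)
...
== model3 ==
linear model: sbp_z ~ ht9_z + lmr_h + fmr_lm + bw_z + cwv
-- male (n = 1315, r2 = 0.33)
   ...
   bw_z          -0.09 (-0.13; -0.04)
   cwv           -0.00 (-0.07; 0.07)
```

This is the headline pattern: in the growth-only model the conditional
weight velocity coefficient is strongly positive (0.41 SDS per SRR) and
birth weight is null (−0.02, CI covering 0); adding the three load
components flips birth weight negative (−0.09, CI excluding 0) and
attenuates the velocity to the null (−0.00). The generator planted exactly
this structure (marginal CWV 0.40, marginal birth weight 0.00, conditional
birth weight −0.10 for males), so the fit is a parameter-recovery check,
not a happy accident. The per-step exclusion ledger is available as
`attr(d, "ledger")`; here the six screens flagged 8 of 3,000 records,
including the generator's planted gross outliers.

`implied_coefficients(cfg, "marginal_growth", "sbp", "male")` returns the
analytic values the fits above are converging to, and
`run_pipeline(cohort, reference, out_dir = "out")` runs the whole analysis
(z-scores → screening → SRRs → all model suites) and writes
machine-readable results.

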