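# cd4slope

Does the *rate* at which an HIV-positive patient's CD4 count has been
falling tell you anything about their prognosis once combination
antiretroviral therapy (cART) starts — beyond what the current CD4 count,
viral load, age and clinical history already say?  Treatment guidelines
have suggested starting therapy early in "rapid decliners" (a loss of more
than 100 cells/µl per year), which only makes sense if the pre-treatment
CD4 slope carries independent prognostic information.

`cd4slope` implements the full analysis pipeline for that question, built
for seroconverter cohorts (patients whose infection date is bracketed by a
last-negative and first-positive antibody test) and exercised end to end on
synthetic cohorts, so no patient data is required.  It is aimed at
biostatisticians and HIV epidemiologists who want to reproduce, stress-test
or extend this style of prognostic analysis.

## What is inside

**Cohort rules** (`new_cohort`, `read_cohort`, `apply_eligibility`,
`build_endpoint`, `build_pre_cart_baseline`): midpoint seroconversion
dating, the 91-day baseline window with a ≥3-month earlier CD4 count,
first-new-AIDS-event-or-death and death endpoints, and the supplementary
untreated-era design (baseline at the last 1993 CD4 count, censoring at
1995-12-31).

**Slope estimators** (`estimate_slopes`, `slope_two_point`, `slope_ols`,
`summarize_slopes`): three competing definitions of a patient's CD4 slope
`β1 + b1i` (cells/µl per year, negative = decline):

* two-point interpolation of the last two counts at least 6 months apart;
* per-patient ordinary least squares;
* best linear unbiased predictions (BLUPs) from the linear mixed model
  `CD4_ij = β0 + b0i + (β1 + b1i) t_ij + ε_ij`, which shrink noisy
  individual slopes towards the population slope.

**Trajectory models** (`fit_lmm`, `fit_iou`, `loglik_iou`, `iou_kernel`,
`profile_ci_alpha`, `compare_models`): alongside the linear mixed model, an
integrated Ornstein–Uhlenbeck (IOU) process model

`CD4_i(t) = β0 + b0i + β1 t + W_i(t) + ε`, with
`Cov(W(s), W(t)) = σ²/(2α³) · (2α min(s,t) + e^{−αs} + e^{−αt} − 1 −
e^{−α|s−t|})`.

The stability parameter α is the mean-reversion rate of the latent slope:
α → 0 recovers a constant patient-specific slope, large α means slopes
wander Brownian-fashion around the population slope, with slope
autocorrelation `e^{−α·lag}`.  α is profiled, because its upper confidence
limit is typically unbounded.

**Joint model** (`fit_joint`): CD4 trajectory and time-to-cART-initiation
modelled jointly, the initiation hazard
`λ0(t) exp(γ0 b0i + γ1 b1i)` acting as the missing-data mechanism for
informative treatment start (low-CD4 patients start therapy, truncating
their own series).  Fitted by maximum likelihood with pseudo-adaptive
Gauss–Hermite quadrature over the shared random effects.

**Outcome models** (`cox_fit_stratified`, `rapid_decline_binary_cox`,
`event_rate`, `concordance_5y`, `risk_scores_5y`, `quartile_event_table`):
Cox proportional-hazards models stratified by baseline CD4 category
(<100, 100–<200, 200–<350, ≥350 cells/µl) and injection-drug-use
transmission, adjusted for log viral load, age and prior AIDS; hazard
ratios reported per +10 cells/µl/year of slope; discrimination of 5-year
risk predictions by Harrell's c index over horizon-truncated comparable
pairs; person-year event rates with Poisson normal-approximation intervals.

**Synthetic cohorts** (`simulation_config`, `simulate_cohort`,
`draw_trajectory_linear`, `draw_trajectory_iou`): seroconversion windows,
irregular visit schedules, linear or IOU trajectories with measurement
error, CD4-threshold-driven (informative) cART initiation, and post-cART
event times from a proportional-hazards model on baseline covariates —
with the ground truth returned for parameter-recovery tests.

**Pipelines** (`run_main_analysis`, `run_pre_cart_analysis`,
`run_sensitivity_suite`) orchestrate the stages; the numbered scripts in
`analysis/` drive them and write tables under `results/`.

## Worked example

```r
library(cd4slope)

cfg <- simulation_config(n_patients = 600, seed = 42)  # null: hazard ignores slope
sim <- simulate_cohort(cfg)
res <- run_main_analysis(sim$cohort, analysis_config())
```

This prints (via the summaries in `res`):

```
eligible 486 of 600; events 62; rate 2.71 (2.04-3.39) per 100 py
median BLUP slope -60.8 (IQR -68.2 to -54.1); rapid decliners: 69% / 26% / 0% (two-point/OLS/BLUP)
adjusted HR per +10 cells/ul/yr: 0.85 (0.70-1.05), p = 0.13
c index without/with slope: 0.697 / 0.702
```

Reading it: 486 patients meet the baseline-measurement rules; AIDS/death
events accrue at 2.7 per 100 person-years.  The population declines about
61 cells/µl per year, but the fraction of apparent "rapid decliners"
collapses from 69% to 0% as the estimator borrows more strength — the
two-point rule mostly measures noise.  The adjusted hazard ratio per +10
cells/µl/year confidence interval straddles 1 and the c index is unchanged
by adding the slope: under this (null) generator the slope carries no
prognostic information beyond the baseline covariates, which is exactly
what the pipeline should report.

The `analysis/` scripts run the same machinery at larger scale:
`01_simulate_cohorts.R` (cohort generation), `02_slope_estimators.R`
(shrinkage hierarchy), `03_trajectory_models.R` (IOU vs linear, α profile),
`04_outcome_models.R` (outcome table for all patients and the >350
subgroup), `05_pre_cart_era.R` (untreated-era design with a small true
slope effect), `06_sensitivity.R` (alternative slope definitions).

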