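---
title: "Models and design choices behind the CD4-slope prognosis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind the CD4-slope prognosis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cd4slope)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the places
where the design was genuinely open and a decision had to be made.

## The scientific question

A patient's CD4 count is the strongest routine predictor of AIDS or death,
both untreated and after starting combination antiretroviral therapy
(cART).  Guidelines have additionally pointed at the *slope* — how fast
the count has been falling — as a trigger for earlier treatment.  That
recommendation presumes two things: that a patient has a reasonably stable
slope to measure, and that the slope predicts outcome beyond the current
CD4 count and the other established predictors.  The pipeline interrogates
both presumptions on seroconverter cohorts, where time since infection is
known to within a documented test window.

## Cohort rules

Seroconversion is dated at the midpoint of the last-negative /
first-positive test window; windows wider than 3 years disqualify.  The
treated-era analysis requires a CD4 count and a viral load within 91 days
before cART initiation and at least one CD4 count ≥91 days earlier ("at
least 3 months"; we encode both as 91 days, configurable — whether the
original rule meant 90 days, 91 days or calendar months is not stated
anywhere we could verify, and nothing downstream is sensitive to the
choice).  When several measurements fall inside the window, the one
closest to initiation is the baseline value, later date winning ties;
the rule is a package decision, as the convention is not otherwise pinned
down.  Exclusion reasons are assigned in a fixed order (fewer than two CD4
counts → missing window measurements → insufficient interval) so each
excluded patient is counted exactly once.

The untreated-era design takes each patient's last CD4 count in 1993 as
baseline, requires an earlier count within 1989–1993, excludes prior AIDS,
and censors follow-up administratively at 1995-12-31.  Its sensitivity
variant drops anyone on antiretroviral therapy by 1993 and censors at
therapy start in 1994–95; this is why the patient table carries an
optional `art_start_date` column beyond the core schema.

## Three slope estimators and the shrinkage hierarchy

The two-point estimator interpolates the last two counts at least six
months apart, choosing the later point as late as possible and then the
earlier point as late as possible subject to the gap.  Per-patient least
squares uses all of a patient's counts.  The BLUP estimator predicts
`β1 + b1i` from the random-intercept/random-slope mixed model, fitted by
(RE)ML via `lme4`; a patient with little data is shrunk towards the
population slope, which is how an experienced clinician reads a sparse
chart.  On any noisy cohort the spread of estimates — and with it the
apparent prevalence of "rapid decliners" — falls strictly from two-point
to least squares to BLUP.  The tests assert the ordering, not particular
percentages: the magnitudes depend on visit density and noise.

Formal model comparisons run on square-root CD4 (variance stabilisation);
reported slopes stay on the raw scale (cells/µl/year), because that is the
scale guidelines speak.  When a model is fitted on the square-root scale,
its slope is mapped back by the delta method, `2·m̂·s`, with `m̂` the
patient's fitted square-root level at the midpoint of their observation
span — the midpoint is our choice of evaluation point; any point in the
span gives rank-identical slopes.  Intercept–slope correlation is allowed
by default (the original specification is silent); an independence
structure is the automatic fallback when the correlated fit is singular.

## The integrated Ornstein–Uhlenbeck model

Is a constant patient-specific slope even tenable?  The IOU model replaces
the random slope with the integral of a stationary OU velocity process:
mean reversion α (1/years) and diffusion scale σ², stationary slope SD
τ = √(σ²/2α), covariance kernel

Cov(W(s), W(t)) = σ²/(2α³) · (2α·min(s,t) + e^{−αs} + e^{−αt} − 1 − e^{−α|s−t|}).

The velocity starts in its stationary distribution — that is what gives
the closed-form kernel above; a non-stationary start is out of scope.  The
kernel is evaluated through `expm1`, which keeps the α → 0 limit (τ²·s·t,
the random-slope covariance) accurate to ~10⁻⁸ relative error instead of
losing it to cancellation; the α → ∞, σ²/α² = κ limit is Brownian motion
κ·min(s,t).  Slope autocorrelation at lag ℓ is e^{−αℓ}: at the lower
confidence bound of α ≈ 36 seen in seroconverter data, the six-month
autocorrelation is ~1.5×10⁻⁸ — this period's slope says nothing about the
next.

Fitting is maximum likelihood on log-transformed variance parameters with
the two fixed effects concentrated out by generalized least squares at
every evaluation, three deterministic moment-informed starts, Nelder–Mead
followed by BFGS.  Patients sharing a visit grid share one Cholesky
factorisation per likelihood evaluation, which is what makes the
fixed-schedule simulations cheap.  Confidence for α is by profile
likelihood, not Wald, because the upper limit is typically unbounded and a
Wald interval cannot say so; each profile point re-optimises the remaining
variance parameters from two warm starts, one preserving τ (small-α
regime) and one preserving κ (large-α regime), keeping the better.  The
linear-vs-IOU comparison uses AIC on ML fits of identical data
(fingerprint-checked): the models are non-nested and the α → 0 boundary
makes likelihood-ratio calibration dubious, a known and deliberately
unsolved limitation.

**Identifiability caveat.**  Under realistic visit spacing (~5 months) and
measurement error (~80 cells/µl), α is only bounded from below: the
likelihood is flat from moderate α to infinity, which is exactly the
real-data phenomenon (a CI "from 36 to infinity").  Parameter *recovery*
experiments therefore use an informative design — early visits at the
velocity decorrelation scale 1/α and small measurement error — because a
recovery test under a non-identifying design tests nothing.  The package
states this as an information-design argument, not a tuning choice: with
visit gaps Δ ≫ 1/α every kernel entry collapses to the Brownian form and
no estimator could recover α.

## The joint longitudinal / time-to-initiation model

Threshold-driven treatment initiation truncates exactly the trajectories
that are falling fastest.  The joint model pairs the linear mixed model
with a proportional-hazards initiation model sharing the random effects:
piecewise-constant baseline hazard on quartiles of observed initiation
times (4 pieces), association terms per unit random intercept and random
slope, an optional linear calendar covariate standing in for cohort and
era effects.  The marginal likelihood integrates the random effects by
pseudo-adaptive Gauss–Hermite quadrature (9² nodes by default): node grids
are centred on each patient's longitudinal posterior mode, the
optimisation is run, the grids are re-centred at the fitted solution and
the optimisation repeated — without the re-centring round the optimiser
can exploit grid-edge inaccuracy.  Under-resolution is detected by a
doubling check on the log-likelihood (threshold 0.1) with one automatic
refit at doubled resolution before erroring.  Gauss–Hermite nodes come
from the Golub–Welsch eigendecomposition, computed in-package.

Two subtleties surfaced during development and are worth recording.
First, when initiation is driven by the *observed* CD4 value, the
missingness is "missing at random given observed data" and the ordinary
mixed model is already consistent — a joint model has nothing to correct
and will, if anything, overcorrect slightly.  The generator therefore
offers `cart_trigger = "latent"` (clinicians reacting to the patient's
true immune state, e.g. through symptoms), the genuinely informative
mechanism, and that is the regime in which the joint model demonstrably
reduces slope bias.  Second, with a free association and free baseline
pieces the joint likelihood has a flat ridge coupling the population slope
to the mean random slope; the maximum can drift a few cells/µl/year along
it at negligible likelihood cost (verified against exact fine-grid
integration).  Joint and mixed-model slopes therefore agree in rank and up
to a small common drift, not datum by datum.

## Outcome models

Cox proportional-hazards models with Efron tie handling (the original tie
method is unstated; Efron is the better default), stratified by baseline
CD4 category (<100, 100–<200, 200–<350, ≥350 cells/µl) × injection-drug
use, adjusted for log₁₀ viral load, age (per 10 years) and prior AIDS.
The slope enters per +10 cells/µl/year, so a hazard ratio below 1 means
"a less steep decline is protective".  Wald intervals throughout (again
the original choice is unstated).  Monotone-likelihood separation and
degenerate covariates are flagged, not silently reported.

Discrimination uses Harrell's c over horizon-truncated comparable pairs —
(i, j) comparable when tᵢ < tⱼ, tᵢ ≤ 5 years, i had the event; score ties
count ½.  The score is the predicted 5-year event probability
1 − exp(−H₀ₛ(5)·e^{lp}), with H₀ₛ the Breslow baseline of the subject's
stratum; for the "discrimination of the slope alone" line the score is the
sign-flipped slope itself.  Event rates per 100 person-years carry the
Poisson normal-approximation interval 100·(n ± 1.96√n)/PY floored at zero
— this is fixed as the method because it reproduces the published interval
arithmetic exactly.  Slope quartiles cut at the empirical 25/50/75
percentiles, values on a cut going to the lower quartile; the quartile
table degrades gracefully (to absent) when a degenerate mixed-model fit
collapses all BLUPs onto the population slope, which genuinely happens in
small homogeneous subgroups.

## The synthetic cohort generator

The generator is the study's stand-in for a seroconverter cohort and its
defaults are fixed study conditions, not tuning knobs: CD4 620 cells/µl at
seroconversion declining 60 cells/µl/year; intercept SD 150, slope SD 25
(linear regime) or τ = 60 with α = 20 (IOU regime); measurement error SD
80; exponential visit gaps of mean 0.4 years (a deterministic shared-grid
schedule is available for fast exact tests); test windows uniform on
(0, 1.64] years so the median window is 0.82 years; initiation below 350
cells/µl with probability 0.8 per visit, and at 4% of that rate above the
threshold — without that minority of above-threshold starts, a cohort
with a CD4 > 350 subgroup could not exist under a pure threshold rule;
log₁₀ viral load Normal(4.7, 0.8) at initiation, uncorrelated with slope
by default (the correlation is a config knob, default 0, because only "a
weak correlation" is documented, without a value); post-cART events
exponential with hazard 0.025/year at the centring point acting on
baseline CD4 (−0.30 per 100 cells), viral load (+0.30 per log₁₀), age
(+0.30 per 10 years) and prior AIDS (+0.80) — and on the true slope with
coefficient 0 by default, realising the null in which the slope carries no
signal beyond baseline covariates.  Events are drawn from covariates
frozen at initiation, matching the baseline-covariate outcome models; CD4
is floored at zero on observation only, never on the latent path; each
patient consumes an independent substream derived from (seed, index), so
enlarging a cohort never perturbs existing patients.

What the generator does not emulate: calendar trends in treatment
guidelines, regimen assignment, viral-load trajectories, inter-cohort
heterogeneity, and visit schedules reacting to disease state.  Passing
tests on these cohorts therefore demonstrate that the *pipeline* measures
what it claims under known conditions — not that real cohorts satisfy
those conditions.  One realistic feature deserves emphasis: because the
outcome hazard uses continuous baseline CD4 while the models stratify it
into four bands, some within-stratum confounding remains, and narrow-CI
slope variants can drift off the null in subgroups.  That is a faithful
rendering of why apparent slope effects deserve suspicion, not an artifact
to be removed.

## Problem sizes and runtime

The test suite simulates every dataset it uses and completes in a few
minutes on one core: mixed-model recovery at 1,000 patients, IOU recovery
at 500 patients on the informative dense design, profile-CI coverage for α
at 200 replicates of 150-patient shared-grid panels (each replicate fits
and profiles in well under a second thanks to the shared factorisation),
the headline null-pattern cohort at 2,000 patients, and the joint model at
250–300 patients.  The acceptance script re-runs the headline quantities
at the same sizes in under a minute.

## Known limitations

The IOU α is one-sided identified under routine monitoring designs; the
joint model's association is linear in the random effects while the
generator's truncation is a threshold rule, so its correction is partial
by construction; AIC is the only model-comparison tool offered for the
linear-vs-IOU choice; and the pre-treatment-era event generator anchors
event times to the calendar rather than to each patient's baseline visit,
a simplification that slightly blurs its baseline alignment.
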