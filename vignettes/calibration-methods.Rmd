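---
title: "Modelling energy expenditure from heart rate: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling energy expenditure from heart rate: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hr2ee)
```

This vignette documents the statistical model behind `hr2ee`, the
synthetic cohort generator it is exercised on, and the numerical and
design choices made where more than one reasonable option existed.

## The model

Energy expenditure is measured as oxygen uptake `EE` (ml O2/kg/min) at
five exertion levels per subject — rest, slow treadmill walking,
customary-pace walking, peak sustained (400 m fast) walking, and
maximal treadmill exertion. Within a subject the `HR`–`EE` relationship
is treated as linear, with subject-specific deviations of both the
intercept and the slope:

$$EE_{ij} = x_{ij}'\beta + b_{0i} + b_{1i}\,HR_{ij} + w_{ij},$$

with $(b_{0i}, b_{1i})$ jointly zero-mean bivariate normal with
unconstrained covariance $G$, and homoscedastic normal residuals
$w_{ij} \sim N(0, \sigma^2)$. Two fixed-effect parameterisations are
implemented:

* **stratified** — separate intercepts and heart-rate slopes for the
  four sex/age groups (men under 65 as the reference; "65 and older"
  means age ≥ 65), via indicator offsets
  `(1, G2, G3, G4, HR, HR·G2, HR·G3, HR·G4)`;
* **continuous** — `(1, HR, male, age, age·HR)`, replacing the age
  stratification with a continuous age effect and an age-by-heart-rate
  interaction.

Height is deliberately not a covariate (it adds nothing once weight
enters through the unit of `EE` and the kcal conversion); a `height`
column in input data is accepted and ignored. Heart rate is treated as
a fixed covariate — no measurement-error model — and the assumptions
worth remembering are linearity across the whole exertion range, a
*constant* residual variance across levels, and normal subject effects.

Estimation is by maximum likelihood (the default, and what all
headline numbers use) or REML. ML was chosen as the default because
the estimates it produces match the conventions of the mixed-model
software generation this analysis style comes from, and because the
cross-validation compares predictions, where the ML/REML difference is
immaterial at 232 training subjects.

## Fitting: profiled likelihood over variance components

The fitter is written from scratch rather than wrapping an existing
mixed-model package (which serves instead as an independent
cross-check in the test suite). For each subject, the marginal
covariance is $V_i = Z_i G Z_i' + \sigma^2 I$ with $Z_i = (1, HR)$.
Three structural facts keep this cheap:

* fixed effects enter linearly, so they are **profiled out by GLS** at
  every likelihood evaluation;
* $G$ is 2×2, so Woodbury/determinant-lemma identities reduce every
  per-subject quantity to arithmetic on the sufficient statistics
  $(n_i, \sum HR, \sum HR^2)$ and the crossproducts of $[X, y]$,
  precomputed once per dataset;
* the per-subject 2×2 operations vectorise across subjects, so one
  likelihood evaluation is a handful of matrix products regardless of
  cohort size.

The optimisation runs on an unconstrained scale: the log-Cholesky
factor of $G$ plus $\log\sigma$. This guarantees positive
semidefiniteness and stays smooth when the intercept–slope correlation
approaches the boundary — the fitted correlation is about −0.87, close
enough to −1 that a direct `(sd, sd, corr)` parameterisation would be
awkward. Three data-driven starts are used (a per-subject OLS moment
start, deliberately over-dispersed because it includes sampling noise,
plus the same scaled up and down threefold), each polished by BFGS on
numerical gradients and then Nelder–Mead, with relative convergence
tolerance `1e-10`. Fixed-effect standard errors come from the GLS
covariance (Wald z-tests, no degrees-of-freedom correction);
variance-component standard errors from the numerically differentiated
observed information, delta-method-mapped to the SD/correlation scale.

Degenerate corners are handled explicitly rather than left to the
optimiser:

* far off-optimum parameter values that overflow the determinant
  arithmetic return a large finite value instead of `NaN`;
* if the data are *exactly* interpolated by one common line (a
  zero-variance synthetic cohort), the likelihood is unbounded as
  $\sigma \to 0$; the fitter detects this (pooled OLS residuals at
  machine zero) and returns the OLS line with all variance components
  zero instead of racing the optimiser down a divergent ray;
* a rank-deficient fixed-effect design raises an error naming the
  collinear columns (e.g. constant heart rate, or a single-sex toy
  cohort under the continuous form);
* non-convergence is flagged in the returned object, not thrown.

## Subject calibration as conditional-normal prediction

"Calibrating" a subject with $k$ measurements means predicting that
subject's $(b_0, b_1)$ by the classical BLUP at plug-in estimates: with
residuals $r$ computed from the *training-fit* fixed effects (never a
per-subject refit — this mirrors applying a published equation plus
personal calibration points),

$$\hat b = G Z' (Z G Z' + \sigma^2 I)^{-1} r,\qquad
\mathrm{Cov} = G - G Z' (Z G Z' + \sigma^2 I)^{-1} Z G.$$

With $k = 0$ the prior is returned — mean zero, covariance $G$ — which
is exactly the "population equation" prediction. Prediction variance at
heart rate $h$ is $z' C z + \sigma^2$ with $z = (1, h)$, so it is
non-increasing in the calibration set (asserted as a property test).
If the fitted $G$ is essentially zero the posterior is the prior by
construction, avoiding a 0/0 solve.

The four calibration scenarios form the hierarchy studied throughout:
none, rest only, rest + peak sustained walking, all five levels.
"Peak" is the peak sustained *walking* test, not maximal exertion: the
second calibration point is meant to be obtainable in a corridor, and
it also spans the heart-rate range much better than a second low-end
point would.

## Cross-validation design

Each replicate splits *subjects* (never rows) 80/20 — stratified by the
four sex/age groups when the stratified model is used — with training
counts allocated per stratum by floor plus largest remainder. The model
is fitted to the training subjects; each validation subject is
calibrated per scenario from their own rows and predicted at **all
five** levels. Scoring calibration levels too keeps all four scenarios
on a common support (a `holdout_only` flag provides the sensitivity
analysis that scores only unseen levels). Errors are
observed − predicted, converted to kcal/min with *each subject's own
weight* (`kcal/min = EE · weight · 5/1000`; 5 kcal per litre of O2) —
the only choice under which subject-level errors mean anything — and
pooled across subjects and levels into one SD per scenario (n−1
denominator). Kernel density summaries use a Gaussian kernel on 512
points spanning mean ± 4 SD with Silverman's rule-of-thumb bandwidth.

Because a single 58-subject validation set is noisy, the default
surface is 20 seeded replicates with the per-replicate values reported
alongside their mean. One empirical caveat the test suite documents:
the *mean* scenario SDs decrease strictly along the calibration
hierarchy, but the none → rest-only step is small (≈0.18 kcal/min)
relative to per-replicate sampling noise (≈0.12), so individual
replicates can invert that one step. A single resting point mostly
helps, but its benefit is not certain in any given split; the larger
calibration steps are monotone in every replicate.

## The synthetic cohort generator

No individual-level data ship with the package; everything runs on
synthetic cohorts whose defaults are the study conditions themselves.

| parameter | default | units |
|---|---|---|
| cohort size | 290 | subjects |
| male fraction | 0.593 | — |
| age | 67.6 ± 11.5, truncated to [32, 90] | years |
| weight | 79.2 ± 14.4, truncated to [45, 140] | kg |
| HR level means | 61.2, 85.7, 97.8, 120.4, 148.6 | bpm |
| HR level SDs | 9.7, 12.9, 15.7, 19.8, 21.0 | bpm |
| HR age slopes | 0, 0, 0, −0.55, −1.05 | bpm/year |
| fixed effects (continuous) | −23.046, 0.339 (HR), 2.241 (male), 0.099 (age), −0.0007 (age·HR) | ml/kg/min scale |
| `sd_b0`, `sd_b1`, `corr_b`, `sd_resid` | 3.966, 0.062, −0.874, 2.787 | ml/kg/min; per bpm |

The stratified generating form instead uses the four fitted stratum
lines (intercepts −15.392, −14.960, −17.591, −17.055; slopes 0.296,
0.279, 0.297, 0.285) with its own variance components (4.007, 0.063,
−0.875, 2.785).

Choices the published marginal moments do not pin down, and how they
were resolved:

* **Truncated normals are mean-matched.** Naively truncating
  `N(67.6, 11.5²)` to [32, 90] drops the mean to 66.9 years because the
  interval is asymmetric; the generator solves for the underlying
  location so the *truncated* mean equals the target exactly. (The SD
  still shrinks slightly, to ≈10.7 — matching both moments would
  distort the shape more than it is worth.) Weight is treated the same
  way, and drawn independently of age and sex, since only pooled
  moments are available.
* **Within-subject heart-rate dependence.** Marginal per-level moments
  say nothing about how a subject's five heart rates co-move. A single
  latent "fitness" factor with loading 0.7 on every level encodes that
  fit subjects run low at every intensity. On top of it, the residual
  level noise is given an AR(1) correlation of 0.9 across adjacent
  levels. The AR component matters: with *independent* level noise,
  about a third of subjects would violate the protocol's non-decreasing
  HR ordering (the slow-walk → customary-walk gap is only ~12 bpm
  against ~14 bpm of noise), and enforcing the ordering by rejection
  would then distort the per-level means by up to 3 bpm. With the
  smooth residual process violations drop to ~1–2%, and rejection
  resampling (100 rounds, then a sort fallback with a warning) leaves
  every marginal mean within half a bpm of its target. Both parameters
  are configurable; this dependence structure is a modelling stand-in,
  not an estimated quantity.
* **HR age trend.** Per-level slopes (0, 0, 0, −0.55, −1.05) bpm/year,
  centred at 67.6 years, reproduce the decline of peak and maximal
  heart rate with age visible in group-level summaries; resting and
  ordinary walking heart rates are essentially age-flat.
* **Faithful noise over cosmetic realism.** EE errors are homoscedastic
  normal exactly as the model assumes, so a rare resting draw can be
  ≤ 0 ml/kg/min. No floor is applied by default (`ee_floor` exists for
  users who want one); clipping would make the generator disagree with
  the model the fitter estimates.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: heart-rate monitor and
metabolic-cart measurement error, level-dependent (heteroscedastic) EE
noise, non-normal subject effects, beta-blocker-style blunted HR
response, missing or invalid tests, and any EE pattern for
non-ambulatory activity. Tests passing on this generator show the
*pipeline* is correct under the model's own assumptions, not that the
model is right.

## Scales used by the checks

The test suite exercises oracle comparisons (dense multivariate-normal
likelihood on 3-subject toys, joint-normal conditioning for the BLUP,
two-parameter grid search against the optimiser) at toy sizes, module
properties at 10–200 subjects, and the headline comparisons at the
study's own scale: 20 replicate cross-validations on fresh cohorts of
290 (per model form) and 50 replicate fits for parameter recovery.
Those sizes make the Monte-Carlo error of the reported means small
relative to the tolerances checked (e.g. ±0.15 kcal/min on scenario
SDs) while the full suite still runs in a couple of minutes.

## Known limitations

* The two-regime ("flex heart rate") models used in some calibration
  literature — flat below a transition heart rate, linear above — are
  out of scope; the model is linear throughout.
* ML variance components carry the usual small downward bias relative
  to REML; at 290 subjects this is negligible for every quantity
  reported.
* The intra-person correlation summary is model-implied: with
  homoscedastic noise, a low-fitness subject with a narrow heart-rate
  range can show a low within-subject r even though the mean across
  subjects stays ≥ 0.95. Real graded-exertion data, with noise that
  grows with intensity less than the signal does, sits a little higher.
* Partially degenerate inputs (zero residual noise but non-zero subject
  effects) also have an unbounded likelihood; only the fully
  interpolated case is shortcut explicitly.
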