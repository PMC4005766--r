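# hr2ee

Estimating energy expenditure from heart rate in older adults, with and
without individual calibration.

## The problem

Heart rate is an attractive, cheap surrogate for free-living energy
expenditure because, within a person, oxygen uptake rises almost
perfectly linearly with heart rate. Across people, however, the line
differs substantially: two adults with the same age and sex can differ
by 1–2 kcal/min at the same heart rate, mostly through the intercept
(the resting, "flex" end of the line). A population regression equation
is therefore fine for group averages but can misstate an individual's
daily expenditure by hundreds of kcal. The practical question this
package quantifies: **how many individual calibration measurements
(0, 1, 2 or 5) are needed before heart-rate-based predictions become
individually accurate?**

`hr2ee` is aimed at biostatisticians and physiologists working with
graded exertion protocols (rest, slow walk, customary walk, peak
sustained walk, maximal exertion) in older cohorts. It provides:

* a **synthetic cohort generator** emulating such a protocol in a
  population aged 32–90 (mean 67.6 ± 11.5, 59.3% male, weight
  79.2 ± 14.4 kg), so the whole pipeline runs without access to any
  individual-level data;
* a from-scratch **linear mixed model fitter** (ML/REML, profiled
  likelihood) for the model

  ```
  EE_ij = x_ij' beta + b0_i + b1_i * HR_ij + w_ij,
  (b0_i, b1_i) ~ N(0, G) — unconstrained 2x2 covariance,
  w_ij ~ N(0, sigma^2),
  ```

  where `EE` is oxygen uptake (ml/kg/min), with two fixed-effect forms:
  *stratified* (separate intercept/slope for men/women under/over 65)
  and *continuous* (heart rate, sex, age, age×HR interaction);
* **subject calibration**: empirical-Bayes (BLUP) prediction of
  `(b0_i, b1_i)` from k calibration measurements by conditional-normal
  computation, and prediction of EE at any heart rate with prediction
  SDs;
* a **cross-validation harness**: replicate subject-level 80/20 splits,
  per-scenario prediction errors pooled in kcal/min
  (1 L O2 = 5 kcal), kernel density summaries, and intra-person
  correlation diagnostics.

## Worked example

```r
library(hr2ee)

cohort <- simulate_cohort(generator_config(seed = 1))
fit <- fit_hr_ee(cohort, model = "continuous", method = "ML")
round(fit$coefficients, 4)
#> (Intercept)          hr        male         age      age:hr
#>    -22.0174      0.3493      2.3600      0.0905     -0.0009
round(fit$vc, 4)
#>    sd_b0    sd_b1   corr_b sd_resid
#>   3.4815   0.0592  -0.8598   2.8216
```

The population equation says a 60-year-old man at 110 bpm spends about
18 ml O2/kg/min; `sd_b0` ≈ 3.5 says individuals deviate from that line
by several ml/kg/min, and `corr_b` ≈ −0.86 that high-intercept subjects
have flatter slopes. Within subjects the relationship is almost exactly
linear:

```r
intra_person_correlation(cohort)
#> Within-subject heart rate~energy expenditure correlation:
#>   mean r = 0.958 (range 0.293-0.999, 0 subject(s) excluded)
```

Calibrating one subject from their resting measurement alone and
predicting at 110 bpm:

```r
rest <- dplyr::filter(cohort, subject_id == "S0001", level == "rest")
re <- posterior_random_effects(fit, rest)
round(c(re$b0, re$b1), 4)
#> [1]  0.2215 -0.0003
```

The cross-validation quantifies what calibration buys at the cohort
level — the pooled SD of prediction errors (kcal/min) under no
calibration, rest only, rest + peak walking, and all five levels:

```r
cv <- run_scenarios(cohort, model = "continuous", replicates = 5, seed = 1)
summary(cv)
#> # A tibble: 4 x 5
#>   scenario  mean_sd sd_of_sd mean_error replicates
#>   <fct>       <dbl>    <dbl>      <dbl>      <int>
#> 1 none         2.08   0.210      0.0328          5
#> 2 rest_only    1.83   0.113      0.0166          5
#> 3 rest_peak    1.27   0.0781     0.0906          5
#> 4 all_five     1.00   0.0554     0.0116          5
```

Two calibration points already cut the error SD by ~0.8 kcal/min; five
cut it in half. `autoplot(cv)` draws the narrowing error densities, and
`plot_subject_calibration(fit, rest)` the population-versus-subject
lines. `run_full_experiment()` ties generation, both model fits and the
cross-validation into one seeded, file-producing run.

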