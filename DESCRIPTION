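Package: hr2ee
Title: Calibrated Estimation of Energy Expenditure from Heart Rate in
    Older Adults
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the linear relationship between heart rate
    and energy expenditure (oxygen uptake, ml/kg/min) in older adults with
    random-intercept/random-slope linear mixed models, and for quantifying
    how much individual calibration data improves person-level prediction.
    Includes a synthetic cohort generator emulating a five-level exertion
    protocol (rest through maximal exertion), a from-scratch profile
    likelihood mixed-model fitter (ML and REML) with a stratified and a
    continuous-age model form, empirical-Bayes (BLUP) prediction of
    subject-specific effects from 0, 1, 2 or 5 calibration measurements,
    and a subject-level cross-validation that summarises prediction error
    in kcal/min under each calibration scenario.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
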