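#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic cohort generator. The defaults
#' reproduce the study conditions the package models: a cohort of 290
#' community-dwelling older adults (age 67.6 +/- 11.5 years over 32--90,
#' 59.3% male, weight 79.2 +/- 14.4 kg) measured at five exertion levels
#' whose heart-rate means rise from 61.2 bpm at rest to 148.6 bpm at
#' maximal exertion, with energy expenditure generated from a
#' random-intercept/random-slope linear model on heart rate.
#'
#' Two generating model forms are available. The continuous-age form uses
#' the population equation `ee = intercept + b_hr*hr + b_male*male +
#' b_age*age + b_age_hr*age*hr` plus subject effects; the stratified form
#' uses a separate intercept and heart-rate slope per sex/age stratum.
#' Each form carries its own default fixed effects and variance
#' components (the fitted values of the corresponding model), so
#' `generator_config(model = "stratified")` is a complete parameter set.
#'
#' Heart rates are generated as `hr_ij = mean_j + age_slope_j*(age - age_center)
#' + lambda_j*f_i + e_ij`, where `f_i` is a standard-normal subject fitness
#' factor loading on every level (`lambda_j = hr_within_subject_corr * sd_j`)
#' and the residuals `e_ij` have an AR(1) correlation `hr_noise_ar` across
#' adjacent levels, so each level keeps its marginal `N(mean_j, sd_j^2)`
#' distribution while a subject's five heart rates move smoothly together.
#' Draws violating the protocol's non-decreasing ordering are resampled.
#'
#' @param n_subjects Default cohort size.
#' @param male_fraction Probability a subject is male.
#' @param age_mean,age_sd,age_bounds Mean, SD (years) and truncation bounds
#'   of the age distribution. The truncated normal is location-adjusted so
#'   its mean equals `age_mean` exactly.
#' @param weight_mean,weight_sd,weight_bounds Same for body weight (kg).
#' @param hr_level_means,hr_level_sds Per-level heart-rate means and SDs
#'   (bpm), one per exertion level in protocol order.
#' @param hr_age_slopes Per-level linear age trend of heart rate
#'   (bpm per year), centred at `hr_age_center`.
#' @param hr_age_center Reference age (years) for the heart-rate age trend.
#' @param hr_within_subject_corr Loading of the latent subject fitness
#'   factor, inducing within-subject coupling of the five heart rates.
#' @param hr_noise_ar AR(1) correlation of the residual heart-rate noise
#'   across adjacent exertion levels.
#' @param model Generating model form, `"continuous"` or `"stratified"`.
#' @param fixed_effects Fixed effects of the generating equation. For the
#'   continuous form a named vector with elements `intercept`, `hr`,
#'   `male`, `age`, `age_hr`; for the stratified form a list with
#'   `intercepts` and `slopes`, each of length four in stratum order
#'   `M<65, M>=65, F<65, F>=65`. `NULL` selects the form's defaults.
#' @param sd_b0 SD of the random intercept (ml/kg/min).
#' @param sd_b1 SD of the random heart-rate slope (ml/kg/min per bpm).
#' @param corr_b Correlation between random intercept and slope.
#' @param sd_resid Residual SD of energy expenditure (ml/kg/min).
#'   `NULL` for any of these selects the form's default.
#' @param ee_floor Optional lower bound applied to generated energy
#'   expenditure (ml/kg/min). The default `NULL` applies none: the
#'   homoscedastic normal errors the model assumes can produce a rare
#'   resting value at or below zero, and model faithfulness is preferred.
#' @param seed Default integer seed for [simulate_cohort()].
#'
#' @return An object of class `ee_generator_config` (a named list).
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' cfg <- generator_config(n_subjects = 50, seed = 42)
#' cfg$fixed_effects
generator_config <- function(n_subjects = 290L,
                             male_fraction = 0.593,
                             age_mean = 67.6,
                             age_sd = 11.5,
                             age_bounds = c(32, 90),
                             weight_mean = 79.2,
                             weight_sd = 14.4,
                             weight_bounds = c(45, 140),
                             hr_level_means = c(61.2, 85.7, 97.8, 120.4, 148.6),
                             hr_level_sds = c(9.7, 12.9, 15.7, 19.8, 21.0),
                             hr_age_slopes = c(0, 0, 0, -0.55, -1.05),
                             hr_age_center = 67.6,
                             hr_within_subject_corr = 0.7,
                             hr_noise_ar = 0.9,
                             model = c("continuous", "stratified"),
                             fixed_effects = NULL,
                             sd_b0 = NULL,
                             sd_b1 = NULL,
                             corr_b = NULL,
                             sd_resid = NULL,
                             ee_floor = NULL,
                             seed = 1L) {
  model <- arg_match(model)

  if (is.null(fixed_effects)) {
    fixed_effects <- switch(model,
      continuous = c(intercept = -23.046, hr = 0.339, male = 2.241,
                     age = 0.099, age_hr = -0.0007),
      stratified = list(
        intercepts = setNames(c(-15.392, -14.960, -17.591, -17.055), EE_STRATA),
        slopes     = setNames(c(0.296, 0.279, 0.297, 0.285), EE_STRATA)
      )
    )
  }
  vc_default <- switch(model,
    continuous = c(sd_b0 = 3.966, sd_b1 = 0.062, corr_b = -0.874, sd_resid = 2.787),
    stratified = c(sd_b0 = 4.007, sd_b1 = 0.063, corr_b = -0.875, sd_resid = 2.785)
  )
  sd_b0    <- sd_b0    %||% unname(vc_default["sd_b0"])
  sd_b1    <- sd_b1    %||% unname(vc_default["sd_b1"])
  corr_b   <- corr_b   %||% unname(vc_default["corr_b"])
  sd_resid <- sd_resid %||% unname(vc_default["sd_resid"])

  cfg <- list(
    n_subjects = as.integer(n_subjects),
    male_fraction = male_fraction,
    age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
    weight_mean = weight_mean, weight_sd = weight_sd,
    weight_bounds = weight_bounds,
    hr_level_means = setNames(as.numeric(hr_level_means), EE_LEVELS),
    hr_level_sds = setNames(as.numeric(hr_level_sds), EE_LEVELS),
    hr_age_slopes = setNames(as.numeric(hr_age_slopes), EE_LEVELS),
    hr_age_center = hr_age_center,
    hr_within_subject_corr = hr_within_subject_corr,
    hr_noise_ar = hr_noise_ar,
    model = model,
    fixed_effects = fixed_effects,
    sd_b0 = sd_b0, sd_b1 = sd_b1, corr_b = corr_b, sd_resid = sd_resid,
    ee_floor = ee_floor,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "ee_generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 1L)
  if (cfg$male_fraction < 0 || cfg$male_fraction > 1) {
    abort("`male_fraction` must lie in [0, 1].")
  }
  check_bounds <- function(b, what) {
    if (length(b) != 2 || b[1] >= b[2]) {
      abort(sprintf("`%s` must be an ordered pair (lower < upper).", what))
    }
  }
  check_bounds(cfg$age_bounds, "age_bounds")
  check_bounds(cfg$weight_bounds, "weight_bounds")
  sds <- c(cfg$age_sd, cfg$weight_sd, cfg$hr_level_sds,
           cfg$sd_b0, cfg$sd_b1, cfg$sd_resid)
  if (any(sds < 0)) abort("all standard deviations must be >= 0.")
  if (abs(cfg$corr_b) > 1) abort("`corr_b` must lie in [-1, 1].")
  if (abs(cfg$hr_within_subject_corr) > 1 || abs(cfg$hr_noise_ar) > 1) {
    abort("heart-rate correlations must lie in [-1, 1].")
  }
  for (nm in c("hr_level_means", "hr_level_sds", "hr_age_slopes")) {
    if (length(cfg[[nm]]) != 5L) {
      abort(sprintf("`%s` must have one value per exertion level (5).", nm))
    }
  }
  ## level means must increase at the reference age
  if (any(diff(cfg$hr_level_means) <= 0)) {
    abort("`hr_level_means` must be strictly increasing across levels.")
  }
  if (cfg$model == "continuous") {
    need <- c("intercept", "hr", "male", "age", "age_hr")
    if (!all(need %in% names(cfg$fixed_effects))) {
      abort("continuous-form `fixed_effects` needs: intercept, hr, male, age, age_hr.")
    }
  } else {
    if (!all(c("intercepts", "slopes") %in% names(cfg$fixed_effects)) ||
        length(cfg$fixed_effects$intercepts) != 4L ||
        length(cfg$fixed_effects$slopes) != 4L) {
      abort("stratified-form `fixed_effects` needs four intercepts and four slopes.")
    }
  }
  invisible(cfg)
}

#' @export
print.ee_generator_config <- function(x, ...) {
  cat("<ee_generator_config>\n")
  cat(sprintf("  cohort: n = %d, male fraction %.3f, age %.1f +/- %.1f [%g, %g]\n",
              x$n_subjects, x$male_fraction, x$age_mean, x$age_sd,
              x$age_bounds[1], x$age_bounds[2]))
  cat(sprintf("  weight: %.1f +/- %.1f kg [%g, %g]\n",
              x$weight_mean, x$weight_sd, x$weight_bounds[1], x$weight_bounds[2]))
  cat("  heart rate (bpm):\n")
  for (lv in EE_LEVELS) {
    cat(sprintf("    %-15s %6.1f +/- %4.1f  (age slope %+.2f bpm/yr)\n",
                lv, x$hr_level_means[lv], x$hr_level_sds[lv], x$hr_age_slopes[lv]))
  }
  cat(sprintf("  ee model: %s;  sd_b0 %.3f, sd_b1 %.3f, corr %.3f, sd_resid %.3f\n",
              x$model, x$sd_b0, x$sd_b1, x$corr_b, x$sd_resid))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
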