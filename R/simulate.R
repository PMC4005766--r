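## Truncated-normal sampler, location-adjusted so the truncated mean hits
## `target` exactly (plain truncation of an asymmetric interval would bias
## the mean, e.g. by -0.7 years for the default age distribution).
trunc_normal_location <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  f <- function(m) {
    a <- (lo - m) / sd
    b <- (hi - m) / sd
    m + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a)) - target
  }
  uniroot(f, interval = c(lo, hi), tol = 1e-10)$root
}

rtrunc_normal <- function(n, target, sd, lo, hi) {
  if (sd == 0) return(rep(target, n))
  m <- trunc_normal_location(target, sd, lo, hi)
  u <- runif(n, pnorm(lo, m, sd), pnorm(hi, m, sd))
  qnorm(u, m, sd)
}

#' Sample subject covariates
#'
#' Draws subject ages (truncated normal on the configured bounds,
#' mean-matched), sex (Bernoulli) and weight (truncated normal), and
#' derives the sex/age stratum.
#'
#' @param config An [generator_config()] object.
#' @param n Number of subjects (defaults to `config$n_subjects`).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A tibble with columns `subject_id`, `age`, `sex`, `weight_kg`,
#'   `stratum`.
#' @export
#' @examples
#' sample_subjects(generator_config(), n = 5, seed = 1)
sample_subjects <- function(config = generator_config(),
                            n = config$n_subjects,
                            seed = config$seed) {
  validate_generator_config(config)
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    age <- rtrunc_normal(n, config$age_mean, config$age_sd,
                         config$age_bounds[1], config$age_bounds[2])
    sex <- factor(ifelse(runif(n) < config$male_fraction, "M", "F"),
                  levels = c("M", "F"))
    weight <- rtrunc_normal(n, config$weight_mean, config$weight_sd,
                            config$weight_bounds[1], config$weight_bounds[2])
    tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age,
      sex = sex,
      weight_kg = weight,
      stratum = subject_stratum(age, sex)
    )
  })
}

#' Sample subject-level random effects
#'
#' Draws `(b0, b1)` pairs — subject deviations of the intercept
#' (ml/kg/min) and heart-rate slope (ml/kg/min per bpm) — from the
#' zero-mean bivariate normal with SDs `sd_b0`, `sd_b1` and correlation
#' `corr_b`.
#'
#' @param n Number of pairs.
#' @param sd_b0,sd_b1,corr_b Random-effect SDs and correlation.
#' @param seed Integer seed.
#' @return A tibble with columns `b0` and `b1`.
#' @export
#' @examples
#' sample_random_effects(3, 3.966, 0.062, -0.874, seed = 1)
sample_random_effects <- function(n, sd_b0, sd_b1, corr_b, seed = 1L) {
  if (sd_b0 < 0 || sd_b1 < 0 || abs(corr_b) > 1) {
    abort("implied random-effect covariance is not positive semidefinite.")
  }
  withr::with_seed(seed, {
    z0 <- rnorm(n)
    z1 <- rnorm(n)
    b0 <- sd_b0 * z0
    b1 <- sd_b1 * (corr_b * z0 + sqrt(1 - corr_b^2) * z1)
    tibble(b0 = b0, b1 = b1)
  })
}

## One heart-rate draw (n_subjects x 5) about per-subject level means
## `base`; residual noise has marginal sd `esd[j]` at level j and AR(1)
## correlation `ar` across adjacent levels.
draw_hr_noise <- function(k, esd, chol_ar) {
  (matrix(rnorm(k * 5L), k, 5L) %*% chol_ar) * rep(esd, each = k)
}

#' Sample per-level heart rates for a set of subjects
#'
#' Generates each subject's five heart rates as level mean + age trend +
#' latent fitness factor + correlated residual noise, then enforces the
#' protocol's non-decreasing ordering across levels by resampling the
#' noise (up to `max_retries` rounds); the rare subjects still unordered
#' are sorted, with a warning.
#'
#' @param subjects A tibble from [sample_subjects()] (needs `subject_id`,
#'   `age`).
#' @param config An [generator_config()] object.
#' @param seed Integer seed.
#' @param max_retries Resampling rounds before falling back to sorting.
#' @return A tibble with columns `subject_id`, `level` (ordered factor)
#'   and `hr_bpm`, five rows per subject, non-decreasing within subject.
#' @export
sample_heart_rates <- function(subjects, config = generator_config(),
                               seed = config$seed, max_retries = 100L) {
  validate_generator_config(config)
  n <- nrow(subjects)
  mu <- config$hr_level_means
  sds <- config$hr_level_sds
  rho <- config$hr_within_subject_corr
  lambda <- rho * sds
  esd <- sds * sqrt(1 - rho^2)
  R <- config$hr_noise_ar^abs(outer(1:5, 1:5, "-"))
  chol_ar <- chol(R)

  withr::with_seed(seed, {
    f <- rnorm(n)
    base <- matrix(mu, n, 5L, byrow = TRUE) +
      outer(subjects$age - config$hr_age_center, config$hr_age_slopes) +
      outer(f, lambda)
    hr <- base + draw_hr_noise(n, esd, chol_ar)
    bad <- which(.row_unordered(hr))
    tries <- 0L
    while (length(bad) > 0L && tries < max_retries) {
      tries <- tries + 1L
      hr[bad, ] <- base[bad, , drop = FALSE] +
        draw_hr_noise(length(bad), esd, chol_ar)
      bad <- bad[.row_unordered(hr[bad, , drop = FALSE])]
    }
    if (length(bad) > 0L) {
      warn(sprintf(
        "monotone heart-rate ordering not reached by resampling for %d subject(s); sorted their draws",
        length(bad)
      ))
      hr[bad, ] <- t(apply(hr[bad, , drop = FALSE], 1L, sort))
    }
    tibble(
      subject_id = rep(subjects$subject_id, each = 5L),
      level = factor(rep(EE_LEVELS, n), levels = EE_LEVELS, ordered = TRUE),
      hr_bpm = as.vector(t(hr))
    )
  })
}

.row_unordered <- function(m) {
  if (nrow(m) == 0L) return(logical(0))
  rowSums(m[, -1L, drop = FALSE] < m[, -5L, drop = FALSE]) > 0
}

## Fixed-effect linear predictor of the generating equation.
generator_linpred <- function(config, age, sex, stratum, hr) {
  if (config$model == "continuous") {
    fe <- config$fixed_effects
    male <- as.numeric(as.character(sex) == "M")
    fe[["intercept"]] + fe[["hr"]] * hr + fe[["male"]] * male +
      fe[["age"]] * age + fe[["age_hr"]] * age * hr
  } else {
    idx <- as.integer(stratum)
    unname(config$fixed_effects$intercepts[idx] +
             config$fixed_effects$slopes[idx] * hr)
  }
}

#' Simulate a synthetic cohort
#'
#' Generates a complete measurement table: subject covariates, five
#' ordered heart rates per subject, bivariate-normal subject effects, and
#' energy expenditure from the configured fixed-effect equation plus
#' `b0 + b1*hr` plus homoscedastic normal residuals.
#'
#' The result is deterministic given the seed; the seed and the full
#' parameter set are recorded in the `"ee_meta"` attribute.
#'
#' @param config An [generator_config()] object.
#' @param n Number of subjects (defaults to `config$n_subjects`).
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A tibble with one row per subject x exertion level and columns
#'   `subject_id`, `age`, `sex`, `weight_kg`, `stratum`, `level`,
#'   `hr_bpm`, `ee_mlkgmin`.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(n_subjects = 20, seed = 7))
#' dplyr::count(cohort, level)
simulate_cohort <- function(config = generator_config(),
                            n = config$n_subjects,
                            seed = config$seed) {
  validate_generator_config(config)
  ## independent sub-streams per stage, all derived from the one seed
  sub <- withr::with_seed(seed, sample.int(.Machine$integer.max, 4L))

  subjects <- sample_subjects(config, n = n, seed = sub[1])
  re <- sample_random_effects(n, config$sd_b0, config$sd_b1, config$corr_b,
                              seed = sub[2])
  hr <- sample_heart_rates(subjects, config, seed = sub[3])

  tab <- left_join(hr, subjects, by = "subject_id")
  idx <- match(tab$subject_id, subjects$subject_id)
  linpred <- generator_linpred(config, tab$age, tab$sex, tab$stratum, tab$hr_bpm)
  resid <- withr::with_seed(sub[4], rnorm(nrow(tab), 0, config$sd_resid))
  ee <- linpred + re$b0[idx] + re$b1[idx] * tab$hr_bpm + resid
  if (!is.null(config$ee_floor)) ee <- pmax(ee, config$ee_floor)

  out <- tab %>%
    mutate(ee_mlkgmin = ee) %>%
    select("subject_id", "age", "sex", "weight_kg", "stratum",
           "level", "hr_bpm", "ee_mlkgmin")
  attr(out, "ee_meta") <- list(seed = seed, n_subjects = n,
                               config = unclass(config))
  out
}
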