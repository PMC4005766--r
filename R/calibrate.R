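#' Calibration scenarios
#'
#' The four calibration scenarios of the cross-validation design: no
#' calibration data (subject effects set to zero), the resting
#' measurement only, rest plus peak sustained walking, and all five
#' exertion levels. "Peak" is the peak sustained (400 m fast) walking
#' test, not maximal treadmill exertion.
#'
#' @return A named list mapping scenario name to the exertion levels used
#'   for calibration.
#' @export
#' @examples
#' calibration_scenarios()
calibration_scenarios <- function() {
  list(
    none      = character(0),
    rest_only = "rest",
    rest_peak = c("rest", "peak_walk"),
    all_five  = EE_LEVELS
  )
}

#' Conditional (empirical-Bayes) prediction of subject random effects
#'
#' Predicts each subject's random intercept and slope from its
#' calibration measurements by conditional-normal computation under the
#' fitted model (the classical BLUP at plug-in parameter estimates):
#' with residuals `res = y - X beta` on the calibration rows and
#' `Z = (1, hr)` per row, the posterior mean is
#' `G Z' (Z G Z' + sigma^2 I)^-1 res` and the posterior covariance
#' `G - G Z' (Z G Z' + sigma^2 I)^-1 Z G`. A subject with no calibration
#' rows gets the prior: mean `(0, 0)` and covariance `G`.
#'
#' Residuals are computed with the supplied fit's fixed effects; the
#' model is never refitted per subject, mirroring the application of a
#' published equation plus personal calibration points.
#'
#' @param fit An `hr_ee_fit` (fitted or built with [hr_ee_model()]).
#' @param calib Calibration measurements in the cohort table format
#'   (columns `subject_id`, `age`, `sex`, `hr_bpm`, `ee_mlkgmin`). May
#'   cover several subjects; each subject's rows must share covariates.
#' @param subjects Optional character vector of subject ids to include in
#'   the output even when they contribute no calibration rows (they
#'   receive the prior).
#' @return A tibble with one row per subject: `subject_id`, `k_used`,
#'   `b0`, `b1`, `var_b0`, `cov_b0b1`, `var_b1`.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(n_subjects = 30, seed = 2))
#' fit <- fit_hr_ee(cohort)
#' calib <- dplyr::filter(cohort, level == "rest")
#' posterior_random_effects(fit, calib)
posterior_random_effects <- function(fit, calib, subjects = NULL) {
  if (!inherits(fit, "hr_ee_fit")) abort("`fit` must be an `hr_ee_fit`.")
  if (isFALSE(fit$converged)) {
    warn("using random-effect predictions from a non-converged fit")
  }
  G <- fit$G
  s2 <- fit$sigma^2

  prior_row <- function(id) tibble(
    subject_id = id, k_used = 0L, b0 = 0, b1 = 0,
    var_b0 = G[1, 1], cov_b0b1 = G[1, 2], var_b1 = G[2, 2]
  )

  ## a degenerate fit (no between-subject variance) has nothing to learn
  ## from calibration: every posterior is the (point-mass) prior
  if (max(abs(G)) < 1e-10) {
    ids <- unique(c(as.character(calib$subject_id %||% character(0)),
                    as.character(subjects %||% character(0))))
    return(bind_rows(map(ids, prior_row)))
  }

  out <- list()
  if (!is.null(calib) && nrow(calib) > 0L) {
    check_consistent_covariates(calib)
    X <- design_matrix(fit$model, calib, reference = fit$reference)
    r <- calib$ee_mlkgmin - drop(X %*% fit$coefficients)
    pieces <- split(seq_len(nrow(calib)), calib$subject_id)
    out <- imap(pieces, function(rows, id) {
      Z <- cbind(1, calib$hr_bpm[rows])
      Vi <- Z %*% G %*% t(Z) + s2 * diag(length(rows))
      K <- G %*% t(Z) %*% solve(Vi)          # 2 x k gain
      mu <- drop(K %*% r[rows])
      Cv <- G - K %*% Z %*% G
      tibble(subject_id = id, k_used = length(rows),
             b0 = mu[1], b1 = mu[2],
             var_b0 = Cv[1, 1], cov_b0b1 = (Cv[1, 2] + Cv[2, 1]) / 2,
             var_b1 = Cv[2, 2])
    })
  }
  done <- vapply(out, function(x) x$subject_id[1], character(1))
  extra <- setdiff(as.character(subjects %||% character(0)), done)
  out <- c(out, map(extra, prior_row))
  bind_rows(out)
}

check_consistent_covariates <- function(calib) {
  bad <- calib %>%
    group_by(.data$subject_id) %>%
    summarise(ok = length(unique(.data$age)) == 1L &&
                length(unique(as.character(.data$sex))) == 1L,
              .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0L) {
    abort(paste0("inconsistent covariates within subject(s): ",
                 paste(bad$subject_id, collapse = ", ")))
  }
  invisible(calib)
}

#' Predict energy expenditure from heart rate
#'
#' Computes predicted energy expenditure (ml/kg/min) at given heart
#' rates, either at the population level (subject effects set to zero)
#' or for specific subjects using random-effect predictions from
#' [posterior_random_effects()]. The prediction SD is
#' `sqrt(z' C z + sigma^2)` with `z = (1, hr)` and `C` the subject's
#' posterior covariance (the prior `G` for population predictions): the
#' uncertainty of a new measurement of that subject.
#'
#' @param fit An `hr_ee_fit`.
#' @param new_data A tibble of query rows with columns `age`, `sex`,
#'   `hr_bpm`, optionally `subject_id` (for joining `ranef`) and
#'   `weight_kg` (adds kcal/min columns).
#' @param ranef Optional tibble from [posterior_random_effects()];
#'   joined by `subject_id`. Rows without a match get the population
#'   prediction.
#' @return `new_data` plus `ee_pred_mlkgmin`, `pred_sd_mlkgmin`, and —
#'   when `weight_kg` is present — `ee_pred_kcalmin`, `pred_sd_kcalmin`.
#' @export
#' @examples
#' eq <- hr_ee_model(c(-23.046, 0.339, 2.241, 0.099, -0.0007),
#'                   vc = c(sd_b0 = 3.966, sd_b1 = 0.062,
#'                          corr_b = -0.874, sd_resid = 2.787))
#' predict_ee(eq, tibble::tibble(age = 55.5, sex = "M",
#'                               hr_bpm = c(62, 167.7)))
predict_ee <- function(fit, new_data, ranef = NULL) {
  if (!inherits(fit, "hr_ee_fit")) abort("`fit` must be an `hr_ee_fit`.")
  stopifnot(all(c("age", "sex", "hr_bpm") %in% names(new_data)))
  hr <- new_data$hr_bpm
  if (any(hr < 30 | hr > 220)) {
    warn("heart rate outside the plausible physiologic range (30-220 bpm)")
  }
  X <- design_matrix(fit$model, new_data, reference = fit$reference)
  mu <- drop(X %*% fit$coefficients)

  b0 <- rep(0, nrow(new_data)); b1 <- rep(0, nrow(new_data))
  c11 <- rep(fit$G[1, 1], nrow(new_data))
  c12 <- rep(fit$G[1, 2], nrow(new_data))
  c22 <- rep(fit$G[2, 2], nrow(new_data))
  if (!is.null(ranef)) {
    if (!"subject_id" %in% names(new_data)) {
      abort("`new_data` needs `subject_id` to use `ranef`.")
    }
    idx <- match(new_data$subject_id, ranef$subject_id)
    hit <- !is.na(idx)
    b0[hit] <- ranef$b0[idx[hit]]
    b1[hit] <- ranef$b1[idx[hit]]
    c11[hit] <- ranef$var_b0[idx[hit]]
    c12[hit] <- ranef$cov_b0b1[idx[hit]]
    c22[hit] <- ranef$var_b1[idx[hit]]
  }
  pred <- mu + b0 + b1 * hr
  pvar <- c11 + 2 * c12 * hr + c22 * hr^2 + fit$sigma^2
  out <- new_data %>%
    mutate(ee_pred_mlkgmin = pred, pred_sd_mlkgmin = sqrt(pmax(pvar, 0)))
  if ("weight_kg" %in% names(new_data)) {
    out <- out %>%
      mutate(
        ee_pred_kcalmin = to_kcal_per_min(.data$ee_pred_mlkgmin, .data$weight_kg),
        pred_sd_kcalmin = to_kcal_per_min(.data$pred_sd_mlkgmin, .data$weight_kg)
      )
  }
  out
}

#' Convert oxygen uptake to energy expenditure in kcal/min
#'
#' Uses the standard energetic equivalent of 5 kcal per litre of oxygen:
#' `kcal/min = VO2(ml/kg/min) * weight(kg) / 1000 * 5`.
#'
#' @param ee Oxygen uptake in ml/kg/min.
#' @param weight_kg Body weight in kg (must be positive).
#' @return Energy expenditure in kcal/min.
#' @export
#' @examples
#' to_kcal_per_min(2.787, 79.2)
to_kcal_per_min <- function(ee, weight_kg) {
  if (any(weight_kg <= 0)) abort("`weight_kg` must be positive.")
  ee * weight_kg / 1000 * 5
}

#' Extrapolate a per-minute bias to a per-day bias
#'
#' A constant prediction bias in kcal/min accumulates over the 1440
#' minutes of a day; the sign (over- vs underestimation) is preserved.
#'
#' @param bias_kcal_min Bias in kcal/min.
#' @return Bias in kcal/day.
#' @export
#' @examples
#' daily_bias(0.35)  # ~500 kcal/day
daily_bias <- function(bias_kcal_min) bias_kcal_min * 1440
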