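#' Plot population heart-rate / energy-expenditure lines
#'
#' Draws the fitted population-level relationship between heart rate and
#' energy expenditure for chosen ages and sexes, optionally over the
#' measurement scatter.
#'
#' @param object An `hr_ee_fit`.
#' @param data Optional cohort tibble plotted as points behind the lines.
#' @param ages Ages (years) at which to draw population lines.
#' @param sexes Sexes for which to draw lines.
#' @param hr_range Heart-rate range (bpm) spanned by the lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hr_ee_fit <- function(object, data = NULL, ages = c(55, 75),
                               sexes = c("M", "F"), hr_range = c(50, 170),
                               ...) {
  grid <- tidyr::expand_grid(
    age = ages, sex = sexes,
    hr_bpm = seq(hr_range[1], hr_range[2], length.out = 50)
  )
  grid <- predict_ee(object, grid)
  grid$group <- sprintf("%s, age %g", grid$sex, grid$age)
  p <- ggplot2::ggplot()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data,
      ggplot2::aes(x = .data$hr_bpm, y = .data$ee_mlkgmin),
      alpha = 0.2, size = 0.6, colour = "grey50")
  }
  p +
    ggplot2::geom_line(
      data = grid,
      ggplot2::aes(x = .data$hr_bpm, y = .data$ee_pred_mlkgmin,
                   colour = .data$group), linewidth = 0.8) +
    ggplot2::labs(x = "heart rate (bpm)", y = "energy expenditure (ml/kg/min)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot prediction-error densities by calibration scenario
#'
#' Kernel density estimates of the pooled prediction errors for each
#' calibration scenario, mirroring how the cross-validation results are
#' usually displayed: distributions narrow as calibration data
#' accumulate.
#'
#' @param object An `ee_cv` object from [run_scenarios()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ee_cv <- function(object, ...) {
  dens <- object$errors %>%
    group_by(.data$scenario) %>%
    dplyr::group_modify(~ error_density(.x$error_kcal_min)) %>%
    ungroup() %>%
    mutate(scenario = factor(.data$scenario, levels = names(object$scenarios)))
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                     colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "prediction error (kcal/min)", y = "density",
                  colour = "calibration") +
    ggplot2::theme_minimal()
}

#' Population versus subject-specific prediction lines
#'
#' Illustrates the individual-calibration story for one subject: the
#' population line (random effects set to zero) against the
#' subject-specific line obtained by conditioning on that subject's
#' calibration measurements, with the calibration points overlaid.
#'
#' @param fit An `hr_ee_fit`.
#' @param calib Calibration rows for a single subject (cohort format).
#' @param hr_range Heart-rate range (bpm) for the lines.
#' @return A ggplot object.
#' @export
plot_subject_calibration <- function(fit, calib, hr_range = c(50, 170)) {
  stopifnot(length(unique(calib$subject_id)) == 1L)
  re <- posterior_random_effects(fit, calib)
  base <- tibble(
    subject_id = calib$subject_id[1], age = calib$age[1], sex = calib$sex[1],
    hr_bpm = seq(hr_range[1], hr_range[2], length.out = 50)
  )
  pop <- predict_ee(fit, base)
  subj <- predict_ee(fit, base, ranef = re)
  lines <- bind_rows(
    mutate(pop, line = "population (no calibration)"),
    mutate(subj, line = "subject-specific (calibrated)")
  )
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = lines,
      ggplot2::aes(x = .data$hr_bpm, y = .data$ee_pred_mlkgmin,
                   colour = .data$line), linewidth = 0.9) +
    ggplot2::geom_point(
      data = calib,
      ggplot2::aes(x = .data$hr_bpm, y = .data$ee_mlkgmin), size = 2) +
    ggplot2::labs(x = "heart rate (bpm)", y = "energy expenditure (ml/kg/min)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
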