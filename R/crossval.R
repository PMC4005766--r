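#' Split subjects into training and validation sets
#'
#' Subject-level random split. With `stratified = TRUE` the split is
#' performed within each of the four sex/age strata; training counts are
#' allocated per stratum by floor with largest-remainder assignment, so
#' the overall training fraction is within one subject of `frac` and so
#' is each stratum's.
#'
#' @param data A cohort measurement table (one or more rows per subject).
#' @param frac Training fraction in (0, 1).
#' @param stratified Stratify the randomisation by sex/age stratum?
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A tibble with columns `subject_id`, `stratum`, `set`
#'   (`"training"`/`"validation"`), carrying the seed as attribute
#'   `"seed"`.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(n_subjects = 20, seed = 3))
#' table(split_subjects(cohort, 0.8, seed = 1)$set)
split_subjects <- function(data, frac = 0.8, stratified = FALSE, seed = 1L) {
  if (frac <= 0 || frac >= 1) abort("`frac` must lie strictly in (0, 1).")
  subjects <- data %>%
    distinct(.data$subject_id, .keep_all = TRUE) %>%
    mutate(stratum = subject_stratum(.data$age, .data$sex)) %>%
    select("subject_id", "stratum")

  groups <- if (stratified) split(subjects, subjects$stratum, drop = TRUE) else
    list(all = subjects)
  sizes <- vapply(groups, nrow, integer(1))
  if (stratified && any(sizes < 2L)) {
    abort("stratified splitting needs at least 2 subjects per stratum.")
  }

  ## per-group training counts: floor, then largest remainders take the
  ## seats left to reach round(frac * N)
  raw <- frac * sizes
  n_train <- floor(raw)
  left <- round(frac * sum(sizes)) - sum(n_train)
  if (left > 0) {
    order_rem <- order(raw - n_train, decreasing = TRUE)
    n_train[order_rem[seq_len(left)]] <- n_train[order_rem[seq_len(left)]] + 1L
  }
  n_train <- pmin(pmax(n_train, 1L), sizes - 1L)  # both sets nonempty per group

  out <- withr::with_seed(seed, {
    bind_rows(map2(groups, n_train, function(g, k) {
      tr <- sample(g$subject_id, k)
      g$set <- ifelse(g$subject_id %in% tr, "training", "validation")
      g
    }))
  })
  out <- arrange(out, .data$subject_id)
  attr(out, "seed") <- seed
  out
}

#' Cross-validated prediction error under calibration scenarios
#'
#' Runs the full cross-validation experiment: in each replicate, subjects
#' are split 80/20 (at the subject level, optionally stratified by
#' sex/age group), the mixed model is fitted to the training subjects,
#' and each validation subject's energy expenditure is predicted at all
#' five exertion levels under each calibration scenario — the subject's
#' random effects being predicted from the scenario's calibration rows
#' (none, rest, rest+peak, or all five). Prediction errors
#' (observed − predicted) are converted to kcal/min with each subject's
#' own weight and pooled across validation subjects and levels; the
#' pooled SD (n−1 denominator) per scenario is the headline summary.
#'
#' @param data A cohort measurement table with all five levels per
#'   subject.
#' @param model `"continuous"` or `"stratified"` (the stratified form
#'   also stratifies the split by default).
#' @param scenarios Named list of calibration level sets, as from
#'   [calibration_scenarios()].
#' @param frac Training fraction.
#' @param stratified Stratify the split? Defaults to `TRUE` for the
#'   stratified model form.
#' @param replicates Number of replicate splits.
#' @param seed Integer seed; replicate `r` uses `seed + r - 1`.
#' @param method Estimation method passed to [fit_hr_ee()].
#' @param holdout_only If `TRUE`, score only the levels *not* used for
#'   calibration in each scenario (sensitivity analysis); by default all
#'   five levels are scored so scenarios share a common support.
#' @return An object of class `ee_cv`: a list with `$summary` (tibble:
#'   `replicate`, `scenario`, `n_errors`, `mean`, `sd`), `$errors`
#'   (tibble of pooled errors in kcal/min), and the run settings. See
#'   [tidy.ee_cv()], [summary.ee_cv()], [autoplot.ee_cv()].
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(n_subjects = 60, seed = 5))
#' cv <- run_scenarios(cohort, replicates = 2, seed = 1)
#' summary(cv)
run_scenarios <- function(data,
                          model = c("continuous", "stratified"),
                          scenarios = calibration_scenarios(),
                          frac = 0.8,
                          stratified = NULL,
                          replicates = 20L,
                          seed = 1L,
                          method = "ML",
                          holdout_only = FALSE) {
  model <- arg_match(model)
  stratified <- stratified %||% (model == "stratified")
  data <- validate_cohort(data, quiet = TRUE)

  res <- list()
  for (r in seq_len(replicates)) {
    rep_seed <- seed + r - 1L
    sp <- split_subjects(data, frac = frac, stratified = stratified,
                         seed = rep_seed)
    train_ids <- sp$subject_id[sp$set == "training"]
    training <- filter(data, .data$subject_id %in% train_ids)
    validation <- filter(data, !.data$subject_id %in% train_ids)

    fit <- fit_hr_ee(training, model = model, method = method)
    if (isFALSE(fit$converged)) {
      warn(sprintf("replicate %d: training fit did not converge; replicate excluded", r))
      next
    }

    for (sc in names(scenarios)) {
      lv <- scenarios[[sc]]
      calib <- filter(validation, .data$level %in% lv)
      ranef <- if (nrow(calib) > 0L) {
        posterior_random_effects(fit, calib,
                                 subjects = unique(validation$subject_id))
      } else NULL
      score <- if (holdout_only && length(lv) > 0L && length(lv) < 5L) {
        filter(validation, !.data$level %in% lv)
      } else validation
      pred <- predict_ee(fit, score, ranef = ranef)
      err <- to_kcal_per_min(pred$ee_mlkgmin - pred$ee_pred_mlkgmin,
                             pred$weight_kg)
      res[[length(res) + 1L]] <- tibble(
        replicate = r, scenario = sc,
        subject_id = pred$subject_id, level = as.character(pred$level),
        error_kcal_min = err
      )
    }
  }
  errors <- bind_rows(res)
  if (nrow(errors) == 0L) abort("no replicate produced a converged training fit.")
  summary_tbl <- errors %>%
    group_by(.data$replicate, .data$scenario) %>%
    summarise(n_errors = dplyr::n(), mean = mean(.data$error_kcal_min),
              sd = sd(.data$error_kcal_min), .groups = "drop") %>%
    mutate(scenario = factor(.data$scenario, levels = names(scenarios)))

  structure(list(
    summary = summary_tbl, errors = errors, model = model,
    scenarios = scenarios, frac = frac, stratified = stratified,
    replicates = replicates, seed = seed, holdout_only = holdout_only
  ), class = "ee_cv")
}

#' @export
print.ee_cv <- function(x, ...) {
  cat(sprintf("Cross-validated prediction error (%s form, %d replicate(s))\n",
              x$model, length(unique(x$summary$replicate))))
  print(summary(x))
  invisible(x)
}

#' Per-scenario summary of a cross-validation run
#'
#' Averages the per-replicate pooled error SD and mean over replicates.
#'
#' @param object An `ee_cv` object.
#' @param ... Unused.
#' @return A tibble: `scenario`, `mean_sd` (kcal/min, averaged over
#'   replicates), `sd_of_sd`, `mean_error`, `replicates`.
#' @export
summary.ee_cv <- function(object, ...) {
  object$summary %>%
    group_by(.data$scenario) %>%
    summarise(mean_sd = mean(.data$sd), sd_of_sd = sd(.data$sd),
              mean_error = mean(.data$mean), replicates = dplyr::n(),
              .groups = "drop")
}

#' Tidy a cross-validation result
#'
#' @param x An `ee_cv` object.
#' @param ... Unused.
#' @return The per-replicate, per-scenario summary tibble.
#' @export
tidy.ee_cv <- function(x, ...) x$summary

#' Kernel density estimate of prediction errors
#'
#' Gaussian-kernel density on 512 evenly spaced points spanning
#' mean ± 4 SD, with Silverman's rule-of-thumb bandwidth by default.
#'
#' @param errors Numeric vector of prediction errors (kcal/min), length
#'   at least 2.
#' @param bw Bandwidth: a number, or a rule name accepted by
#'   [stats::density()] (default `"nrd0"`, Silverman's rule).
#' @return A tibble with columns `x` and `density`. Zero-variance input
#'   yields a one-row point-mass representation (`density = Inf`) with a
#'   warning.
#' @export
#' @examples
#' err <- rnorm(1000)
#' d <- error_density(err)
#' sum(d$density) * diff(d$x[1:2])  # ~1
error_density <- function(errors, bw = "nrd0") {
  if (length(errors) < 2L) abort("need at least 2 errors.")
  s <- sd(errors)
  if (s == 0) {
    warn("zero-variance errors: returning a point mass")
    return(tibble(x = errors[1], density = Inf))
  }
  m <- mean(errors)
  d <- density(errors, bw = bw, kernel = "gaussian", n = 512L,
               from = m - 4 * s, to = m + 4 * s)
  tibble(x = d$x, density = d$y)
}

#' Within-subject correlation of heart rate and energy expenditure
#'
#' Pearson correlation of a subject's five (heart rate, energy
#' expenditure) pairs, summarised across subjects. Subjects with no
#' heart-rate variance have an undefined correlation; they are reported
#' as `NA` and excluded from the summary, with a warning.
#'
#' @param data A cohort measurement table.
#' @return An object of class `ee_ipc`: a list with `$per_subject`
#'   (tibble `subject_id`, `r`), `$mean_r`, `$min_r`, `$max_r`,
#'   `$n_excluded`.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(n_subjects = 50, seed = 4))
#' intra_person_correlation(cohort)
intra_person_correlation <- function(data) {
  per <- data %>%
    group_by(.data$subject_id) %>%
    summarise(
      n_levels = dplyr::n(),
      r = if (var(.data$hr_bpm) > 0) cor(.data$hr_bpm, .data$ee_mlkgmin)
          else NA_real_,
      .groups = "drop"
    )
  if (any(per$n_levels < 3L)) {
    warn("some subjects have fewer than 3 measurements; their r is unstable")
  }
  n_excl <- sum(is.na(per$r))
  if (n_excl > 0L) {
    warn(sprintf("%d subject(s) with constant heart rate excluded from the summary",
                 n_excl))
  }
  ok <- per$r[!is.na(per$r)]
  structure(list(
    per_subject = select(per, "subject_id", "r"),
    mean_r = mean(ok), min_r = min(ok), max_r = max(ok),
    n_excluded = n_excl
  ), class = "ee_ipc")
}

#' @export
print.ee_ipc <- function(x, ...) {
  cat(sprintf(
    "Within-subject heart rate~energy expenditure correlation:\n  mean r = %.3f (range %.3f-%.3f, %d subject(s) excluded)\n",
    x$mean_r, x$min_r, x$max_r, x$n_excluded))
  invisible(x)
}

#' @export
tidy.ee_ipc <- function(x, ...) x$per_subject
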