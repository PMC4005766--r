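COHORT_COLS <- c("subject_id", "age", "sex", "weight_kg", "level",
                 "hr_bpm", "ee_mlkgmin")

#' Validate a cohort measurement table
#'
#' Checks a measurement table (or a CSV file) against the cohort schema:
#' required columns, known exertion-level labels, sex in `{M, F}`, no
#' duplicated subject-by-level rows and — when `complete = TRUE` — exactly
#' five rows per subject, one per level. Schema violations are errors
#' naming the offending subjects/levels; physiologically implausible
#' values (heart rate outside 30–220 bpm, energy expenditure outside
#' 0–70 ml/kg/min) only raise warnings.
#'
#' @param x A data frame or the path to a cohort CSV.
#' @param complete Require the full five-level protocol per subject?
#' @param quiet Suppress range warnings?
#' @return The validated table as a tibble, with `level` as an ordered
#'   factor, `sex` as a factor and a derived `stratum` column.
#' @export
validate_cohort <- function(x, complete = TRUE, quiet = FALSE) {
  if (is.character(x)) {
    if (!file.exists(x)) abort(sprintf("file not found: %s", x))
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- as_tibble(x)
  missing_cols <- setdiff(setdiff(COHORT_COLS, c("weight_kg")), names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_lv <- setdiff(unique(as.character(x$level)), EE_LEVELS)
  if (length(bad_lv) > 0L) {
    abort(paste0("unknown exertion level label(s): ",
                 paste(bad_lv, collapse = ", ")))
  }
  if (!all(as.character(x$sex) %in% c("M", "F"))) {
    abort("`sex` must be \"M\" or \"F\".")
  }
  x <- x %>%
    mutate(
      subject_id = as.character(.data$subject_id),
      level = factor(as.character(.data$level), levels = EE_LEVELS,
                     ordered = TRUE),
      sex = factor(as.character(.data$sex), levels = c("M", "F")),
      stratum = subject_stratum(.data$age, .data$sex)
    )

  dup <- x %>%
    dplyr::count(.data$subject_id, .data$level) %>%
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("duplicated subject x level row(s): ",
                 paste(paste0(dup$subject_id, "/", dup$level), collapse = ", ")))
  }
  if (complete) {
    counts <- x %>% dplyr::count(.data$subject_id)
    short <- counts$subject_id[counts$n != 5L]
    if (length(short) > 0L) {
      missing_lv <- x %>%
        filter(.data$subject_id %in% short) %>%
        group_by(.data$subject_id) %>%
        summarise(missing = paste(setdiff(EE_LEVELS, as.character(.data$level)),
                                  collapse = "+"), .groups = "drop")
      abort(paste0(
        "incomplete five-level protocol for subject(s): ",
        paste(paste0(missing_lv$subject_id, " (missing ", missing_lv$missing, ")"),
              collapse = ", ")))
    }
  }
  if (any(x$hr_bpm <= 0)) abort("non-positive heart rate.")
  if (!is.null(x$weight_kg) && any(x$weight_kg <= 0)) {
    abort("non-positive weight.")
  }
  if (!quiet) {
    if (any(x$hr_bpm < 30 | x$hr_bpm > 220)) {
      warn("heart rate value(s) outside 30-220 bpm")
    }
    if (any(x$ee_mlkgmin < 0 | x$ee_mlkgmin > 70)) {
      warn("energy expenditure value(s) outside 0-70 ml/kg/min")
    }
  }
  x
}

#' Read a cohort CSV
#'
#' Reads and validates a cohort table written by [write_cohort()] (or any
#' CSV with the columns `subject_id, age, sex, weight_kg, level, hr_bpm,
#' ee_mlkgmin`).
#'
#' @param path CSV path.
#' @param ... Passed to [validate_cohort()].
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, ...) validate_cohort(path, ...)

#' Write a cohort CSV (with generation metadata sidecar)
#'
#' Writes the standard cohort columns to `path`; if the table carries
#' generation metadata (the `"ee_meta"` attribute set by
#' [simulate_cohort()]), it is written alongside as
#' `<path>_meta.json`, making the file pair self-describing and
#' reproducible.
#'
#' @param data A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- data %>%
    mutate(sex = as.character(.data$sex), level = as.character(.data$level)) %>%
    select(dplyr::any_of(COHORT_COLS))
  readr::write_csv(out, path)
  meta <- attr(data, "ee_meta")
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(sub("\\.[^./]+$", "", path), "_meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a fitted model as JSON
#'
#' Serialises coefficients, standard errors, variance components,
#' log-likelihood and convergence metadata.
#'
#' @param fit An `hr_ee_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  se <- if (is.null(fit$vcov)) NULL else sqrt(diag(fit$vcov))
  jsonlite::write_json(list(
    model = fit$model, method = fit$method, reference = fit$reference,
    coefficients = as.list(fit$coefficients),
    se_fixed = if (is.null(se)) NULL else as.list(se),
    variance_components = as.list(fit$vc),
    se_variance_components = as.list(fit$se_vc),
    loglik = fit$loglik, converged = fit$converged,
    n_subjects = fit$n_subjects, n_obs = fit$n_obs
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
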