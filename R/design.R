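#' Fixed-effect design row
#'
#' Builds the fixed-effect covariate vector for one measurement under
#' either model form. The continuous-age form uses
#' `(1, hr, male, age, age*hr)`; the stratified form uses the reference
#' stratum's intercept and slope plus indicator offsets for the other
#' three strata: `(1, G2, G3, G4, hr, hr*G2, hr*G3, hr*G4)`, where G2-G4
#' indicate men 65 and older, women under 65, and women 65 and older
#' (men under 65 are the default reference). The random-effect design row
#' is always `(1, hr)`.
#'
#' @param model `"continuous"` or `"stratified"`.
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param hr Heart rate (bpm).
#' @param reference Reference stratum for the stratified form.
#' @return A named numeric vector (length 5 or 8).
#' @export
#' @examples
#' design_row("stratified", age = 70, sex = "M", hr = 100)
#' design_row("continuous", age = 60, sex = "F", hr = 90)
design_row <- function(model = c("continuous", "stratified"),
                       age, sex, hr, reference = "M<65") {
  model <- arg_match(model)
  drop(design_matrix(model,
                     tibble(age = age, sex = sex, hr_bpm = hr),
                     reference = reference))
}

## Vectorised design matrix; rows follow `data`.
design_matrix <- function(model, data, reference = "M<65") {
  hr <- data$hr_bpm
  if (model == "continuous") {
    male <- as.numeric(as.character(data$sex) == "M")
    X <- cbind(1, hr, male, data$age, data$age * hr)
    colnames(X) <- c("(Intercept)", "hr", "male", "age", "age:hr")
  } else {
    if (!reference %in% EE_STRATA) {
      abort(sprintf("unknown reference stratum \"%s\".", reference))
    }
    stratum <- subject_stratum(data$age, data$sex)
    others <- setdiff(EE_STRATA, reference)
    ind <- vapply(others, function(s) as.numeric(stratum == s),
                  numeric(length(hr)))
    if (length(hr) == 1L) ind <- matrix(ind, nrow = 1L)
    X <- cbind(1, ind, hr, ind * hr)
    gl <- paste0("G[", others, "]")
    colnames(X) <- c("(Intercept)", gl, "hr", paste0("hr:", gl))
  }
  X
}

n_fixef <- function(model) if (model == "continuous") 5L else 8L
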