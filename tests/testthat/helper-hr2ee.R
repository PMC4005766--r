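# Shared fixtures, all generated in code.

small_cohort <- function(n = 40, seed = 1, model = "continuous", ...) {
  simulate_cohort(generator_config(n_subjects = n, model = model,
                                   seed = seed, ...))
}

# Variance components of the continuous-age generating model.
TRUTH_VC <- list(sd_b0 = 3.966, sd_b1 = 0.062, corr_b = -0.874,
                 sd_resid = 2.787)
TRUTH_FE <- c(intercept = -23.046, hr = 0.339, male = 2.241,
              age = 0.099, age_hr = -0.0007)

vc_to_G_mat <- function(vc) {
  g12 <- vc$corr_b * vc$sd_b0 * vc$sd_b1
  matrix(c(vc$sd_b0^2, g12, g12, vc$sd_b1^2), 2)
}

table3_equation <- function() {
  hr_ee_model(TRUTH_FE, vc = unlist(TRUTH_VC), model = "continuous")
}

# Independent dense evaluation of the marginal negative log-likelihood:
# block-diagonal V assembled subject by subject, GLS fixed effects by a
# direct solve, joint normal density summed per subject.
dense_nll <- function(cohort, model, vc, method = "ML") {
  X <- hr2ee:::design_matrix(model, cohort)
  y <- cohort$ee_mlkgmin
  G <- vc_to_G_mat(vc)
  s2 <- vc$sd_resid^2
  ids <- unique(cohort$subject_id)
  Vi_list <- lapply(ids, function(i) {
    k <- which(cohort$subject_id == i)
    Z <- cbind(1, cohort$hr_bpm[k])
    solve(Z %*% G %*% t(Z) + s2 * diag(length(k)))
  })
  XtVX <- matrix(0, ncol(X), ncol(X))
  XtVy <- numeric(ncol(X))
  for (j in seq_along(ids)) {
    k <- which(cohort$subject_id == ids[j])
    XtVX <- XtVX + t(X[k, , drop = FALSE]) %*% Vi_list[[j]] %*% X[k, , drop = FALSE]
    XtVy <- XtVy + t(X[k, , drop = FALSE]) %*% Vi_list[[j]] %*% y[k]
  }
  beta <- solve(XtVX, XtVy)
  r <- y - X %*% beta
  nll <- 0
  for (j in seq_along(ids)) {
    k <- which(cohort$subject_id == ids[j])
    ld <- -determinant(Vi_list[[j]])$modulus  # log det V_i
    nll <- nll + 0.5 * (ld + t(r[k]) %*% Vi_list[[j]] %*% r[k] +
                          length(k) * log(2 * pi))
  }
  nll <- as.numeric(nll)
  if (method == "REML") {
    nll <- nll + 0.5 * (as.numeric(determinant(XtVX)$modulus) -
                          ncol(X) * log(2 * pi))
  }
  nll
}
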