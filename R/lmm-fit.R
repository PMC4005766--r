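## ---- likelihood machinery -------------------------------------------------
##
## Marginal model per subject i:  y_i = X_i beta + Z_i b_i + e_i,
## Z_i = (1, hr), b_i ~ N(0, G), e_i ~ N(0, sigma^2 I), so
## V_i = Z_i G Z_i' + sigma^2 I.  Everything the likelihood needs reduces,
## via the Woodbury identity and the matrix determinant lemma, to 2x2
## per-subject blocks built from sufficient statistics (sums of 1, hr,
## hr^2 and the crossproducts of [X, y]), which are precomputed once per
## dataset.  Each likelihood evaluation is then a handful of vectorised
## operations, and fixed effects are profiled out by generalised least
## squares at every evaluation.

lmm_prep <- function(data, model, reference = "M<65") {
  id <- factor(data$subject_id)
  X <- design_matrix(model, data, reference = reference)
  y <- data$ee_mlkgmin
  hr <- data$hr_bpm
  XY <- cbind(X, y)
  list(
    p = ncol(X),
    terms = colnames(X),
    n_obs = length(y),
    n_subjects = nlevels(id),
    C_tot = crossprod(XY),
    D1 = rowsum(XY, id),        # per-subject column sums of [X, y]
    D2 = rowsum(XY * hr, id),   # per-subject hr-weighted sums
    m  = as.vector(rowsum(rep(1, length(y)), id)),
    s1 = as.vector(rowsum(hr, id)),
    s2 = as.vector(rowsum(hr^2, id))
  )
}

## theta = (log l11, l21, log l22, log sigma), G = L L' (log-Cholesky):
## positive semidefinite by construction and smooth where the fitted
## correlation sits near the boundary.
theta_to_vc <- function(theta) {
  l11 <- exp(theta[1]); l21 <- theta[2]; l22 <- exp(theta[3])
  sd_b1 <- sqrt(l21^2 + l22^2)
  c(sd_b0 = l11,
    sd_b1 = sd_b1,
    corr_b = if (sd_b1 > 0) l21 / sd_b1 else 0,
    sd_resid = exp(theta[4]))
}

vc_to_theta <- function(sd_b0, sd_b1, corr_b, sd_resid, floor = 1e-6) {
  corr_b <- max(min(corr_b, 1), -1)
  c(log(max(sd_b0, floor)),
    corr_b * sd_b1,
    log(max(sd_b1 * sqrt(1 - corr_b^2), floor * 1e-2)),
    log(max(sd_resid, floor)))
}

vc_to_G <- function(vc) {
  g12 <- vc[["corr_b"]] * vc[["sd_b0"]] * vc[["sd_b1"]]
  matrix(c(vc[["sd_b0"]]^2, g12, g12, vc[["sd_b1"]]^2), 2L, 2L)
}

## Negative log-likelihood (ML) or negative restricted log-likelihood
## (REML) at theta, with fixed effects profiled out.  Optionally returns
## the GLS pieces for reuse at the optimum.
nll_theta <- function(theta, prep, method = "ML", pieces = FALSE) {
  theta <- pmin(pmax(theta, -30), 30)   # keep exp() finite far from optimum
  l11 <- exp(theta[1]); l21 <- theta[2]; l22 <- exp(theta[3])
  g11 <- l11^2; g12 <- l11 * l21; g22 <- l21^2 + l22^2
  s2e <- exp(2 * theta[4])
  m <- prep$m; s1 <- prep$s1; s2 <- prep$s2

  ## A_i = sigma^2 I + M_i G with M_i = Z_i'Z_i = [m s1; s1 s2]
  a11 <- s2e + m * g11 + s1 * g12
  a12 <-        m * g12 + s1 * g22
  a21 <-        s1 * g11 + s2 * g12
  a22 <- s2e + s1 * g12 + s2 * g22
  detA <- a11 * a22 - a12 * a21
  if (!all(is.finite(detA)) || any(detA <= 0)) {
    return(.Machine$double.xmax / 2)   # numerical overflow far from optimum
  }
  ## W_i = G A_i^{-1} (symmetric)
  w11 <- (g11 * a22 - g12 * a21) / detA
  w22 <- (g22 * a11 - g12 * a12) / detA
  w12 <- (g12 * a11 - g11 * a12) / detA
  w21 <- (g12 * a22 - g22 * a21) / detA
  w12 <- (w12 + w21) / 2

  D1 <- prep$D1; D2 <- prep$D2
  S <- (prep$C_tot -
          (crossprod(D1, w11 * D1) + crossprod(D1, w12 * D2) +
             crossprod(D2, w12 * D1) + crossprod(D2, w22 * D2))) / s2e
  p <- prep$p
  Sxx <- S[seq_len(p), seq_len(p), drop = FALSE]
  Sxy <- S[seq_len(p), p + 1L]
  Syy <- S[p + 1L, p + 1L]

  ch <- tryCatch(chol(Sxx), error = function(e) NULL)
  if (is.null(ch)) {
    if (pieces) .singular_design_error(Sxx, prep$terms)
    return(.Machine$double.xmax / 2)   # off-optimum numerical corner
  }
  beta <- backsolve(ch, forwardsolve(t(ch), Sxy))
  quad <- max(Syy - sum(Sxy * beta), 0)
  logdet <- sum((m - 2) * log(s2e)) + sum(log(detA))

  n <- prep$n_obs
  nll <- 0.5 * (logdet + quad + n * log(2 * pi))
  if (method == "REML") {
    nll <- nll + 0.5 * (2 * sum(log(diag(ch))) - p * log(2 * pi))
  }
  if (!is.finite(nll)) nll <- .Machine$double.xmax / 2
  if (pieces) {
    vcov_beta <- chol2inv(ch)
    dimnames(vcov_beta) <- list(prep$terms, prep$terms)
    return(list(nll = nll, beta = setNames(drop(beta), prep$terms),
                vcov_beta = vcov_beta, quad = quad))
  }
  nll
}

.singular_design_error <- function(Sxx, terms) {
  qr_s <- qr(Sxx)
  bad <- terms[qr_s$pivot[seq(qr_s$rank + 1L, length(terms))]]
  abort(paste0("profiled fixed-effect design is singular; collinear column(s): ",
               paste(bad, collapse = ", ")))
}

#' Profiled negative log-likelihood at given variance components
#'
#' Evaluates the marginal (restricted) negative log-likelihood of the
#' mixed model at fixed variance components, with the fixed effects
#' profiled out by generalised least squares. Useful for likelihood
#' surface inspection and for checking the fitter against independent
#' evaluations.
#'
#' @param data A cohort measurement table (see [simulate_cohort()]).
#' @param model `"continuous"` or `"stratified"`.
#' @param vc Named list or vector with `sd_b0`, `sd_b1`, `corr_b`,
#'   `sd_resid`.
#' @param method `"ML"` or `"REML"`.
#' @param reference Reference stratum for the stratified form.
#' @return The negative (restricted) log-likelihood, a single number.
#' @export
profile_nll <- function(data, model = c("continuous", "stratified"), vc,
                        method = c("ML", "REML"), reference = "M<65") {
  model <- arg_match(model)
  method <- arg_match(method)
  vc <- as.list(vc)
  prep <- lmm_prep(data, model, reference)
  check_design_rank(prep)
  theta <- vc_to_theta(vc$sd_b0, vc$sd_b1, vc$corr_b, vc$sd_resid, floor = 1e-12)
  nll_theta(theta, prep, method)
}

check_design_rank <- function(prep) {
  Cxx <- prep$C_tot[seq_len(prep$p), seq_len(prep$p), drop = FALSE]
  qr_c <- qr(Cxx)
  if (qr_c$rank < prep$p) .singular_design_error(Cxx, prep$terms)
  invisible(prep)
}

#' Generalised least squares fixed effects at given variance components
#'
#' Computes the GLS fixed-effect estimates and their covariance under the
#' marginal covariance implied by `vc`. [fit_hr_ee()] returns exactly
#' these quantities evaluated at the estimated variance components.
#'
#' @inheritParams profile_nll
#' @return A list with `coefficients` and `vcov`.
#' @export
gls_fixed_effects <- function(data, model = c("continuous", "stratified"), vc,
                              reference = "M<65") {
  model <- arg_match(model)
  vc <- as.list(vc)
  prep <- lmm_prep(data, model, reference)
  theta <- vc_to_theta(vc$sd_b0, vc$sd_b1, vc$corr_b, vc$sd_resid, floor = 1e-12)
  pc <- nll_theta(theta, prep, "ML", pieces = TRUE)
  list(coefficients = pc$beta, vcov = pc$vcov_beta)
}

## ---- starting values ------------------------------------------------------

## Per-subject ordinary least squares of ee on hr gives a deliberately
## over-dispersed estimate of G (it includes sampling noise) — a robust
## central start; two further starts scale all components up and down.
starting_thetas <- function(data) {
  by_subj <- data %>%
    group_by(.data$subject_id) %>%
    summarise(
      vx = var(.data$hr_bpm),
      slope = ifelse(.data$vx[1] > 0,
                     cov(.data$hr_bpm, .data$ee_mlkgmin) / .data$vx[1], NA_real_),
      int = mean(.data$ee_mlkgmin) - .data$slope[1] * mean(.data$hr_bpm),
      rss = sum((.data$ee_mlkgmin - .data$int[1] -
                   .data$slope[1] * .data$hr_bpm)^2),
      df = sum(!is.na(.data$ee_mlkgmin)) - 2L,
      .groups = "drop"
    ) %>%
    filter(is.finite(.data$slope))

  if (nrow(by_subj) >= 3L && sum(by_subj$df) > 0L) {
    sd_b0 <- max(sd(by_subj$int), 1e-3)
    sd_b1 <- max(sd(by_subj$slope), 1e-5)
    corr_b <- suppressWarnings(cor(by_subj$int, by_subj$slope))
    if (!is.finite(corr_b)) corr_b <- 0
    corr_b <- max(min(corr_b, 0.98), -0.98)
    sd_w <- sqrt(max(sum(by_subj$rss) / max(sum(by_subj$df), 1L), 1e-6))
  } else {
    sd_y <- max(sd(data$ee_mlkgmin), 1e-3)
    sd_b0 <- sd_y / 2; sd_b1 <- sd_y / 200; corr_b <- 0; sd_w <- sd_y / 2
  }
  central <- vc_to_theta(sd_b0, sd_b1, corr_b, sd_w)
  scale_up <- vc_to_theta(3 * sd_b0, 3 * sd_b1, corr_b / 2, 3 * sd_w)
  scale_dn <- vc_to_theta(sd_b0 / 3, sd_b1 / 3, 0, sd_w / 3)
  list(central, scale_up, scale_dn)
}

## ---- the fitter -----------------------------------------------------------

#' Fit the heart-rate / energy-expenditure mixed model
#'
#' Fits a linear mixed model for energy expenditure (ml/kg/min) on heart
#' rate with a subject-level random intercept and random heart-rate
#' slope, by maximum likelihood or REML. Two fixed-effect forms are
#' available: `"stratified"` (separate intercept and slope per sex/age
#' stratum, men under 65 as reference) and `"continuous"` (heart rate,
#' sex, continuous age and the age-by-heart-rate interaction).
#'
#' Estimation maximises the profiled (restricted) likelihood over a
#' log-Cholesky parameterisation of the random-effect covariance and the
#' log residual SD, using a quasi-Newton pass refined by Nelder--Mead
#' simplex from three dispersed data-driven starts. Fixed effects are the
#' GLS solution at the estimated variance components; their standard
#' errors come from the GLS covariance, and variance-component standard
#' errors from the numerically differentiated observed information mapped
#' to the SD/correlation scale by the delta method. Wald z-tests are
#' reported for fixed effects.
#'
#' @param data A cohort measurement table with columns `subject_id`,
#'   `age`, `sex`, `hr_bpm`, `ee_mlkgmin` (see [simulate_cohort()],
#'   [read_cohort()]). A `height` column, if present, is ignored.
#' @param model Fixed-effect form, `"continuous"` (default) or
#'   `"stratified"`.
#' @param method `"ML"` (default) or `"REML"`.
#' @param reference Reference stratum for the stratified form.
#' @param vc_fixed Optional named list pinning variance components during
#'   optimisation: `sd_b0` and/or `sd_resid`, and/or the pair
#'   `sd_b1` + `corr_b` (the pair maps onto dedicated parameters and must
#'   be pinned together).
#' @param start Optional starting value, a named list like `vc_fixed`
#'   with all four components.
#' @param control List of optimiser settings: `reltol` (default `1e-10`),
#'   `maxit_bfgs`, `maxit_nm`.
#' @return An object of class `hr_ee_fit`; see [tidy.hr_ee_fit()],
#'   [glance.hr_ee_fit()], [compare_strata()], [predict_ee()].
#'   Non-convergence is flagged in `$converged`, not raised as an error.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(n_subjects = 40, seed = 1))
#' fit <- fit_hr_ee(cohort, model = "continuous")
#' tidy(fit)
#' glance(fit)
fit_hr_ee <- function(data,
                      model = c("continuous", "stratified"),
                      method = c("ML", "REML"),
                      reference = "M<65",
                      vc_fixed = NULL,
                      start = NULL,
                      control = list()) {
  model <- arg_match(model)
  method <- arg_match(method)
  data <- validate_cohort(data, complete = FALSE, quiet = TRUE)
  if (nrow(data) == 0L) abort("`data` is empty.")
  if (length(unique(data$subject_id)) < 2L) {
    abort("need at least 2 subjects to separate within- from between-subject variance.")
  }
  ctrl <- modifyList(list(reltol = 1e-10, maxit_bfgs = 200L, maxit_nm = 2000L),
                     control)
  prep <- lmm_prep(data, model, reference)
  check_design_rank(prep)

  ## exact-interpolation corner: if every measurement lies on one common
  ## line the likelihood is unbounded (sigma -> 0) and the optimisation
  ## degenerates; the ordinary least-squares solution is exact and all
  ## variance components are zero
  X <- design_matrix(model, data, reference = reference)
  ols <- stats::lm.fit(X, data$ee_mlkgmin)
  tss <- sum((data$ee_mlkgmin - mean(data$ee_mlkgmin))^2)
  if (sum(ols$residuals^2) <= 1e-16 * max(tss, 1)) {
    vc0 <- c(sd_b0 = 0, sd_b1 = 0, corr_b = 0, sd_resid = 0)
    vcov0 <- matrix(0, prep$p, prep$p, dimnames = list(prep$terms, prep$terms))
    return(structure(list(
      model = model, method = method, reference = reference,
      coefficients = setNames(ols$coefficients, prep$terms), vcov = vcov0,
      vc = vc0, se_vc = setNames(rep(0, 4L), names(vc0)),
      G = vc_to_G(vc0), sigma = 0, loglik = Inf, converged = TRUE,
      n_subjects = prep$n_subjects, n_obs = prep$n_obs,
      theta = NULL, optim = list(degenerate = "exact interpolation")
    ), class = "hr_ee_fit"))
  }

  ## which theta coordinates are free
  free <- rep(TRUE, 4L)
  pinned <- rep(NA_real_, 4L)
  if (!is.null(vc_fixed)) {
    has <- names(vc_fixed)
    if (xor("sd_b1" %in% has, "corr_b" %in% has)) {
      abort("`sd_b1` and `corr_b` must be pinned together.")
    }
    if ("sd_b0" %in% has) {
      free[1] <- FALSE; pinned[1] <- log(max(vc_fixed$sd_b0, 1e-12))
    }
    if ("sd_b1" %in% has) {
      th <- vc_to_theta(1, vc_fixed$sd_b1, vc_fixed$corr_b, 1, floor = 1e-12)
      free[2:3] <- FALSE; pinned[2:3] <- th[2:3]
    }
    if ("sd_resid" %in% has) {
      free[4] <- FALSE; pinned[4] <- log(max(vc_fixed$sd_resid, 1e-12))
    }
  }
  expand <- function(par) { th <- pinned; th[free] <- par; th }
  obj <- function(par) nll_theta(expand(par), prep, method)

  starts <- if (!is.null(start)) {
    list(vc_to_theta(start$sd_b0, start$sd_b1, start$corr_b, start$sd_resid))
  } else {
    starting_thetas(data)
  }

  best <- NULL
  for (th0 in starts) {
    par0 <- th0[free]
    o1 <- tryCatch(
      optim(par0, obj, method = "BFGS",
            control = list(reltol = ctrl$reltol, maxit = ctrl$maxit_bfgs)),
      error = function(e) list(par = par0, value = obj(par0), convergence = 99L)
    )
    o2 <- optim(o1$par, obj, method = "Nelder-Mead",
                control = list(reltol = ctrl$reltol, maxit = ctrl$maxit_nm,
                               warn.1d.NelderMead = FALSE))
    if (is.null(best) || o2$value < best$value) best <- o2
  }
  theta_hat <- expand(best$par)
  converged <- best$convergence == 0L

  pc <- nll_theta(theta_hat, prep, method, pieces = TRUE)
  vc <- theta_to_vc(theta_hat)

  ## delta-method SEs for the variance components (free coordinates only)
  se_vc <- setNames(rep(NA_real_, 4L), names(vc))
  if (converged && any(free)) {
    se_vc_try <- tryCatch({
      H <- optimHess(best$par, obj)
      cov_par <- solve(H)
      J <- numeric_jacobian(function(par) theta_to_vc(expand(par)), best$par)
      v <- diag(J %*% cov_par %*% t(J))
      sqrt(pmax(v, 0))
    }, error = function(e) rep(NA_real_, 4L))
    se_vc <- setNames(se_vc_try, names(vc))
  }

  structure(list(
    model = model,
    method = method,
    reference = reference,
    coefficients = pc$beta,
    vcov = pc$vcov_beta,
    vc = vc,
    se_vc = se_vc,
    G = vc_to_G(vc),
    sigma = vc[["sd_resid"]],
    loglik = -pc$nll,
    converged = converged,
    n_subjects = prep$n_subjects,
    n_obs = prep$n_obs,
    theta = theta_hat,
    optim = list(value = best$value, convergence = best$convergence,
                 counts = best$counts)
  ), class = "hr_ee_fit")
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Construct a model object from known parameters
#'
#' Builds an `hr_ee_fit`-compatible object directly from published or
#' otherwise known coefficients and variance components, so that
#' [predict_ee()], [posterior_random_effects()] and friends can be used
#' without refitting — e.g. to apply a published population equation.
#'
#' @param coefficients Named coefficient vector. For the continuous form:
#'   `(Intercept)`, `hr`, `male`, `age`, `age:hr`. For the stratified
#'   form the eight terms of [design_row()]. A bare numeric vector of the
#'   right length is accepted and named positionally.
#' @param vc Named list or vector with `sd_b0`, `sd_b1`, `corr_b`,
#'   `sd_resid`.
#' @param model `"continuous"` or `"stratified"`.
#' @param reference Reference stratum for the stratified form.
#' @return An object of class `hr_ee_fit` (with no likelihood or
#'   standard errors).
#' @export
#' @examples
#' eq <- hr_ee_model(c(-23.046, 0.339, 2.241, 0.099, -0.0007),
#'                   vc = c(sd_b0 = 3.966, sd_b1 = 0.062,
#'                          corr_b = -0.874, sd_resid = 2.787))
#' predict_ee(eq, tibble::tibble(age = 55.5, sex = "M", hr_bpm = 62))
hr_ee_model <- function(coefficients, vc,
                        model = c("continuous", "stratified"),
                        reference = "M<65") {
  model <- arg_match(model)
  p <- n_fixef(model)
  if (length(coefficients) != p) {
    abort(sprintf("`coefficients` must have length %d for the %s form.", p, model))
  }
  terms <- colnames(design_matrix(model, tibble(age = 70, sex = "M", hr_bpm = 100),
                                  reference = reference))
  if (is.null(names(coefficients))) names(coefficients) <- terms
  vc <- unlist(as.list(vc)[c("sd_b0", "sd_b1", "corr_b", "sd_resid")])
  structure(list(
    model = model, method = "none", reference = reference,
    coefficients = coefficients, vcov = NULL,
    vc = vc, se_vc = setNames(rep(NA_real_, 4L), names(vc)),
    G = vc_to_G(vc), sigma = vc[["sd_resid"]],
    loglik = NA_real_, converged = NA,
    n_subjects = NA_integer_, n_obs = NA_integer_,
    theta = NULL, optim = NULL
  ), class = "hr_ee_fit")
}

## ---- stratified contrasts -------------------------------------------------

#' Per-stratum intercepts and slopes from a stratified fit
#'
#' Composes the four stratum intercepts and four heart-rate slopes from a
#' stratified-form fit (reference value plus offset) with standard errors
#' of the composites, and Wald tests. For the reference stratum the test
#' is of the composite itself being zero; for the other strata it is the
#' test of the offset from the reference (i.e. "does this stratum differ
#' from the reference"), matching how stratified estimates are usually
#' reported.
#'
#' @param fit An `hr_ee_fit` with `model = "stratified"`.
#' @return A tibble with columns `stratum`, `parameter`
#'   (`"intercept"`/`"hr_slope"`), `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
compare_strata <- function(fit) {
  if (!inherits(fit, "hr_ee_fit")) abort("`fit` must be an `hr_ee_fit`.")
  if (fit$model != "stratified") {
    abort("`compare_strata()` requires a stratified-form fit.")
  }
  beta <- fit$coefficients
  V <- fit$vcov
  terms <- names(beta)
  ref <- fit$reference
  others <- setdiff(EE_STRATA, ref)

  rows <- list()
  for (par in c("intercept", "hr_slope")) {
    base_term <- if (par == "intercept") "(Intercept)" else "hr"
    for (s in EE_STRATA) {
      off_term <- if (s == ref) NULL else {
        g <- paste0("G[", s, "]")
        if (par == "intercept") g else paste0("hr:", g)
      }
      L <- setNames(numeric(length(beta)), terms)
      L[base_term] <- 1
      if (!is.null(off_term)) L[off_term] <- 1
      est <- sum(L * beta)
      se <- if (is.null(V)) NA_real_ else sqrt(drop(t(L) %*% V %*% L))
      ## contrast under test: composite for the reference, offset otherwise
      if (is.null(off_term)) {
        c_est <- est; c_se <- se
      } else {
        c_est <- beta[[off_term]]
        c_se <- if (is.null(V)) NA_real_ else sqrt(V[off_term, off_term])
      }
      z <- c_est / c_se
      rows[[length(rows) + 1L]] <- tibble(
        stratum = s, parameter = par, estimate = est, std.error = se,
        statistic = z, p.value = 2 * pnorm(-abs(z))
      )
    }
  }
  bind_rows(rows) %>%
    mutate(stratum = factor(.data$stratum, levels = EE_STRATA)) %>%
    arrange(.data$parameter, .data$stratum)
}

## ---- methods --------------------------------------------------------------

#' @export
print.hr_ee_fit <- function(x, ...) {
  cat(sprintf("Heart-rate / energy-expenditure mixed model (%s form, %s)\n",
              x$model, x$method))
  if (!is.na(x$n_obs)) {
    cat(sprintf("  %d observations, %d subjects;  logLik %.3f;  converged: %s\n",
                x$n_obs, x$n_subjects, x$loglik, x$converged))
  }
  cat("Fixed effects:\n")
  print(round(x$coefficients, 4))
  cat("Random effects / residual:\n")
  print(round(x$vc, 4))
  invisible(x)
}

#' Tidy a fitted heart-rate / energy-expenditure model
#'
#' @param x An `hr_ee_fit`.
#' @param effects `"fixed"` for fixed-effect terms (with Wald z-tests),
#'   `"ran_pars"` for the variance components, or both.
#' @param ... Unused.
#' @return A tibble with columns `effect`, `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value` (tests for fixed effects only).
#' @export
tidy.hr_ee_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- list()
  if ("fixed" %in% effects) {
    se <- if (is.null(x$vcov)) rep(NA_real_, length(x$coefficients)) else
      sqrt(diag(x$vcov))
    z <- x$coefficients / se
    out$fixed <- tibble(
      effect = "fixed", term = names(x$coefficients),
      estimate = unname(x$coefficients), std.error = unname(se),
      statistic = unname(z), p.value = unname(2 * pnorm(-abs(z)))
    )
  }
  if ("ran_pars" %in% effects) {
    out$ran <- tibble(
      effect = "ran_pars",
      term = c("sd__(Intercept)", "sd__hr", "cor__(Intercept).hr",
               "sd__Observation"),
      estimate = unname(x$vc),
      std.error = unname(x$se_vc),
      statistic = NA_real_, p.value = NA_real_
    )
  }
  bind_rows(out)
}

#' Model-level summary of a fitted heart-rate / energy-expenditure model
#'
#' @param x An `hr_ee_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `nobs`, `n_subjects`, `sigma`, `logLik`,
#'   `AIC`, `BIC`, `method`, `converged`.
#' @export
glance.hr_ee_fit <- function(x, ...) {
  k <- length(x$coefficients) + 4L
  tibble(
    nobs = x$n_obs, n_subjects = x$n_subjects, sigma = x$sigma,
    logLik = x$loglik, AIC = 2 * k - 2 * x$loglik,
    BIC = k * log(x$n_obs) - 2 * x$loglik,
    method = x$method, converged = x$converged
  )
}
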