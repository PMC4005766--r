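test_that("design rows encode both model forms", {
  expect_equal(unname(design_row("stratified", age = 70, sex = "M", hr = 100)),
               c(1, 1, 0, 0, 100, 100, 0, 0))
  expect_equal(unname(design_row("continuous", age = 60, sex = "F", hr = 90)),
               c(1, 90, 0, 60, 5400))
  # the age-65 boundary belongs to the older stratum
  expect_equal(unname(design_row("stratified", age = 64.99, sex = "M", hr = 80)),
               c(1, 0, 0, 0, 80, 0, 0, 0))
  expect_equal(unname(design_row("stratified", age = 65, sex = "M", hr = 80)),
               c(1, 1, 0, 0, 80, 80, 0, 0))
})

test_that("profiled likelihood collapses to the iid regression likelihood when G = 0", {
  co <- small_cohort(n = 15, seed = 21)
  sig <- 1.7
  vc0 <- list(sd_b0 = 0, sd_b1 = 0, corr_b = 0, sd_resid = sig)
  X <- hr2ee:::design_matrix("continuous", co)
  rss <- sum(resid(lm(co$ee_mlkgmin ~ X - 1))^2)
  n <- nrow(co)
  nll_ols <- 0.5 * (n * log(2 * pi * sig^2) + rss / sig^2)
  expect_equal(profile_nll(co, "continuous", vc0), nll_ols, tolerance = 1e-10)
})

test_that("likelihood matches a direct multivariate-normal evaluation", {
  co <- small_cohort(n = 3, seed = 5)
  vc <- list(sd_b0 = 2.1, sd_b1 = 0.05, corr_b = -0.5, sd_resid = 1.3)
  for (method in c("ML", "REML")) {
    expect_equal(profile_nll(co, "continuous", vc, method = method),
                 dense_nll(co, "continuous", vc, method = method),
                 tolerance = 1e-10)
  }
  # invariance under subject permutation
  perm <- co[order(rev(co$subject_id), co$level), ]
  expect_equal(profile_nll(perm, "continuous", vc),
               profile_nll(co, "continuous", vc), tolerance = 1e-10)
})

test_that("noise-free cohorts are interpolated exactly", {
  cfg0 <- generator_config(n_subjects = 20, sd_b0 = 0, sd_b1 = 0, sd_resid = 0,
                           seed = 9)
  fit <- fit_hr_ee(simulate_cohort(cfg0), model = "continuous")
  expect_equal(unname(fit$coefficients), unname(cfg0$fixed_effects),
               tolerance = 1e-8)
})

test_that("optimizer agrees with a dense grid search on a two-parameter subproblem", {
  co <- small_cohort(n = 10, seed = 31)
  fit <- fit_hr_ee(co, model = "continuous", method = "ML",
                   vc_fixed = list(sd_b1 = 0.062, corr_b = -0.874))
  expect_equal(fit$vc[["sd_b1"]], 0.062, tolerance = 1e-10)
  expect_equal(fit$vc[["corr_b"]], -0.874, tolerance = 1e-10)

  step <- 0.02
  g_b0 <- seq(fit$vc[["sd_b0"]] * 0.5, fit$vc[["sd_b0"]] * 1.6, by = step)
  g_sw <- seq(fit$vc[["sd_resid"]] * 0.5, fit$vc[["sd_resid"]] * 1.6, by = step)
  grid <- expand.grid(sd_b0 = g_b0, sd_resid = g_sw)
  grid$nll <- vapply(seq_len(nrow(grid)), function(i) {
    profile_nll(co, "continuous",
                list(sd_b0 = grid$sd_b0[i], sd_b1 = 0.062, corr_b = -0.874,
                     sd_resid = grid$sd_resid[i]))
  }, numeric(1))
  best <- grid[which.min(grid$nll), ]
  expect_lt(abs(best$sd_b0 - fit$vc[["sd_b0"]]), step)
  expect_lt(abs(best$sd_resid - fit$vc[["sd_resid"]]), step)
  expect_lte(-fit$loglik, min(grid$nll) + 1e-8)
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  co <- small_cohort(n = 80, seed = 13)
  ours <- fit_hr_ee(co, model = "continuous", method = "ML")
  lf <- suppressWarnings(suppressMessages(
    lme4::lmer(ee_mlkgmin ~ hr_bpm + sex + age + age:hr_bpm +
                 (1 + hr_bpm | subject_id), data = co, REML = FALSE)
  ))
  Gm <- lme4::VarCorr(lf)$subject_id
  vc_lme4 <- list(sd_b0 = sqrt(Gm[1, 1]), sd_b1 = sqrt(Gm[2, 2]),
                  corr_b = Gm[1, 2] / sqrt(Gm[1, 1] * Gm[2, 2]),
                  sd_resid = lme4::getME(lf, "sigma"))
  # our likelihood function evaluated at lme4's solution reproduces
  # lme4's log-likelihood, and our optimum is at least as good
  expect_equal(-profile_nll(co, "continuous", vc_lme4),
               as.numeric(logLik(lf)), tolerance = 1e-4)
  expect_gte(ours$loglik, as.numeric(logLik(lf)) - 1e-4)
})

test_that("profile-GLS identity and optimizer sanity hold", {
  co <- small_cohort(n = 60, seed = 17)
  fit <- fit_hr_ee(co, model = "continuous", method = "ML")
  refit <- gls_fixed_effects(co, "continuous", as.list(fit$vc))
  expect_equal(refit$coefficients, fit$coefficients, tolerance = 1e-10)
  # likelihood at the optimum dominates the generating parameters
  expect_gte(fit$loglik + 1e-8, -profile_nll(co, "continuous", TRUTH_VC))
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$se_vc)))
  td <- tidy(fit)
  expect_setequal(td$term[td$effect == "fixed"],
                  c("(Intercept)", "hr", "male", "age", "age:hr"))
  expect_true(all(is.finite(td$std.error[td$effect == "fixed"])))
  expect_equal(nrow(glance(fit)), 1L)
})

test_that("REML and ML differ as expected on small samples", {
  co <- small_cohort(n = 25, seed = 19)
  ml <- fit_hr_ee(co, method = "ML")
  reml <- fit_hr_ee(co, method = "REML")
  # REML corrects the downward bias of ML variance components
  expect_gt(reml$vc[["sd_resid"]], 0)
  expect_gte(reml$vc[["sd_b0"]], ml$vc[["sd_b0"]] - 0.05)
  expect_false(isTRUE(all.equal(ml$loglik, reml$loglik)))
})

test_that("stratified contrasts compose reference and offsets", {
  # raw coefficients derived from the composed per-stratum values
  beta <- c(-15.392, 0.432, -2.199, -1.663, 0.296, -0.017, 0.001, -0.011)
  eq <- hr_ee_model(beta, vc = unlist(TRUTH_VC), model = "stratified")
  cs <- compare_strata(eq)
  expect_equal(cs$estimate[cs$parameter == "intercept"],
               c(-15.392, -14.960, -17.591, -17.055), tolerance = 1e-12)
  expect_equal(cs$estimate[cs$parameter == "hr_slope"],
               c(0.296, 0.279, 0.297, 0.285), tolerance = 1e-12)

  # zero offsets give four identical lines
  eq0 <- hr_ee_model(c(-16, 0, 0, 0, 0.3, 0, 0, 0), vc = unlist(TRUTH_VC),
                     model = "stratified")
  cs0 <- compare_strata(eq0)
  expect_true(all(cs0$estimate[cs0$parameter == "intercept"] == -16))
  expect_true(all(cs0$estimate[cs0$parameter == "hr_slope"] == 0.3))

  expect_error(compare_strata(table3_equation()), "stratified")
})

test_that("composed strata are invariant to the reference group", {
  co <- small_cohort(n = 60, seed = 23, model = "stratified")
  f1 <- fit_hr_ee(co, model = "stratified", method = "ML")
  # same variance components, different parameterisation of the mean
  f2 <- fit_hr_ee(co, model = "stratified", method = "ML",
                  reference = "F>=65",
                  vc_fixed = list(sd_b0 = f1$vc[["sd_b0"]],
                                  sd_b1 = f1$vc[["sd_b1"]],
                                  corr_b = f1$vc[["corr_b"]],
                                  sd_resid = f1$vc[["sd_resid"]]))
  c1 <- compare_strata(f1)
  c2 <- compare_strata(f2)
  expect_equal(c1$estimate, c2$estimate, tolerance = 1e-6)
})

test_that("degenerate inputs raise informative errors", {
  co <- small_cohort(n = 10, seed = 3)
  expect_error(fit_hr_ee(co[co$subject_id == "S0001", ]), "2 subjects")
  # constant heart rate makes the slope columns collinear with the intercept
  co_flat <- co
  co_flat$hr_bpm <- 100
  expect_error(profile_nll(co_flat, "continuous", TRUTH_VC), "collinear")
  expect_error(fit_hr_ee(co, vc_fixed = list(sd_b1 = 0.06)), "together")
})
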