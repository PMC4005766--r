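test_that("subject splits partition the cohort at the requested fraction", {
  co <- small_cohort(n = 290, seed = 51)
  sp <- split_subjects(co, frac = 0.8, seed = 1)
  expect_equal(sum(sp$set == "training"), 232L)
  expect_equal(sum(sp$set == "validation"), 58L)
  expect_setequal(sp$subject_id, unique(co$subject_id))

  sps <- split_subjects(co, frac = 0.8, stratified = TRUE, seed = 2)
  expect_equal(sum(sps$set == "training"), 232L)
  per <- table(sps$stratum, sps$set)
  expect_true(all(abs(per[, "training"] - 0.8 * rowSums(per)) <= 1))

  expect_identical(split_subjects(co, 0.8, seed = 9),
                   split_subjects(co, 0.8, seed = 9))
  expect_false(identical(split_subjects(co, 0.8, seed = 9)$set,
                         split_subjects(co, 0.8, seed = 10)$set))
  expect_error(split_subjects(co, frac = 1.2), "strictly")

  # a stratum with a single subject cannot be split
  one_idx <- match(unique(co$subject_id[co$stratum == "F<65"]),
                   co$subject_id)
  keep <- co$stratum != "F<65" |
    co$subject_id == co$subject_id[one_idx[1]]
  expect_error(split_subjects(co[keep, ], 0.8, stratified = TRUE, seed = 1),
               "at least 2")
})

test_that("a noiseless cohort cross-validates with zero error", {
  cfg0 <- generator_config(n_subjects = 30, sd_b0 = 0, sd_b1 = 0, sd_resid = 0,
                           seed = 52)
  cv <- run_scenarios(simulate_cohort(cfg0), replicates = 1, seed = 1)
  expect_true(all(abs(cv$errors$error_kcal_min) < 1e-6))
  expect_true(all(cv$summary$sd < 1e-6))
  expect_equal(unique(cv$summary$n_errors), 6L * 5L)  # 20% of 30 subjects
})

test_that("pooled error SDs shrink with calibration on average and are reproducible", {
  co <- small_cohort(n = 150, seed = 53)
  cv <- run_scenarios(co, replicates = 4, seed = 7)
  s <- summary(cv)
  sds <- s$mean_sd[match(c("none", "rest_only", "rest_peak", "all_five"),
                         as.character(s$scenario))]
  expect_true(all(diff(sds) < 0))
  # the big calibration steps hold in every single replicate
  per_rep <- tidyr::pivot_wider(cv$summary, id_cols = "replicate",
                                names_from = "scenario", values_from = "sd")
  expect_true(all(per_rep$rest_peak <= per_rep$rest_only))
  expect_true(all(per_rep$all_five <= per_rep$rest_peak))

  cv2 <- run_scenarios(co, replicates = 4, seed = 7)
  expect_identical(cv$summary, cv2$summary)
  expect_equal(unique(cv$summary$n_errors), 30L * 5L)
})

test_that("both model forms have similar predictive performance", {
  co <- small_cohort(n = 290, seed = 54)
  cv2 <- run_scenarios(co, model = "continuous", stratified = TRUE,
                       replicates = 2, seed = 3)
  cv1 <- run_scenarios(co, model = "stratified", stratified = TRUE,
                       replicates = 2, seed = 3)
  s2 <- summary(cv2); s1 <- summary(cv1)
  expect_equal(as.character(s1$scenario), as.character(s2$scenario))
  expect_true(all(abs(s1$mean_sd - s2$mean_sd) < 0.1))
})

test_that("uncalibrated error SD matches the closed-form marginal SD", {
  # at a fixed heart rate and weight, the no-calibration error is
  # b0 + b1*hr + w, with SD sqrt(z'Gz + sigma^2) on the oxygen scale
  hr <- 100; w_kg <- 80
  re <- sample_random_effects(50000, 3.966, 0.062, -0.874, seed = 55)
  noise <- withr::with_seed(56, rnorm(50000, 0, 2.787))
  err <- to_kcal_per_min(re$b0 + re$b1 * hr + noise, w_kg)
  G <- vc_to_G_mat(TRUTH_VC)
  z <- c(1, hr)
  analytic <- sqrt(drop(t(z) %*% G %*% z) + 2.787^2) * w_kg * 5 / 1000
  expect_lt(abs(sd(err) - analytic) / analytic, 0.02)
})

test_that("error densities behave like proper kernel density estimates", {
  x <- withr::with_seed(57, rnorm(10000))
  d <- error_density(x)
  expect_equal(nrow(d), 512L)
  expect_lt(abs(d$density[which.min(abs(d$x))] - dnorm(0)), 0.03)
  expect_true(all(d$density >= 0))
  step <- diff(d$x[1:2])
  expect_lt(abs(sum(d$density) * step - 1), 1e-3)

  # scaling equivariance: doubling the errors doubles the support and
  # halves the height (Silverman's bandwidth scales linearly)
  d2 <- error_density(2 * x)
  expect_equal(d2$x, 2 * d$x, tolerance = 1e-12)
  expect_equal(d2$density, d$density / 2, tolerance = 1e-10)

  expect_warning(pm <- error_density(rep(1.5, 10)), "point mass")
  expect_equal(pm$x, 1.5)
  expect_error(error_density(1), "at least 2")
})

test_that("within-subject correlation is near-perfect for the linear model", {
  cfg0 <- generator_config(n_subjects = 25, sd_resid = 0, seed = 58)
  ipc0 <- intra_person_correlation(simulate_cohort(cfg0))
  expect_equal(ipc0$per_subject$r, rep(1, 25), tolerance = 1e-12)

  co <- small_cohort(n = 200, seed = 59)
  ipc <- intra_person_correlation(co)
  expect_gt(ipc$mean_r, 0.9)
  expect_lte(ipc$max_r, 1)

  # antisymmetry under sign reversal of the response
  flipped <- intra_person_correlation(dplyr::mutate(co, ee_mlkgmin = -ee_mlkgmin))
  expect_equal(flipped$per_subject$r, -ipc$per_subject$r, tolerance = 1e-12)

  # a constant-heart-rate subject is excluded with a warning
  co_flat <- co
  co_flat$hr_bpm[co_flat$subject_id == "S0001"] <- 90
  expect_warning(ipc_f <- intra_person_correlation(co_flat), "constant heart rate")
  expect_equal(ipc_f$n_excluded, 1L)
  expect_true(is.na(ipc_f$per_subject$r[ipc_f$per_subject$subject_id == "S0001"]))
})
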