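test_that("no calibration data returns the prior", {
  eq <- table3_equation()
  post <- posterior_random_effects(eq, calib = NULL, subjects = "A")
  expect_equal(post$k_used, 0L)
  expect_equal(c(post$b0, post$b1), c(0, 0))
  expect_equal(matrix(c(post$var_b0, post$cov_b0b1, post$cov_b0b1, post$var_b1), 2),
               eq$G, tolerance = 1e-12)
})

test_that("posterior matches brute-force conditioning of the joint normal", {
  eq <- table3_equation()
  G <- eq$G
  s2 <- eq$sigma^2
  hrs <- c(61, 120)
  resids <- c(1.5, -2.0)
  base <- tibble::tibble(subject_id = "A", age = 70, sex = "M", hr_bpm = hrs)
  mu <- predict_ee(eq, base)$ee_pred_mlkgmin
  calib <- dplyr::mutate(base, ee_mlkgmin = mu + resids)

  post <- posterior_random_effects(eq, calib)

  # oracle: condition the joint 4-dim normal of (b0, b1, y1, y2) directly
  Z <- cbind(1, hrs)
  S11 <- G
  S12 <- G %*% t(Z)
  S22 <- Z %*% G %*% t(Z) + s2 * diag(2)
  mean_oracle <- drop(S12 %*% solve(S22, resids))
  cov_oracle <- S11 - S12 %*% solve(S22) %*% t(S12)
  expect_equal(c(post$b0, post$b1), mean_oracle, tolerance = 1e-10)
  expect_equal(c(post$var_b0, post$cov_b0b1, post$var_b1),
               c(cov_oracle[1, 1], cov_oracle[1, 2], cov_oracle[2, 2]),
               tolerance = 1e-10)
  expect_equal(post$k_used, 2L)
})

test_that("zero residuals shrink the covariance without moving the mean", {
  eq <- table3_equation()
  base <- tibble::tibble(subject_id = "A", age = 70, sex = "M",
                         hr_bpm = c(61, 120))
  calib <- dplyr::mutate(base,
                         ee_mlkgmin = predict_ee(eq, base)$ee_pred_mlkgmin)
  post <- posterior_random_effects(eq, calib)
  expect_equal(c(post$b0, post$b1), c(0, 0), tolerance = 1e-12)
  Cpost <- matrix(c(post$var_b0, post$cov_b0b1, post$cov_b0b1, post$var_b1), 2)
  expect_true(all(eigen(eq$G - Cpost, symmetric = TRUE)$values > 0))
})

test_that("population predictions reproduce the group-equation arithmetic", {
  eq <- table3_equation()
  q <- tibble::tibble(age = 55.5, sex = "M", hr_bpm = c(62.0, 167.7))
  pred <- predict_ee(eq, q)$ee_pred_mlkgmin
  hand <- -23.046 + 0.339 * c(62.0, 167.7) + 2.241 + 0.099 * 55.5 -
    0.0007 * 55.5 * c(62.0, 167.7)
  expect_equal(pred, hand, tolerance = 1e-12)
  # rounded to the precision of a printed prediction table
  expect_equal(round(pred, 1), c(3.3, 35.0))
})

test_that("subject effects shift predictions linearly", {
  eq <- table3_equation()
  q <- tibble::tibble(subject_id = "A", age = 70, sex = "F",
                      hr_bpm = c(60, 100, 150))
  pop <- predict_ee(eq, q)$ee_pred_mlkgmin
  re <- tibble::tibble(subject_id = "A", k_used = 5L, b0 = 1.3, b1 = -0.02,
                       var_b0 = 0.5, cov_b0b1 = 0, var_b1 = 1e-4)
  subj <- predict_ee(eq, q, ranef = re)$ee_pred_mlkgmin
  expect_equal(subj - pop, 1.3 - 0.02 * q$hr_bpm, tolerance = 1e-12)

  # population line is the prior mean of subject lines
  re_neg <- dplyr::mutate(re, b0 = -b0, b1 = -b1)
  subj_neg <- predict_ee(eq, q, ranef = re_neg)$ee_pred_mlkgmin
  expect_equal((subj + subj_neg) / 2, pop, tolerance = 1e-12)
})

test_that("posterior prediction variance never grows as calibration accumulates", {
  co <- small_cohort(n = 50, seed = 41)
  fit <- fit_hr_ee(co)
  one <- co[co$subject_id == "S0007", ]
  sets <- calibration_scenarios()
  hr_grid <- c(55, 80, 110, 140, 170)
  pv <- sapply(sets, function(lv) {
    calib <- one[as.character(one$level) %in% lv, ]
    re <- if (nrow(calib)) posterior_random_effects(fit, calib) else NULL
    q <- tibble::tibble(subject_id = "S0007", age = one$age[1], sex = one$sex[1],
                        hr_bpm = hr_grid)
    predict_ee(fit, q, ranef = re)$pred_sd_mlkgmin
  })
  # columns ordered none, rest_only, rest_peak, all_five
  for (j in 2:4) expect_true(all(pv[, j] <= pv[, j - 1] + 1e-10))
})

test_that("calibration recovers exact subject effects as noise vanishes", {
  eq <- hr_ee_model(TRUTH_FE, vc = c(sd_b0 = 3.966, sd_b1 = 0.062,
                                     corr_b = -0.874, sd_resid = 1e-6))
  b0 <- 2.4; b1 <- -0.03
  base <- tibble::tibble(subject_id = "A", age = 64, sex = "M",
                         hr_bpm = c(58, 132))
  mu <- predict_ee(eq, base)$ee_pred_mlkgmin
  calib <- dplyr::mutate(base, ee_mlkgmin = mu + b0 + b1 * hr_bpm)
  post <- posterior_random_effects(eq, calib)
  expect_equal(c(post$b0, post$b1), c(b0, b1), tolerance = 1e-4)
})

test_that("unit conversions follow the oxygen energy equivalent", {
  expect_equal(to_kcal_per_min(2.787, 79.2), 1.10365, tolerance = 1e-5)
  expect_equal(to_kcal_per_min(0, 70), 0)
  expect_equal(to_kcal_per_min(10, 100), 5)
  expect_error(to_kcal_per_min(5, 0), "positive")

  expect_equal(daily_bias(0.35), 504)
  expect_equal(daily_bias(0), 0)
  expect_equal(daily_bias(-0.5), -720)
})

test_that("calibration inputs are validated", {
  eq <- table3_equation()
  bad <- tibble::tibble(subject_id = "A", age = c(70, 71), sex = "M",
                        hr_bpm = c(60, 120), ee_mlkgmin = c(3, 20))
  expect_error(posterior_random_effects(eq, bad), "inconsistent")
  expect_warning(predict_ee(eq, tibble::tibble(age = 70, sex = "M", hr_bpm = 250)),
                 "physiologic")
})
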