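test_that("sub-rheobase conditions never produce detections", {
  cfg <- test_cfg()
  cond <- tibble::tibble(amplitude_uA = c(5, 15, 23.9),
                         pulse_width_us = 170, frequency_hz = 300,
                         duration_ms = 166)
  dat <- generate_detection_data(cond, n_trials = 200, cfg, seed = 1)
  expect_equal(dat$activation, rep(0, 3))
  expect_equal(dat$p_detect, rep(0, 3))
  expect_equal(dat$n_detected, rep(0L, 3))
})

test_that("detection rate is one half when the train activation equals theta50", {
  cfg <- test_cfg()
  amp_half <- amplitude_for_activation(cfg$theta50, 170, 300, 166, cfg)
  cond <- tibble::tibble(amplitude_uA = amp_half, pulse_width_us = 170,
                         frequency_hz = 300, duration_ms = 166)
  dat <- generate_detection_data(cond, n_trials = 1e4, cfg, seed = 2)
  expect_lt(abs(dat$n_detected / dat$n_trials - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("synthetic data generation is deterministic given the seed", {
  cfg <- test_cfg()
  cond <- detection_conditions(10, cfg)
  expect_identical(generate_detection_data(cond, 100, cfg, seed = 5),
                   generate_detection_data(cond, 100, cfg, seed = 5))
  expect_identical(generate_brightness_data(cond, 10, 0.05, cfg, seed = 5),
                   generate_brightness_data(cond, 10, 0.05, cfg, seed = 5))
})

test_that("the threshold distribution is recovered within 10% at 20 x 500 trials", {
  cfg <- test_cfg()
  dat <- generate_detection_data(detection_conditions(20, cfg),
                                 n_trials = 500, cfg, seed = 11)
  fit <- fit_threshold_distribution(dat, cfg)
  est <- tidy(fit)
  expect_lt(abs(est$estimate[est$term == "theta50"] - cfg$theta50) /
              cfg$theta50, 0.10)
  expect_lt(abs(est$estimate[est$term == "sigma"] - cfg$sigma) / cfg$sigma,
            0.10)
  expect_gt(glance(fit)$r.squared, 0.9)
})

test_that("a near-deterministic generator yields a near-zero recovered sigma", {
  cfg <- test_cfg(sigma = 1e-12)
  dat <- generate_detection_data(detection_conditions(20, phosim_config()),
                                 n_trials = 500, cfg, seed = 3)
  fit <- fit_threshold_distribution(dat, cfg)
  expect_lt(tidy(fit)$estimate[2], 0.05 * cfg$theta50)
})

test_that("noiseless proportions at normal quantiles are recovered exactly", {
  cfg <- test_cfg()
  z <- seq(-1.8, 1.8, length.out = 13)
  theta_true <- 8e-8
  sigma_true <- 5e-8
  dat <- tibble::tibble(
    activation = theta_true + sigma_true * z,
    n_trials = 1000,
    n_detected = 1000 * pnorm(z))
  fit <- fit_threshold_distribution(dat, cfg)
  est <- tidy(fit)$estimate
  expect_equal(est[1], theta_true, tolerance = 1e-4)
  expect_equal(est[2], sigma_true, tolerance = 1e-4)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-8)
})

test_that("non-identifiable detection data raise an informative error", {
  cfg <- test_cfg()
  all_hit <- tibble::tibble(activation = c(1e-6, 2e-6), n_trials = 100,
                            n_detected = 100)
  expect_error(fit_threshold_distribution(all_hit, cfg), "identifiable")
  none <- tibble::tibble(activation = c(1e-9, 2e-9), n_trials = 100,
                         n_detected = 0)
  expect_error(fit_threshold_distribution(none, cfg), "identifiable")
})

test_that("the brightness sigmoid is recovered within 1% from noiseless data", {
  cfg <- test_cfg()
  dat <- generate_brightness_data(brightness_conditions(15, cfg),
                                  n_repeats = 1, noise_sd = 0, cfg, seed = 1)
  fit <- fit_brightness_sigmoid(dat, cfg)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_lt(abs(est["lambda"] - cfg$lambda) / cfg$lambda, 0.01)
  expect_lt(abs(est["A50"] - cfg$A50) / cfg$A50, 0.01)
  # midpoint identity: predicted brightness at the fitted A50 is one half
  mid <- predict(fit, tibble::tibble(activation = unname(est["A50"])), cfg)
  expect_equal(unname(mid), 0.5)
})

test_that("the brightness sigmoid survives response noise within 10%", {
  cfg <- test_cfg()
  dat <- generate_brightness_data(brightness_conditions(15, cfg),
                                  n_repeats = 20, noise_sd = 0.05, cfg,
                                  seed = 17)
  fit <- fit_brightness_sigmoid(dat, cfg)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_lt(abs(est["lambda"] - cfg$lambda) / cfg$lambda, 0.10)
  expect_lt(abs(est["A50"] - cfg$A50) / cfg$A50, 0.10)
  expect_error(fit_brightness_sigmoid(dat[1, ], cfg), "underdetermined")
})

test_that("the strength-duration line recovers rheobase and chronaxie", {
  I0 <- 23.9
  chronaxie <- 1e-3
  t <- seq(1e-4, 5e-3, length.out = 10)
  exact <- tibble::tibble(duration_s = t, charge_uC = I0 * (chronaxie + t))
  fit <- fit_strength_duration(exact)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_equal(unname(est["I0_uA"]), I0, tolerance = 1e-9)
  expect_equal(unname(est["chronaxie_s"]), chronaxie, tolerance = 1e-9)
  expect_equal(glance(fit)$r.squared, 1)

  noisy <- exact
  noisy$charge_uC <- withr::with_seed(4,
    noisy$charge_uC * (1 + rnorm(10, 0, 0.05)))
  est2 <- setNames(tidy(fit_strength_duration(noisy))$estimate,
                   tidy(fit)$term)
  expect_lt(abs(est2["I0_uA"] - I0) / I0, 0.10)

  flat <- tibble::tibble(duration_s = t, charge_uC = 12)
  expect_warning(fitf <- fit_strength_duration(flat), "degenerate")
  expect_equal(unname(tidy(fitf)$estimate[2]), Inf)
  expect_error(fit_strength_duration(exact[1:2, ]), "3 distinct")
})

test_that("threefold cross-validation predicts held-out detection rates", {
  cfg <- test_cfg()
  dat <- generate_detection_data(detection_conditions(30, cfg),
                                 n_trials = 500, cfg, seed = 23)
  cv <- crossvalidate(dat, fit_threshold_distribution, k = 3, cfg, seed = 1)
  expect_equal(nrow(cv$folds), 3)
  expect_gt(cv$mean_r_squared, 0.8)
  # deterministic fold assignment
  cv2 <- crossvalidate(dat, fit_threshold_distribution, k = 3, cfg, seed = 1)
  expect_identical(cv$folds, cv2$folds)
})

test_that("cross-validation boundary cases behave", {
  cfg <- test_cfg()
  dat <- generate_detection_data(detection_conditions(8, cfg),
                                 n_trials = 400, cfg, seed = 2)
  expect_error(crossvalidate(dat, fit_threshold_distribution, k = 9, cfg),
               "partition")
  # leave-one-condition-out runs end to end
  loo <- crossvalidate(dat, fit_threshold_distribution, k = 8, cfg, seed = 1)
  expect_equal(nrow(loo$folds), 8)
})

test_that("fits are invariant to condition order and trial-count rescaling", {
  cfg <- test_cfg()
  dat <- generate_detection_data(detection_conditions(20, cfg),
                                 n_trials = 400, cfg, seed = 31)
  fit1 <- fit_threshold_distribution(dat, cfg)
  shuffled <- dat[withr::with_seed(1, sample(nrow(dat))), ]
  fit2 <- fit_threshold_distribution(shuffled, cfg)
  expect_equal(tidy(fit1)$estimate, tidy(fit2)$estimate, tolerance = 1e-8)
  scaled <- dat
  scaled$n_trials <- dat$n_trials * 3L
  scaled$n_detected <- dat$n_detected * 3L
  fit3 <- fit_threshold_distribution(scaled, cfg)
  expect_equal(tidy(fit1)$estimate, tidy(fit3)$estimate, tolerance = 1e-8)
})
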