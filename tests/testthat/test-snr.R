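# Analytic phase-noise / SNR machinery and suspension arithmetic.

test_that("mean phase noise is the z-average of per-plane RMS deviations", {
  const <- phase_volume(array(0.7, c(16, 16, 5)), 1:5, 0.1)
  expect_equal(mean_phase_noise(const), 0)

  a <- 0.3
  half <- matrix(c(rep(a, 128), rep(-a, 128)), 16, 16)
  one <- phase_volume(array(half, c(16, 16, 1)), 0, 0.1)
  expect_equal(mean_phase_noise(one), a)
  expect_equal(mean_phase_noise(one, variance = TRUE), a^2)

  # law of large numbers on a 64^3 volume of sigma = 0.1 noise
  set.seed(21)
  noise <- array(rnorm(64^3, sd = 0.1), c(64, 64, 64))
  vol <- phase_volume(noise, 1:64, 0.1)
  # brute-force oracle: recompute the statistic slice by slice
  oracle <- mean(vapply(1:64, function(k) {
    p <- noise[, , k]; sqrt(sum((p - mean(p))^2) / length(p))
  }, numeric(1)))
  expect_equal(mean_phase_noise(vol), oracle, tolerance = 1e-12)
  expect_equal(mean_phase_noise(vol), 0.1, tolerance = 0.02)
})

test_that("phase signal reproduces the printed sample-type values", {
  expect_equal(phase_signal(1.0, 1.42, 1.333, 0.52), 1.05, tolerance = 0.005)
  expect_equal(phase_signal(1.0, 1.388, 1.333, 0.52), 0.66, tolerance = 0.01)
  expect_equal(phase_signal(0.73, 1.388, 1.333, 0.52), 0.48, tolerance = 0.012)
  expect_equal(phase_signal(1, 1.333, 1.333), 0)
})

test_that("noise model evaluates the fitted quadratic in c times L", {
  p <- noise_params()  # k1 = -55, k2 = 0.78, phi_N0 = 0.1
  expect_equal(predict_noise(0, 800, p), 0.1)
  # direct arithmetic of the model at the two reference concentrations
  expect_equal(predict_noise(3e-5, 800, p), 0.11868, tolerance = 1e-4)
  expect_equal(predict_noise(1e-4, 800, p), 0.16196, tolerance = 1e-4)
  expect_error(predict_noise(-1, 800, p), ">= 0")
  expect_error(noise_params(k1 = -1e6, k2 = 0.01, phi_n0 = 0.01), "validity")

  # monotonicity over the declared validity range
  cc <- seq(0, 2e-4, length.out = 50)
  expect_true(all(diff(predict_noise(cc, 800, p)) > 0))
  expect_gt(predict_noise(5e-5, 800, p), predict_noise(5e-5, 200, p))
})

test_that("SNR predictions and attenuation helpers are consistent", {
  p <- noise_params()
  q <- predict_snr(d = 1, n_s = 1.388, c = 3e-5, L = 800, params = p)
  expect_equal(q$attenuation_db, -1.5, tolerance = 0.1)
  q2 <- predict_snr(d = 1, n_s = 1.388, c = 1e-4, L = 800, params = p)
  expect_equal(q2$attenuation_pct, 38.3, tolerance = 0.1)
  # S. warneri at zero concentration: 0.665 / 0.1
  q0 <- predict_snr(d = 1, n_s = 1.388, c = 0, L = 800, params = p)
  expect_equal(q0$snr, phase_signal(1, 1.388) / 0.1, tolerance = 1e-12)
  expect_equal(q0$snr, 6.65, tolerance = 0.01)
  # monotone decreasing in c and in L
  snr_c <- vapply(seq(0, 1e-4, length.out = 20), function(cc)
    predict_snr(d = 1, n_s = 1.42, c = cc, L = 800, params = p)$snr, numeric(1))
  expect_true(all(diff(snr_c) < 0))
  snr_L <- vapply(c(100, 200, 400, 800), function(L)
    predict_snr(d = 1, n_s = 1.42, c = 5e-5, L = L, params = p)$snr, numeric(1))
  expect_true(all(diff(snr_L) < 0))
  expect_warning(predict_snr(d = 1, n_s = 1.30, c = 0, L = 100, params = p), "negative")
})

test_that("noise-parameter fitting is exact on clean tables and robust to noise", {
  k1 <- -55; k2 <- 0.78; phi0 <- 0.1
  tab <- expand.grid(c = c(1e-5, 3e-5, 6e-5, 1e-4), L = c(200, 400))
  tab$noise <- L_noise <- tab$L * (k1 * tab$c^2 + k2 * tab$c) + phi0
  fit <- fit_noise_params(tab, phi_n0 = phi0)
  expect_equal(unname(coef(fit)[c("k1", "k2")]), c(k1, k2), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # fitting the model's own predictions is the identity
  tab2 <- tab; tab2$noise <- predict(fit, tab2)
  refit <- fit_noise_params(tab2, phi_n0 = phi0)
  expect_equal(coef(refit), coef(fit), tolerance = 1e-9)

  expect_error(fit_noise_params(data.frame(c = rep(2e-5, 3), L = 200,
                                           noise = 0.11)), "underdetermined")

  # Monte-Carlo recovery: 6 concentrations x 2 heights x 3 replicates,
  # 5% multiplicative noise; k2 within 15% of truth (median of 100 trials)
  set.seed(99)
  base <- expand.grid(c = c(5e-6, 1e-5, 2e-5, 4e-5, 7e-5, 1e-4),
                      L = c(200, 400), rep = 1:3)
  mu <- base$L * (k1 * base$c^2 + k2 * base$c) + phi0
  k2_hat <- vapply(1:100, function(i) {
    obs <- base
    obs$noise <- mu * (1 + rnorm(nrow(base), 0, 0.05))
    coef(fit_noise_params(obs, phi_n0 = phi0))[["k2"]]
  }, numeric(1))
  expect_lt(abs(median(k2_hat) - k2) / k2, 0.15)
})

test_that("joint fitting of the base level is available behind a flag", {
  tab <- expand.grid(c = c(1e-5, 5e-5, 1e-4), L = c(200, 400))
  tab$noise <- tab$L * (-55 * tab$c^2 + 0.78 * tab$c) + 0.07
  fit <- fit_noise_params(tab, fit_phi_n0 = TRUE)
  expect_equal(unname(coef(fit)), c(-55, 0.78, 0.07), tolerance = 1e-8)
  expect_s3_class(as_noise_params(fit), "noise_params")
})

test_that("stock suspension arithmetic matches the silica reference", {
  expect_equal(stock_concentration(0.985, 1.85, 5), 5.405e10, tolerance = 0.005)
  expect_equal(stock_concentration(0.985, 1.85, 0), 0)
  # d^3 scaling
  expect_equal(stock_concentration(2 * 0.985, 1.85, 5),
               stock_concentration(0.985, 1.85, 5) / 8, tolerance = 1e-12)
  expect_error(stock_concentration(0, 1, 5), "> 0")
  # 1:8000 dilution endpoint
  expect_equal(stock_concentration() / 8000, 6.756e6, tolerance = 0.005)
  # OD600 labels for simulated bacterial series
  expect_equal(unname(od600_cells_per_ml["s_warneri"]), 7e8)
  expect_equal(unname(od600_cells_per_ml["e_coli"]), 5e8)
})
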