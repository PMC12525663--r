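# Wave-optics primitives: angular-spectrum propagation, super-Gaussian
# apertures, Zernike decomposition.

test_that("sampled_field validates its inputs", {
  expect_s3_class(flat_field(), "sampled_field")
  expect_error(sampled_field(matrix(1 + 0i, 1, 4), 0.1), "dimensions")
  expect_error(sampled_field(matrix(1 + 0i, 4, 4), -1), "pitch")
  expect_error(sampled_field(matrix(1 + 0i, 4, 4), 0.1, medium_index = 0.5), "medium_index")
})

test_that("propagation at z = 0 is the identity and plane waves are eigenfunctions", {
  f <- gaussian_field(5)
  expect_identical(propagate_angular_spectrum(f, 0)$amplitude, f$amplitude)
  pw <- flat_field(32)
  out <- propagate_angular_spectrum(pw, 37.3)
  expect_equal(Mod(out$amplitude), Mod(pw$amplitude), tolerance = 1e-12)
  expect_error(propagate_angular_spectrum(pw, NaN), "finite")
})

test_that("Gaussian beam widens by sqrt(2) at the Rayleigh range", {
  w0 <- 5; lam <- 0.52
  zR <- pi * w0^2 / lam  # oracle: analytic Gaussian-beam propagation
  f <- gaussian_field(w0, n = 256, pitch = 0.35, wavelength = lam)
  out <- propagate_angular_spectrum(f, zR)
  I <- Mod(out$amplitude)^2
  xy <- coords(256, 0.35)
  w <- 2 * sqrt(sum(I * outer(rep(1, 256), xy^2)) / sum(I))  # 1/e^2 radius
  expect_equal(w / w0, sqrt(2), tolerance = 0.01)
})

test_that("propagation conserves energy and composes over distances", {
  f <- gaussian_field(5)
  e0 <- sum(Mod(f$amplitude)^2)
  fz <- propagate_angular_spectrum(f, 80)
  expect_equal(sum(Mod(fz$amplitude)^2), e0, tolerance = 1e-10)
  two <- propagate_angular_spectrum(propagate_angular_spectrum(f, 30), 20)
  one <- propagate_angular_spectrum(f, 50)
  expect_lt(max(Mod(two$amplitude - one$amplitude)) / max(Mod(one$amplitude)), 1e-10)
  # forward then back returns the band-limited input
  back <- propagate_angular_spectrum(fz, -80)
  expect_lt(max(Mod(back$amplitude - f$amplitude)), 1e-9)
})

test_that("super-Gaussian mask matches its closed form", {
  m <- super_gaussian_mask(c(65, 65), center = c(33, 33), widths = 10, order = 4)
  expect_equal(m[33, 33], 1)
  expect_equal(m[33, 43], exp(-1))  # r = sigma, any order
  # order 10: near top-hat (direct evaluation of exp(-0.8^20), exp(-1.2^20))
  m10 <- super_gaussian_mask(c(65, 65), c(33, 33), 10, order = 10)
  expect_gte(m10[33, 41], 0.98)         # r = 0.8 sigma
  expect_lte(m10[33, 45], 1e-10)        # r = 1.2 sigma
  expect_true(all(m >= 0 & m <= 1))
  # monotone non-increasing along a ray from the centre
  expect_true(all(diff(m[33, 33:65]) <= 0))
  expect_error(super_gaussian_mask(c(8, 8), c(4, 4), -1), "positive")
})

test_that("large-order super-Gaussian converges to the hard aperture", {
  m <- super_gaussian_mask(c(129, 129), c(65, 65), widths = 30, order = 50)
  x <- seq_len(129) - 65
  r <- sqrt(outer(x^2, x^2, `+`))
  hard <- r <= 30
  disagree <- abs(m - hard) > 0.5
  expect_true(all(abs(r[disagree] - 30) <= 2))  # only within a 2-pixel annulus
})

test_that("Zernike fit recovers pistons, tilts and synthesized surfaces", {
  flat <- matrix(0.7, 64, 64)
  zf <- fit_zernike(flat, n_terms = 10)
  expect_equal(unname(coef(zf)[1]), 0.7, tolerance = 1e-10)
  expect_true(all(abs(coef(zf)[-1]) <= 1e-10))

  disk <- inscribed_disk(c(64, 64))
  x <- (seq_len(64) - disk$center[1]) / disk$radius
  tilt <- matrix(x, 64, 64, byrow = TRUE)  # pure x-tilt
  zt <- fit_zernike(tilt, n_terms = 10, disk = disk)
  expect_lt(zt$residual_rms, 1e-8)
  expect_true(all(abs(coef(zt)[-2]) <= 1e-8))  # only Z2 (x-tilt) survives

  set.seed(42)
  co <- rnorm(15, 0, 0.5)
  surf <- zernike_surface(list(coefficients = co, disk = inscribed_disk(c(256, 256))),
                          c(256, 256))
  zr <- fit_zernike(surf, n_terms = 15)
  expect_equal(unname(coef(zr)), co, tolerance = 1e-6)

  expect_error(fit_zernike(matrix(0, 4, 4), n_terms = 100), "ill-posed")
})

test_that("Zernike fitting is a projection (refit is the identity)", {
  set.seed(7)
  noisy <- matrix(rnorm(64^2), 64, 64)
  z1 <- fit_zernike(noisy, n_terms = 12)
  z2 <- fit_zernike(z1$surface, n_terms = 12)
  expect_equal(coef(z2), coef(z1), tolerance = 1e-10)
})
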