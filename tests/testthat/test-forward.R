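# Synthetic-data generator: particle scenes, phase masks, background
# screens and simulated off-axis holograms.

test_that("generate_scene draws Poisson counts at the target density", {
  expect_error(generate_scene(-1, 10, 10, 10), ">= 0")
  expect_identical(nrow(generate_scene(0, 120, 120, 200, seed = 5)$particles), 0L)

  # Poisson oracle: mean count over 200 seeds ~ c*V = 288
  counts <- vapply(1:200, function(s)
    nrow(generate_scene(1e-4, 120, 120, 200, seed = s)$particles), numeric(1))
  expect_lt(abs(mean(counts) - 288), 3 * sqrt(288 / 200))

  sc <- generate_scene(1e-4, 120, 120, 200, seed = 3)
  p <- sc$particles
  expect_true(all(p$z >= 0 & p$z <= 200))
  expect_true(all(p$x >= 0 & p$x <= 120 & p$y >= 0 & p$y <= 120))
  expect_equal(scene_concentration(sc), nrow(p) / (120 * 120 * 200))
  # reproducibility
  expect_identical(generate_scene(1e-4, 120, 120, 200, seed = 3)$particles, p)
})

test_that("rod orientations are drawn unless the template fixes one", {
  rod <- particle_spec("rod", 0.73, length = 2, n = 1.388)
  sc <- generate_scene(2e-4, 60, 60, 100, rod, seed = 2)
  u <- with(sc$particles, ux^2 + uy^2 + uz^2)
  expect_equal(u, rep(1, nrow(sc$particles)), tolerance = 1e-12)
  fixed <- particle_spec("rod", 0.73, length = 2, n = 1.388, orientation = c(0, 0, 1))
  sf <- generate_scene(2e-4, 60, 60, 100, fixed, seed = 2)
  expect_true(all(sf$particles$uz == 1))
})

test_that("particle phase masks carry the projected optical path", {
  sph <- particle_spec("sphere", 1, n = 1.42)
  m <- particle_phase_mask(sph, c(128, 128), pitch = 0.05, wavelength = 0.52,
                           medium_index = 1.333)
  expect_equal(max(m), 2 * pi * 1 * (1.42 - 1.333) / 0.52, tolerance = 0.01)
  expect_equal(max(m), 1.05, tolerance = 0.01)  # printed phase-signal value
  matched <- particle_phase_mask(particle_spec("sphere", 1, n = 1.333 + 1e-15),
                                 c(64, 64), pitch = 0.05)
  expect_equal(max(abs(matched)), 0, tolerance = 1e-10)

  rod <- particle_spec("rod", 0.73, length = 2, n = 1.388)
  perp <- particle_phase_mask(rod, c(128, 128), pitch = 0.05,
                              orientation = c(1, 0, 0))
  expect_equal(max(perp), 0.485, tolerance = 0.01)  # 2 pi d (nS-nM)/lambda
  par <- particle_phase_mask(rod, c(128, 128), pitch = 0.05,
                             orientation = c(0, 0, 1))
  expect_gt(max(par), max(perp))  # axial rods project their full length
  obl <- particle_phase_mask(rod, c(128, 128), pitch = 0.05,
                             orientation = c(0, 1, 1) / sqrt(2))
  expect_gt(max(obl), max(perp))
  expect_lt(max(obl), max(par))

  expect_error(particle_phase_mask(sph, c(8, 8), pitch = 0.05), "larger than the grid")
})

test_that("background screens hit their RMS and are seed-deterministic", {
  expect_error(background_phase_screen(c(32, 32), -0.1), ">= 0")
  expect_true(all(background_phase_screen(c(32, 32), 0) == 0))
  s <- background_phase_screen(c(256, 256), 0.1, corr_length = 1, seed = 9)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_gte(sqrt(mean(s^2)), 0.095)
  expect_lte(sqrt(mean(s^2)), 0.105)
  expect_identical(background_phase_screen(c(256, 256), 0.1, corr_length = 1, seed = 9), s)
})

test_that("simulated holograms behave like two-beam interference", {
  fov <- 128 * 0.117
  # no particles, no noise, no tilt: uniform intensity
  sc0 <- generate_scene(0, fov, fov, 50, base_noise_rms = 0, seed = 1)
  acq0 <- acquisition_spec(grid = 128L, carrier = c(0, 0.0), snap_carrier = FALSE)
  expect_error(acquisition_spec(grid = 128L, carrier = 1 / 0.117), "Nyquist")
  h0 <- simulate_hologram(sc0, acq0)
  expect_lt(diff(range(h0$intensity)) / mean(h0$intensity), 1e-9)

  # tilt only: spectral maximum at the pixel nearest the carrier
  acq <- acquisition_spec(grid = 128L, tilt_y = 0.06, snap_carrier = FALSE)
  h <- simulate_hologram(sc0, acq)
  S <- Mod(stats::fft(h$intensity))
  S[1, 1] <- 0  # ignore DC
  top <- which(S == max(S), arr.ind = TRUE)
  f_row <- (top[, 1] - 1)          # unshifted index along y
  f_row <- ifelse(f_row > 64, f_row - 128, f_row)
  expected_px <- sin(0.06) / 0.52 * 128 * 0.117
  expect_true(any(abs(abs(f_row) - expected_px) <= 1))

  # intensity is real: spectrum Hermitian (twin at the mirrored carrier)
  Sc <- stats::fft(h$intensity)
  expect_equal(Sc[2, 2], Conj(Sc[128, 128]), tolerance = 1e-6 * Mod(Sc[1, 1]))
})

test_that("reference amplitude scales the carrier linearly and DC quadratically", {
  fov <- 128 * 0.117
  sc <- generate_scene(0, fov, fov, 50, base_noise_rms = 0.05, seed = 4)
  carrier_px <- function(a) {
    acq <- acquisition_spec(grid = 128L, ref_ratio = a)
    h <- simulate_hologram(sc, acq)
    S <- Mod(stats::fft(h$intensity))
    kc <- round(acq$carrier[2] * 128 * 0.117)
    c(dc = S[1, 1], carrier = S[kc + 1, 1])
  }
  s1 <- carrier_px(1); s2 <- carrier_px(2)
  expect_equal(unname(s2["carrier"] / s1["carrier"]), 2, tolerance = 0.05)
  expect_gte(unname(s2["dc"] / s1["dc"]), 2.4)  # dominated by the a^2 term
})

test_that("ground truth records exact concentration and defocus", {
  fov <- 64 * 0.117
  sc <- generate_scene(5e-3, fov, fov, 20, base_noise_rms = 0, seed = 8)
  h <- simulate_hologram(sc, acquisition_spec(grid = 64L), focus_z = 10)
  tr <- hologram_truth(h)
  expect_equal(tr$concentration_um3, nrow(sc$particles) / (fov * fov * 20))
  expect_equal(tr$particles$defocus, tr$particles$z - 10)
})
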