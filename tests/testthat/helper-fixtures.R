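# shared fixtures: small grids keep the unit tests fast; the acceptance
# tests use the full study geometry

# centred coordinates of an n-grid at pitch p
coords <- function(n, p) (seq_len(n) - (floor(n / 2) + 1)) * p

# plane-wave field
flat_field <- function(n = 64, pitch = 0.25, wavelength = 0.52, n_med = 1) {
  sampled_field(matrix(1 + 0i, n, n), pitch, wavelength, n_med)
}

# Gaussian-amplitude beam of waist w0 (um)
gaussian_field <- function(w0, n = 256, pitch = 0.35, wavelength = 0.52) {
  xy <- coords(n, pitch)
  R2 <- outer(xy^2, xy^2, `+`)
  sampled_field(matrix(complex(real = exp(-R2 / w0^2)), n, n), pitch, wavelength, 1)
}

# smooth Gaussian phase blob (peak `a` rad, width sigma um) on an n-grid
blob_phase <- function(n, pitch, a = 1, sigma = 3) {
  xy <- coords(n, pitch)
  a * exp(-outer(xy^2, xy^2, `+`) / (2 * sigma^2))
}

# off-axis hologram of a pure phase map under the default carrier
phase_hologram <- function(phase, pitch = 0.117, wavelength = 0.52,
                           grid = nrow(phase)) {
  acq <- acquisition_spec(grid = grid, pitch = pitch, wavelength = wavelength)
  xy <- coords(grid, pitch)
  ramp <- outer(xy * acq$carrier[2], xy * acq$carrier[1], `+`)
  I <- Mod(exp(1i * phase) + exp(-2i * pi * ramp))^2
  hologram(I, acq)
}

# synthetic phase volume with Gaussian particles at given centres
synthetic_volume <- function(centers, peak = 1.0, sigma_l = 0.4, sigma_z = 2,
                             n = 96, pitch = 0.234, zs = seq(-20, 20, by = 1)) {
  xy <- coords(n, pitch)
  arr <- array(0, c(n, n, length(zs)))
  for (k in seq_along(zs)) {
    sl <- matrix(0, n, n)
    for (i in seq_len(nrow(centers))) {
      g <- exp(-((zs[k] - centers[i, 3]) / sigma_z)^2 / 2)
      if (g < 1e-4) next
      sl <- sl + peak * g *
        exp(-(outer((xy - centers[i, 2])^2, (xy - centers[i, 1])^2, `+`)) /
              (2 * sigma_l^2))
    }
    arr[, , k] <- sl
  }
  phase_volume(arr, zs, pitch)
}
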