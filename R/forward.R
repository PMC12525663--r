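# Seeded forward model: particle scenes in microfluidic chambers and the
# off-axis holograms they produce.  Every simulated hologram carries its
# ground truth, which is what the reconstruction/counting tests are scored
# against.

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Particle template
#'
#' Geometry and refractive index of a single particle.  Rods are modelled as
#' capsules (cylinder with hemispherical caps), the standard E. coli
#' approximation; `length` is the end-to-end length.
#'
#' @param shape `"sphere"` or `"rod"`.
#' @param diameter thickness d, um (> 0).
#' @param length end-to-end length, um; rods only, must be >= `diameter`.
#' @param n refractive index of the particle (> 1).
#' @param orientation unit 3-vector (rods only); `NULL` means "draw at random
#'   per particle" when placed in a scene.
#' @return object of class `particle_spec`.
#' @export
particle_spec <- function(shape = c("sphere", "rod"), diameter, length = NULL,
                          n, orientation = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(diameter) || diameter <= 0) stop("`diameter` must be > 0", call. = FALSE)
  if (!is.numeric(n) || n <= 1) stop("refractive index `n` must be > 1", call. = FALSE)
  if (shape == "rod") {
    if (is.null(length) || length < diameter)
      stop("rods need `length` >= `diameter`", call. = FALSE)
    if (!is.null(orientation)) orientation <- orientation / sqrt(sum(orientation^2))
  } else length <- diameter
  structure(list(shape = shape, diameter = diameter, length = length,
                 n = n, orientation = orientation),
            class = "particle_spec")
}

#' Draw a particle scene at a target concentration
#'
#' Particle count is Poisson with mean `concentration * chamber volume`;
#' positions are uniform in the chamber box (z in `[0, L]`); rod
#' orientations are uniform on the sphere unless the template fixes one.
#' Fully reproducible from `seed`.
#'
#' @param concentration particles/um^3 (>= 0).  Divide cells/mL by 1e12 to
#'   convert.
#' @param width,height lateral extent of the simulated field, um.
#' @param L chamber height, um.
#' @param template a [particle_spec()].
#' @param medium_index refractive index of the suspension medium.
#' @param base_noise_rms target RMS of the base-level background phase
#'   screen phi_N0, rad.
#' @param noise_corr_length correlation length of the background screen, um.
#' @param seed integer seed.
#' @return object of class `holo_scene` with a `particles` data frame
#'   (x, y, z in um; chamber coordinates, z in `[0, L]`) and orientation
#'   columns `ux, uy, uz` for rods.
#' @export
generate_scene <- function(concentration, width, height, L,
                           template = particle_preset("microsphere"),
                           medium_index = .holo_defaults$medium_index,
                           base_noise_rms = 0.1, noise_corr_length = 1,
                           seed = 1L) {
  if (!is.numeric(concentration) || concentration < 0)
    stop("`concentration` must be >= 0", call. = FALSE)
  stopifnot(width > 0, height > 0, L > 0, base_noise_rms >= 0)
  vol <- width * height * L
  .with_seed(seed, {
    n <- rpois(1L, concentration * vol)
    particles <- data.frame(
      x = runif(n, 0, width), y = runif(n, 0, height), z = runif(n, 0, L)
    )
    if (template$shape == "rod") {
      if (is.null(template$orientation)) {
        uz <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
        s <- sqrt(pmax(0, 1 - uz^2))
        particles$ux <- s * cos(phi); particles$uy <- s * sin(phi); particles$uz <- uz
      } else {
        particles$ux <- template$orientation[1]
        particles$uy <- template$orientation[2]
        particles$uz <- template$orientation[3]
      }
    }
    structure(
      list(width = width, height = height, L = L,
           medium_index = medium_index, template = template,
           particles = particles, base_noise_rms = base_noise_rms,
           noise_corr_length = noise_corr_length, seed = seed),
      class = "holo_scene"
    )
  })
}

#' @export
print.holo_scene <- function(x, ...) {
  cat(sprintf(
    "<holo_scene> %d %s(s) in %.3g x %.3g x %.3g um^3 (c = %.3g/um^3 = %.3g/mL), phiN0 %.3g rad\n",
    nrow(x$particles), x$template$shape, x$width, x$height, x$L,
    scene_concentration(x), scene_concentration(x) * 1e12, x$base_noise_rms))
  invisible(x)
}

#' Ground-truth concentration of a scene (particles/um^3)
#' @param scene a `holo_scene`.
#' @export
scene_concentration <- function(scene) {
  nrow(scene$particles) / (scene$width * scene$height * scene$L)
}

# capsule chord length along the optical (z) axis; s = coordinate along the
# in-plane axis projection, q = perpendicular in-plane distance (both um)
.capsule_chord_z <- function(X, Y, u, r, half_cyl) {
  uz <- u[3]
  if (abs(uz) < 1e-9) {          # axis in the sample plane: analytic
    a <- u[1:2]; a <- a / sqrt(sum(a^2))
    s <- X * a[1] + Y * a[2]
    q2 <- (X - s * a[1])^2 + (Y - s * a[2])^2
    out <- matrix(0, nrow(X), ncol(X))
    cyl <- abs(s) <= half_cyl & q2 < r^2
    out[cyl] <- 2 * sqrt(r^2 - q2[cyl])
    e2 <- (abs(s) - half_cyl)^2 + q2
    cap <- abs(s) > half_cyl & e2 < r^2
    out[cap] <- 2 * sqrt(r^2 - e2[cap])
    return(out)
  }
  if (abs(abs(uz) - 1) < 1e-9) { # axis along the optical axis: analytic
    q2 <- X^2 + Y^2
    out <- matrix(0, nrow(X), ncol(X))
    inside <- q2 < r^2
    out[inside] <- 2 * half_cyl + 2 * sqrt(r^2 - q2[inside])
    return(out)
  }
  # oblique: midpoint quadrature of the z-indicator of the capsule
  zmax <- half_cyl * abs(uz) + r
  nzq <- min(2048L, max(256L, ceiling(200 * 2 * zmax / r)))
  dz <- 2 * zmax / nzq
  zq <- -zmax + (seq_len(nzq) - 0.5) * dz
  out <- matrix(0, nrow(X), ncol(X))
  for (z in zq) {
    tproj <- pmin(pmax(X * u[1] + Y * u[2] + z * u[3], -half_cyl), half_cyl)
    d2 <- (X - tproj * u[1])^2 + (Y - tproj * u[2])^2 + (z - tproj * u[3])^2
    out <- out + dz * (d2 <= r^2)
  }
  out
}

#' Projected phase mask of a single particle
#'
#' Thin-object (projection) approximation: the phase at each pixel is
#' `2 pi (n_S - n_M) t(x, y) / lambda` with `t` the chord thickness of the
#' particle along the optical axis.  For a sphere the peak equals the Eq.-style
#' phase signal `2 pi d (n_S - n_M) / lambda`.
#'
#' @param particle a [particle_spec()].
#' @param grid_shape `c(ny, nx)` pixels.
#' @param pitch um/pixel.
#' @param wavelength vacuum wavelength, um.
#' @param medium_index refractive index of the medium.
#' @param center lateral particle centre `c(x, y)` in centred coordinates, um.
#' @param orientation unit 3-vector overriding the template's (rods).
#' @return numeric matrix of phase values, rad (compact support).
#' @export
particle_phase_mask <- function(particle, grid_shape,
                                pitch = .holo_defaults$pitch,
                                wavelength = .holo_defaults$wavelength,
                                medium_index = .holo_defaults$medium_index,
                                center = c(0, 0), orientation = NULL) {
  stopifnot(inherits(particle, "particle_spec"))
  ext <- particle$length
  if (ext > min(grid_shape) * pitch)
    stop("particle larger than the grid", call. = FALSE)
  xs <- .centered_coords(grid_shape[2], pitch) - center[1]
  ys <- .centered_coords(grid_shape[1], pitch) - center[2]
  r <- particle$diameter / 2
  # work on a bounding sub-grid, paste back into the full mask
  pad <- ext / 2 + pitch
  ix <- which(abs(xs) <= pad); iy <- which(abs(ys) <= pad)
  mask <- matrix(0, grid_shape[1], grid_shape[2])
  if (!length(ix) || !length(iy)) return(mask)
  X <- matrix(xs[ix], length(iy), length(ix), byrow = TRUE)
  Y <- matrix(ys[iy], length(iy), length(ix))
  if (particle$shape == "sphere") {
    q2 <- X^2 + Y^2
    t <- matrix(0, nrow(X), ncol(X))
    inside <- q2 < r^2
    t[inside] <- 2 * sqrt(r^2 - q2[inside])
  } else {
    u <- if (!is.null(orientation)) orientation else particle$orientation
    if (is.null(u)) u <- c(1, 0, 0)
    u <- u / sqrt(sum(u^2))
    t <- .capsule_chord_z(X, Y, u, r, (particle$length - particle$diameter) / 2)
  }
  mask[iy, ix] <- 2 * pi * (particle$n - medium_index) * t / wavelength
  mask
}

#' Smooth random background phase screen
#'
#' Zero-mean Gaussian random field, smoothed to the requested correlation
#' length and rescaled to the target RMS.  Models the base-level phase noise
#' contributed by chamber surface roughness and material inhomogeneity.
#' Bitwise-reproducible from `seed`.
#'
#' @param grid_shape `c(ny, nx)`.
#' @param target_rms rad (>= 0).
#' @param corr_length Gaussian correlation length, um.
#' @param pitch um/pixel.
#' @param seed integer seed.
#' @return numeric matrix, rad.
#' @export
background_phase_screen <- function(grid_shape, target_rms, corr_length = 1,
                                    pitch = .holo_defaults$pitch, seed = 1L) {
  if (!is.numeric(target_rms) || target_rms < 0)
    stop("`target_rms` must be >= 0", call. = FALSE)
  if (target_rms == 0) return(matrix(0, grid_shape[1], grid_shape[2]))
  .with_seed(seed, {
    w <- matrix(rnorm(prod(grid_shape)), grid_shape[1], grid_shape[2])
    fy <- .fft_freq(grid_shape[1], pitch)
    fx <- .fft_freq(grid_shape[2], pitch)
    G <- exp(-2 * pi^2 * corr_length^2 * outer(fy^2, fx^2, `+`))
    s <- Re(fft(fft(w) * G, inverse = TRUE)) / length(w)
    s <- s - mean(s)
    s * (target_rms / sqrt(mean(s^2)))
  })
}

#' Acquisition geometry of the off-axis recording
#'
#' The off-axis carrier can be given either as a physical reference tilt
#' `tilt_y` (carrier `sin(tilt_y)/lambda` along +y) or directly as a spatial
#' frequency `carrier = c(fx, fy)` in cycles/um.  The latter is the native
#' parameterisation for a demagnifying microscope, where the camera-space
#' tilt maps to object-space carrier frequencies that may exceed `1/lambda`.
#' The carrier must stay below the Nyquist frequency `1/(2 pitch)` in each
#' axis; by default it is snapped to the nearest DFT bin so demodulation by
#' an integer spectral shift is exact.
#'
#' @param grid grid size in pixels (square grid `grid x grid`).
#' @param pitch object-space pixel pitch, um.
#' @param wavelength vacuum wavelength, um.
#' @param tilt_y reference tilt, rad (used when `carrier` is `NULL`).
#' @param carrier carrier frequency `c(fx, fy)`, cycles/um; a scalar means
#'   `c(0, fy)`.  Default `0.3/pitch` along +y.
#' @param ref_ratio reference/object amplitude ratio (> 0).
#' @param snap_carrier snap the carrier to the nearest DFT bin.
#' @param shot_noise add Poisson shot noise to the intensity.
#' @param photons photon budget per pixel (mean) when `shot_noise` is on.
#' @param seed seed for the shot-noise draw.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(grid = 256L, pitch = .holo_defaults$pitch,
                             wavelength = .holo_defaults$wavelength,
                             tilt_y = NULL, carrier = NULL, ref_ratio = 1,
                             snap_carrier = TRUE, shot_noise = FALSE,
                             photons = 1e4, seed = NULL) {
  if (ref_ratio <= 0) stop("`ref_ratio` must be > 0", call. = FALSE)
  if (is.null(carrier)) {
    carrier <- if (!is.null(tilt_y)) c(0, sin(tilt_y) / wavelength)
               else c(0, 0.3 / pitch)
  }
  if (length(carrier) == 1L) carrier <- c(0, carrier)
  if (snap_carrier) carrier <- round(carrier * grid * pitch) / (grid * pitch)
  nyq <- 1 / (2 * pitch)
  if (any(abs(carrier) >= nyq))
    stop("off-axis carrier at or above the Nyquist frequency 1/(2*pitch)",
         call. = FALSE)
  structure(
    list(grid = as.integer(grid), pitch = pitch, wavelength = wavelength,
         tilt_y = tilt_y, carrier = carrier, ref_ratio = ref_ratio,
         shot_noise = shot_noise, photons = photons, seed = seed),
    class = "acquisition_spec"
  )
}

#' Simulate an off-axis hologram of a scene
#'
#' Multislice forward model: particles are binned to axial slices at
#' `slice_step`, their projected phase masks multiply the object wave, and
#' the angular spectrum method propagates between slices (in the chamber
#' medium) and finally to the focus plane.  The background phase screen is
#' inserted as a single thin slab at the chamber mid-plane.  A tilted plane
#' reference wave is added and the interference intensity recorded.
#'
#' @param scene a [generate_scene()] result.
#' @param acq an [acquisition_spec()]; its physical field
#'   `grid * pitch` must match the scene's lateral extent.
#' @param focus_z focus plane in chamber coordinates, um; default mid-chamber
#'   `L/2`.
#' @param slice_step axial bin width of the multislice model, um.
#' @return object of class `hologram` (non-negative intensity matrix plus
#'   `acq`), with a `truth` attribute carrying the particle table in centred
#'   coordinates (`x_c`, `y_c`, `defocus = z - focus_z`), the true
#'   concentration, and the scene.
#' @export
simulate_hologram <- function(scene, acq, focus_z = NULL,
                              slice_step = .holo_defaults$step) {
  stopifnot(inherits(scene, "holo_scene"), inherits(acq, "acquisition_spec"))
  n <- acq$grid
  if (abs(scene$width - n * acq$pitch) > acq$pitch ||
      abs(scene$height - n * acq$pitch) > acq$pitch)
    stop("scene lateral extent does not match acquisition grid * pitch",
         call. = FALSE)
  if (is.null(focus_z)) focus_z <- scene$L / 2

  # slab phases: particles binned by z, plus the mid-plane noise screen
  p <- scene$particles
  slabs <- list()
  if (nrow(p)) {
    bin <- round(p$z / slice_step) * slice_step
    for (zb in sort(unique(bin))) {
      rows <- which(bin == zb)
      ph <- matrix(0, n, n)
      for (i in rows) {
        ori <- if (scene$template$shape == "rod")
          c(p$ux[i], p$uy[i], p$uz[i]) else NULL
        ph <- ph + particle_phase_mask(
          scene$template, c(n, n), acq$pitch, acq$wavelength,
          scene$medium_index,
          center = c(p$x[i] - scene$width / 2, p$y[i] - scene$height / 2),
          orientation = ori)
      }
      slabs[[length(slabs) + 1L]] <- list(z = zb, phase = ph)
    }
  }
  if (scene$base_noise_rms > 0) {
    # the screen's fluctuation power divides between the phase and amplitude
    # quadratures once propagated away from its plane; sqrt(2) keeps the
    # volume-averaged phase-noise statistic of an empty-chamber
    # reconstruction at the configured base level
    screen <- background_phase_screen(c(n, n), scene$base_noise_rms * sqrt(2),
                                      scene$noise_corr_length, acq$pitch,
                                      seed = scene$seed + 7919L)
    zb <- scene$L / 2
    hit <- which(vapply(slabs, function(s) abs(s$z - zb) < slice_step / 2, logical(1)))
    if (length(hit)) slabs[[hit[1]]]$phase <- slabs[[hit[1]]]$phase + screen
    else slabs[[length(slabs) + 1L]] <- list(z = zb, phase = screen)
  }
  ord <- order(vapply(slabs, `[[`, numeric(1), "z"))
  slabs <- slabs[ord]

  U <- sampled_field(matrix(1 + 0i, n, n), acq$pitch, acq$wavelength,
                     scene$medium_index)
  cur_z <- if (length(slabs)) slabs[[1]]$z else focus_z
  for (s in slabs) {
    U <- propagate_angular_spectrum(U, s$z - cur_z)
    U$amplitude <- U$amplitude * exp(1i * s$phase)
    cur_z <- s$z
  }
  U <- propagate_angular_spectrum(U, focus_z - cur_z)

  xy <- .centered_coords(n, acq$pitch)
  ramp <- outer(xy * acq$carrier[2], xy * acq$carrier[1], `+`)  # fy*y + fx*x
  UR <- acq$ref_ratio * exp(-2i * pi * ramp)  # real-image lobe lands at +f
  I <- Mod(U$amplitude + UR)^2
  if (isTRUE(acq$shot_noise)) {
    I <- .with_seed(if (is.null(acq$seed)) scene$seed + 104729L else acq$seed, {
      scale <- acq$photons / mean(I)
      rpois(length(I), as.vector(I) * scale) / scale
    })
    I <- matrix(I, n, n)
  }

  truth <- list(
    particles = if (nrow(p)) cbind(p,
      x_c = p$x - scene$width / 2, y_c = p$y - scene$height / 2,
      defocus = p$z - focus_z) else p,
    concentration_um3 = scene_concentration(scene),
    concentration_ml = scene_concentration(scene) * 1e12,
    focus_z = focus_z, scene = scene)
  structure(list(intensity = I, acq = acq), class = "hologram", truth = truth)
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d px, pitch %.4g um, carrier (%.3g, %.3g) cyc/um\n",
              nrow(x$intensity), ncol(x$intensity), x$acq$pitch,
              x$acq$carrier[1], x$acq$carrier[2]))
  invisible(x)
}

#' Ground truth of a simulated hologram
#' @param holo a simulated [simulate_hologram()] result.
#' @return the `truth` attribute (particle table, concentration, scene).
#' @export
hologram_truth <- function(holo) attr(holo, "truth")
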