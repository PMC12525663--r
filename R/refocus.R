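# Volumetric numerical refocusing: propagate the corrected wavefield through
# the chamber, collect the per-plane phase, and optionally subtract the
# phase of a propagated idealized (constant-phase) field to cancel
# diffraction ringing introduced by refocusing.

#' Phase z-stack
#'
#' @param phase 3D array `(y, x, z)`, rad.
#' @param z_positions strictly increasing, uniformly spaced, um.
#' @param pitch lateral um/pixel.
#' @param provenance free-form identifier of the source field.
#' @return object of class `phase_volume`.
#' @export
phase_volume <- function(phase, z_positions, pitch, provenance = NULL) {
  stopifnot(is.array(phase), length(dim(phase)) == 3L)
  nz <- dim(phase)[3]
  if (length(z_positions) != nz || nz < 1L)
    stop("`z_positions` must have one entry per slice", call. = FALSE)
  if (nz > 1L) {
    dz <- diff(z_positions)
    if (any(dz <= 0) || max(abs(dz - dz[1])) > 1e-9 * max(abs(dz)))
      stop("`z_positions` must be strictly increasing and uniform", call. = FALSE)
  }
  structure(list(phase = phase, z_positions = z_positions, pitch = pitch,
                 provenance = provenance),
            class = "phase_volume")
}

#' @export
print.phase_volume <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("<phase_volume> %d x %d px x %d slices, z in [%.4g, %.4g] um (step %.3g), pitch %.4g um\n",
              d[1], d[2], d[3], min(x$z_positions), max(x$z_positions),
              if (d[3] > 1) diff(x$z_positions)[1] else NA_real_, x$pitch))
  invisible(x)
}

#' @export
dim.phase_volume <- function(x) dim(x$phase)

# axial step of a phase volume (um); falls back to pitch for single slices
.vol_step <- function(vol) {
  if (length(vol$z_positions) > 1L) diff(vol$z_positions)[1] else vol$pitch
}

# circular-mean piston removal on a wrapped phase map
.remove_piston_wrapped <- function(ph) {
  .wrap(ph - Arg(mean(exp(1i * ph))))
}

# cache of propagated reference (ringing) phases
.ringing_cache <- new.env(parent = emptyenv())

#' Reference ringing phase of a propagated constant-phase field
#'
#' Propagates a unit-amplitude, constant-phase field with the given
#' amplitude envelope (`support`) over a distance `z` and returns its phase.
#' Subtracting this reference, plane by plane, from a refocused stack
#' cancels the diffraction ringing the refocusing itself introduces
#' (ringing artifact extraction).  Results are cached per
#' (grid, pitch, wavelength, medium, z, support).
#'
#' @param support real amplitude envelope matrix; `NULL` means uniform over
#'   the grid, for which the propagated phase is constant and the returned
#'   (piston-removed) reference is identically zero.
#' @param z propagation distance, um.
#' @param grid_shape `c(ny, nx)`; required when `support` is `NULL`.
#' @param pitch,wavelength,medium_index propagation metadata.
#' @return numeric matrix: piston-removed phase of the propagated reference.
#' @export
ringing_reference <- function(support, z, grid_shape = dim(support),
                              pitch = .holo_defaults$pitch,
                              wavelength = .holo_defaults$wavelength,
                              medium_index = .holo_defaults$medium_index) {
  if (is.null(support) || z == 0)
    return(matrix(0, grid_shape[1], grid_shape[2]))
  key <- paste(paste(grid_shape, collapse = "x"), pitch, wavelength,
               medium_index, z, sum(support), sum(support^2), sep = "|")
  hit <- .ringing_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- sampled_field(matrix(complex(real = support), grid_shape[1], grid_shape[2]),
                     pitch, wavelength, medium_index)
  ref <- .remove_piston_wrapped(Arg(propagate_angular_spectrum(f, z)$amplitude))
  .ringing_cache[[key]] <- ref
  ref
}

#' Build the refocused phase z-stack
#'
#' Propagates the field to `z_min + k * step` for
#' `k = 0 .. floor((z_max - z_min)/step)` and stores the piston-removed
#' phase of each plane.  With `ringing_correct = TRUE` the reference ringing
#' phase of `aperture` at the same distance is subtracted (on the wrapped
#' phase, before any unwrapping); the default uniform aperture has a
#' constant reference phase, for which the subtraction is a no-op beyond
#' piston removal.  Per-slice 2D unwrapping is available but off by
#' default: particle phases of a couple of rad on a ~0.1 rad background
#' rarely wrap.
#'
#' @param field a [sampled_field()] (aberration-corrected).
#' @param z_min,z_max signed refocus range, um (`z_min < z_max`).
#' @param step axial step, um (> 0).
#' @param ringing_correct subtract the propagated-reference phase.
#' @param aperture amplitude envelope of the idealized reference field;
#'   `NULL` = uniform.
#' @param unwrap_slices run 2D unwrapping on every slice.
#' @param provenance stored in the result.
#' @return a [phase_volume()].
#' @export
refocus_stack <- function(field, z_min, z_max, step = .holo_defaults$step,
                          ringing_correct = TRUE, aperture = NULL,
                          unwrap_slices = FALSE, provenance = NULL) {
  stopifnot(inherits(field, "sampled_field"))
  if (!is.numeric(step) || step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (z_min >= z_max) stop("`z_min` must be < `z_max`", call. = FALSE)
  zs <- z_min + step * (0:floor((z_max - z_min) / step + 1e-9))
  d <- dim(field$amplitude)
  Uf <- fft(field$amplitude)
  Af <- if (ringing_correct && !is.null(aperture)) fft(aperture + 0i) else NULL
  # axial wavenumber grid shared by all slices
  f2 <- outer(.fft_freq(d[1], field$pitch)^2, .fft_freq(d[2], field$pitch)^2, `+`)
  arg <- (field$medium_index / field$wavelength)^2 - f2
  prop <- arg > 0
  kz <- sqrt(pmax(arg, 0))
  out <- array(0, c(d[1], d[2], length(zs)))
  for (k in seq_along(zs)) {
    z <- zs[k]
    if (z == 0) {
      ph <- Arg(field$amplitude)
      if (!is.null(Af)) ph <- .wrap(ph - Arg(aperture + 0i))
    } else {
      H <- exp(2i * pi * z * kz) * prop
      ph <- Arg(fft(Uf * H, inverse = TRUE))
      if (!is.null(Af)) ph <- .wrap(ph - Arg(fft(Af * H, inverse = TRUE)))
    }
    ph <- if (unwrap_slices) {
      u <- unwrap_phase(.wrap(ph))
      u - mean(u)
    } else .remove_piston_wrapped(ph)
    out[, , k] <- ph
  }
  phase_volume(out, zs, field$pitch, provenance = provenance)
}
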