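#' Complex optical wavefield on a uniform grid
#'
#' Container for a sampled scalar wavefield: a complex matrix (rows = y,
#' columns = x) plus the physical metadata every spectral operation needs.
#' The physical width of the field is `ncol(amplitude) * pitch` micrometres;
#' pixel centres sit on a grid whose origin coincides with the centred-DFT
#' zero-frequency pixel (`floor(n/2) + 1`).
#'
#' @param amplitude complex (or numeric) matrix, both dimensions >= 2.
#' @param pitch object-space sampling interval, um/pixel.
#' @param wavelength vacuum wavelength, um.
#' @param medium_index refractive index of the propagation medium (>= 1);
#'   in-chamber propagation uses the in-medium wavelength
#'   `wavelength / medium_index`.
#' @return object of class `sampled_field`.
#' @export
sampled_field <- function(amplitude, pitch,
                          wavelength = .holo_defaults$wavelength,
                          medium_index = 1.0) {
  if (!is.matrix(amplitude) || nrow(amplitude) < 2L || ncol(amplitude) < 2L)
    stop("`amplitude` must be a matrix with both dimensions >= 2", call. = FALSE)
  if (!is.numeric(pitch) || length(pitch) != 1L || !is.finite(pitch) || pitch <= 0)
    stop("`pitch` must be a single positive number", call. = FALSE)
  if (!is.numeric(wavelength) || wavelength <= 0)
    stop("`wavelength` must be positive", call. = FALSE)
  if (!is.numeric(medium_index) || medium_index < 1)
    stop("`medium_index` must be >= 1", call. = FALSE)
  storage.mode(amplitude) <- "complex"
  structure(
    list(amplitude = amplitude, pitch = pitch,
         wavelength = wavelength, medium_index = medium_index),
    class = "sampled_field"
  )
}

#' @export
print.sampled_field <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf(
    "<sampled_field> %d x %d px, pitch %.4g um (%.3g x %.3g um), lambda %.4g um, n %.4g\n",
    d[1], d[2], x$pitch, d[2] * x$pitch, d[1] * x$pitch,
    x$wavelength, x$medium_index))
  invisible(x)
}

#' @export
dim.sampled_field <- function(x) dim(x$amplitude)

# Centred pixel coordinates (um): origin at the centred-DFT zero pixel.
.centered_coords <- function(n, pitch) (seq_len(n) - (floor(n / 2) + 1)) * pitch

# Unshifted DFT frequencies, cycles/um.
.fft_freq <- function(n, pitch) {
  k <- 0:(n - 1)
  ((k + floor(n / 2)) %% n - floor(n / 2)) / (n * pitch)
}

.fftshift2 <- function(m) {
  dy <- floor(nrow(m) / 2); dx <- floor(ncol(m) / 2)
  m[c((dy + 1):nrow(m), 1:dy), c((dx + 1):ncol(m), 1:dx)]
}

.ifftshift2 <- function(m) {
  dy <- ceiling(nrow(m) / 2); dx <- ceiling(ncol(m) / 2)
  m[c((dy + 1):nrow(m), 1:dy), c((dx + 1):ncol(m), 1:dx)]
}

#' Angular-spectrum propagation
#'
#' Propagates a sampled wavefield over a signed axial distance `z` by
#' multiplying its spectrum with the exact scalar free-space transfer
#' function `exp(i 2 pi z sqrt((n/lambda)^2 - fx^2 - fy^2))`.  Spatial
#' frequencies beyond the propagating band (evanescent components) are set
#' to zero, so propagation by `z` then `-z` returns the band-limited input
#' and the total power of band-limited fields is conserved.
#'
#' @param field a [sampled_field()].
#' @param z signed propagation distance, um; `z = 0` is the identity.
#' @param bandlimit optional anti-aliasing band-limit factor in (0, 1]: keeps
#'   only frequencies below `bandlimit` times the propagating-band edge.
#'   Default `NULL` (off).
#' @return a [sampled_field()] with identical grid and pitch.
#' @export
propagate_angular_spectrum <- function(field, z, bandlimit = NULL) {
  stopifnot(inherits(field, "sampled_field"))
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("`z` must be a single finite number", call. = FALSE)
  if (z == 0) return(field)
  U <- field$amplitude
  H <- .as_transfer(dim(U), field$pitch, field$wavelength, field$medium_index,
                    z, bandlimit)
  out <- fft(fft(U) * H, inverse = TRUE) / length(U)
  field$amplitude <- out
  field
}

# transfer function on the unshifted DFT grid
.as_transfer <- function(dims, pitch, wavelength, medium_index, z,
                         bandlimit = NULL) {
  fy <- .fft_freq(dims[1], pitch)
  fx <- .fft_freq(dims[2], pitch)
  f2 <- outer(fy^2, fx^2, `+`)
  k0 <- (medium_index / wavelength)^2
  arg <- k0 - f2
  prop <- arg > 0
  if (!is.null(bandlimit)) prop <- prop & (f2 < bandlimit^2 * k0)
  kz <- sqrt(pmax(arg, 0))
  H <- matrix(0 + 0i, dims[1], dims[2])
  H[prop] <- exp(2i * pi * z * kz[prop])
  H
}

#' Super-Gaussian (higher-order elliptical Gaussian) mask
#'
#' Soft-edged window `exp(-(((x - cx)^2 / sx^2 + (y - cy)^2 / sy^2))^order)`,
#' used to excise the real-image order from a hologram spectrum without the
#' ringing a hard aperture would introduce.  Values are in (0, 1], the
#' maximum 1 is attained at the centre, and the mask decreases
#' monotonically along any ray from the centre.  As `order` grows the mask
#' approaches the indicator of the ellipse `(r/sigma) = 1`.
#'
#' @param grid_shape integer vector `c(ny, nx)`.
#' @param center `c(cx, cy)` in pixel coordinates (x = column, y = row).
#' @param widths `c(sx, sy)` in pixels, both > 0.
#' @param order integer >= 1.
#' @return numeric matrix of dimension `grid_shape`.
#' @export
super_gaussian_mask <- function(grid_shape, center, widths, order = 6L) {
  if (length(widths) == 1L) widths <- rep(widths, 2L)
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("`widths` must be positive", call. = FALSE)
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  x <- seq_len(grid_shape[2]) - center[1]
  y <- seq_len(grid_shape[1]) - center[2]
  q <- outer((y / widths[2])^2, (x / widths[1])^2, `+`)
  exp(-q^order)
}
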