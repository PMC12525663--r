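# Off-axis hologram -> aberration-corrected complex object wavefield:
# Fourier-domain demodulation of the real-image order with a super-Gaussian
# window, residual-tilt compensation, phase unwrapping and Zernike
# aberration-mask subtraction.

#' Construct a hologram object from a recorded intensity image
#'
#' @param intensity real non-negative matrix.
#' @param acq an [acquisition_spec()] describing pitch, wavelength and
#'   carrier.
#' @return object of class `hologram`.
#' @export
hologram <- function(intensity, acq) {
  stopifnot(is.matrix(intensity), inherits(acq, "acquisition_spec"))
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("hologram intensity must be finite and non-negative", call. = FALSE)
  structure(list(intensity = intensity, acq = acq), class = "hologram")
}

#' Spectral filter for real-image isolation
#'
#' @param center `"auto"` (locate the carrier as the off-DC spectral
#'   maximum in the +fy half-plane) or an offset `c(kx, ky)` from the DC
#'   pixel, in frequency pixels.
#' @param widths super-Gaussian widths `c(sx, sy)` in frequency pixels, or
#'   `NULL` for the default 45% of the DC-to-carrier distance.
#' @param order super-Gaussian order.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(center = "auto", widths = NULL, order = 6L) {
  if (!identical(center, "auto")) {
    if (all(center == 0)) stop("filter center must be off the DC pixel", call. = FALSE)
  }
  if (!is.null(widths) && any(widths <= 0))
    stop("filter widths must be positive", call. = FALSE)
  structure(list(center = center, widths = widths, order = order),
            class = "filter_spec")
}

#' Isolate the real-image term of an off-axis hologram
#'
#' FFT of the intensity, super-Gaussian window about the +1 order, integer
#' spectral shift of the selected order to DC, inverse FFT.  With the
#' default `"auto"` centre the carrier is located as the spectral magnitude
#' maximum in the +fy half-plane outside a DC exclusion disk of radius 5%
#' of the spectral half-width.
#'
#' @param holo a [hologram()].
#' @param filt a [filter_spec()].
#' @param recenter shift the selected order to DC (default).  With
#'   `recenter = FALSE` the demodulation is left to [compensate_tilt()].
#' @param medium_index medium index stamped on the returned field (used by
#'   subsequent in-chamber propagation).
#' @return a [sampled_field()]; attributes `carrier_px` (offset from DC in
#'   frequency pixels) and `carrier_freq` (cycles/um).
#' @export
isolate_real_image <- function(holo, filt = filter_spec(), recenter = TRUE,
                               medium_index = .holo_defaults$medium_index) {
  stopifnot(inherits(holo, "hologram"), inherits(filt, "filter_spec"))
  I <- holo$intensity
  ny <- nrow(I); nx <- ncol(I)
  ctr <- c(floor(nx / 2) + 1, floor(ny / 2) + 1)  # (x, y) of DC after shift
  S <- .fftshift2(fft(I))
  if (identical(filt$center, "auto")) {
    mag <- Mod(S)
    x <- seq_len(nx) - ctr[1]; y <- seq_len(ny) - ctr[2]
    r2 <- outer(y^2, x^2, `+`)
    excl <- r2 <= (0.05 * min(nx, ny) / 2)^2
    half <- matrix(y > 0, ny, nx)          # +fy half-plane by convention
    cand <- half & !excl
    mm <- mag[cand]
    if (!length(mm) || max(mm) <= 0 || max(mm) < 10 * (median(mm) + .Machine$double.eps))
      stop("carrier-not-found: no off-axis order above spectral background",
           call. = FALSE)
    i <- which(cand & mag == max(mm), arr.ind = TRUE)[1, ]
    center_px <- unname(c(i[2] - ctr[1], i[1] - ctr[2]))
  } else center_px <- filt$center
  dist <- sqrt(sum(center_px^2))
  widths <- if (is.null(filt$widths)) rep(0.45 * dist, 2) else filt$widths
  W <- super_gaussian_mask(c(ny, nx),
                           center = ctr + center_px, widths = widths,
                           order = filt$order)
  Sf <- S * W
  if (recenter) {
    # circular shift so the carrier pixel moves onto DC
    sh <- function(n, k) ((seq_len(n) - 1 + k) %% n) + 1
    Sf <- Sf[sh(ny, center_px[2]), sh(nx, center_px[1])]
  }
  U <- fft(.ifftshift2(Sf), inverse = TRUE) / length(Sf)
  out <- sampled_field(U, holo$acq$pitch, holo$acq$wavelength, medium_index)
  attr(out, "carrier_px") <- center_px
  attr(out, "carrier_freq") <- center_px / (c(nx, ny) * holo$acq$pitch)
  out
}

#' Compensate a residual reference tilt
#'
#' Multiplies the field by a wavefront of opposite tilt,
#' `exp(-i 2 pi (sin(tx) x + sin(ty) y) / lambda)`.  Alternatively the tilt
#' may be given directly as a carrier frequency in cycles/um.
#'
#' @param field a [sampled_field()].
#' @param tilt `c(tx, ty)` in radians.
#' @param carrier `c(fx, fy)` in cycles/um, overriding `tilt`.
#' @return a [sampled_field()]; amplitude is unchanged.
#' @export
compensate_tilt <- function(field, tilt = c(0, 0), carrier = NULL) {
  stopifnot(inherits(field, "sampled_field"))
  f <- if (!is.null(carrier)) carrier else sin(tilt) / field$wavelength
  if (any(!is.finite(f))) stop("tilt must be finite", call. = FALSE)
  if (all(f == 0)) return(field)
  d <- dim(field$amplitude)
  x <- .centered_coords(d[2], field$pitch)
  y <- .centered_coords(d[1], field$pitch)
  ramp <- outer(y * f[2], x * f[1], `+`)
  field$amplitude <- field$amplitude * exp(-2i * pi * ramp)
  field
}

#' Subtract the Zernike aberration mask from a field's phase
#'
#' The phase is unwrapped, decomposed onto the first `n_terms` Noll Zernike
#' polynomials over `disk`, and the fitted aberration surface (piston
#' included) is subtracted, leaving a corrected wavefield whose background
#' phase has mean approximately zero.  The amplitude is untouched.
#'
#' A residual-wrap score (fraction of neighbouring pixel pairs still
#' differing by more than pi) is attached as attribute `wrap_failure`;
#' acquisitions of dense suspensions whose wraps cannot be resolved can be
#' gated on it downstream.
#'
#' @param field a [sampled_field()].
#' @param n_terms number of Zernike terms (default 15, through primary
#'   spherical aberration).
#' @param disk disk mapping; the default circumscribes the grid so the
#'   subtracted mask stays bounded at the corners (see
#'   [circumscribed_disk()]).
#' @return a [sampled_field()] with attributes `zernike` (the
#'   [fit_zernike()] result) and `wrap_failure`.
#' @export
correct_aberrations <- function(field, n_terms = 15L, disk = NULL) {
  stopifnot(inherits(field, "sampled_field"))
  if (is.null(disk)) disk <- circumscribed_disk(dim(field$amplitude))
  ph <- unwrap_phase(Arg(field$amplitude))
  zf <- fit_zernike(ph, n_terms = n_terms, disk = disk)
  corrected <- ph - zf$surface
  field$amplitude <- Mod(field$amplitude) * exp(1i * corrected)
  attr(field, "zernike") <- zf
  attr(field, "wrap_failure") <- .wrap_failure_score(corrected)
  field
}
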