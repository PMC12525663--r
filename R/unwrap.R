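# Two-dimensional phase unwrapping.
#
# The unweighted least-squares (Poisson/DCT) solution is computed first and
# then snapped back onto the lattice congruent with the input, so the output
# is pointwise identical to the input modulo 2*pi while smooth regions carry
# no 2*pi jumps.

.wrap <- function(x) atan2(sin(x), cos(x))

# DCT-II along columns via a length-2N FFT of the mirrored signal.
.dct_cols <- function(m) {
  n <- nrow(m)
  e <- rbind(m, m[n:1, , drop = FALSE])
  E <- stats::mvfft(e)
  ph <- exp(-1i * pi * (0:(n - 1)) / (2 * n))
  Re(E[1:n, , drop = FALSE] * ph) / 2
}

# Inverse of .dct_cols (DCT-III, consistent scaling).
.idct_cols <- function(cm) {
  n <- nrow(cm)
  W <- matrix(0 + 0i, 2 * n, ncol(cm))
  ph <- exp(1i * pi * (0:(n - 1)) / (2 * n))
  W[1:n, ] <- 2 * cm * ph
  if (n > 1) W[(n + 2):(2 * n), ] <- Conj(W[n:2, , drop = FALSE])
  e <- Re(stats::mvfft(W, inverse = TRUE)) / (2 * n)
  e[1:n, , drop = FALSE]
}

.dct2 <- function(m) t(.dct_cols(t(.dct_cols(m))))
.idct2 <- function(m) t(.idct_cols(t(.idct_cols(m))))

#' Unwrap a 2D phase map
#'
#' Recovers a continuous phase surface from values known modulo 2*pi by
#' solving the discrete Poisson equation of the wrapped phase gradients
#' (least-squares unwrapping with Neumann boundaries, via the discrete
#' cosine transform) and restoring congruence with the input.  The output
#' equals the input modulo 2*pi at every pixel; over regions where the true
#' phase is smooth it is free of 2*pi jumps.
#'
#' @param wrapped numeric matrix with values in (-pi, pi].
#' @return numeric matrix, rad.
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(is.matrix(wrapped), nrow(wrapped) >= 2L, ncol(wrapped) >= 2L)
  ny <- nrow(wrapped); nx <- ncol(wrapped)
  dy <- .wrap(wrapped[2:ny, , drop = FALSE] - wrapped[1:(ny - 1), , drop = FALSE])
  dx <- .wrap(wrapped[, 2:nx, drop = FALSE] - wrapped[, 1:(nx - 1), drop = FALSE])
  rho <- matrix(0, ny, nx)
  rho[1:(ny - 1), ] <- rho[1:(ny - 1), ] + dy
  rho[2:ny, ]       <- rho[2:ny, ]       - dy
  rho[, 1:(nx - 1)] <- rho[, 1:(nx - 1)] + dx
  rho[, 2:nx]       <- rho[, 2:nx]       - dx
  denom <- outer(2 * cos(pi * (0:(ny - 1)) / ny) - 2,
                 2 * cos(pi * (0:(nx - 1)) / nx) - 2, `+`)
  denom[1, 1] <- 1
  co <- .dct2(rho) / denom
  co[1, 1] <- 0
  phi_ls <- .idct2(co)
  # congruence restoration: keep the least-squares surface's integer cycles.
  # The residual is centred with its circular mean first so that rounding
  # never sits on a half-cycle boundary (the LS surface is only defined up
  # to an arbitrary constant).
  e <- phi_ls - wrapped
  mu <- Arg(mean(exp(1i * e)))
  wrapped + 2 * pi * round((e - mu) / (2 * pi))
}

# Fraction of nearest-neighbour differences exceeding pi: a residual-wrap
# score used to flag phase maps whose wraps could not be resolved.
.wrap_failure_score <- function(phase) {
  ny <- nrow(phase); nx <- ncol(phase)
  dy <- phase[2:ny, ] - phase[1:(ny - 1), ]
  dx <- phase[, 2:nx] - phase[, 1:(nx - 1)]
  mean(c(abs(dy) > pi, abs(dx) > pi))
}
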