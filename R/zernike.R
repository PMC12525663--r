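# Zernike polynomials in Noll single-index ordering, evaluated on an
# arbitrary pixel grid mapped to the unit disk.  Used to model and subtract
# the smooth aberration background of reconstructed phase maps.

# Noll index j -> (n, m) with sign convention: even j -> cosine (m >= 0),
# odd j -> sine (m <= 0).
.noll_nm <- function(j) {
  stopifnot(j >= 1)
  n <- 0L
  while (j > (n + 1L) * (n + 2L) / 2L) n <- n + 1L
  k <- j - n * (n + 1L) / 2L  # position within the row, 1-based
  mm <- if (n %% 2L == 0L) 2L * (k %/% 2L) else 2L * ((k - 1L) %/% 2L) + 1L
  m <- if (mm == 0L) 0L else if (j %% 2L == 0L) mm else -mm
  c(n = n, m = m)
}

# Radial polynomial R_n^{|m|}(rho)
.zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  out <- 0
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s)) *
      rho^(n - 2 * s)
  }
  out
}

# Single Noll-normalised Zernike term on polar coordinates.
.zernike_term <- function(j, rho, theta) {
  nm <- .noll_nm(j)
  n <- nm[["n"]]; m <- nm[["m"]]
  norm <- if (m == 0L) sqrt(n + 1) else sqrt(2 * (n + 1))
  R <- .zernike_radial(n, m, rho)
  if (m == 0L) norm * R
  else if (m > 0L) norm * R * cos(m * theta)
  else norm * R * sin(-m * theta)
}

# rho/theta of every pixel of a grid for a given disk mapping
.disk_polar <- function(grid_shape, disk) {
  x <- (seq_len(grid_shape[2]) - disk$center[1]) / disk$radius
  y <- (seq_len(grid_shape[1]) - disk$center[2]) / disk$radius
  X <- matrix(x, grid_shape[1], grid_shape[2], byrow = TRUE)
  Y <- matrix(y, grid_shape[1], grid_shape[2])
  list(rho = sqrt(X^2 + Y^2), theta = atan2(Y, X))
}

#' Default unit-disk mapping: largest disk inscribed in the grid
#'
#' @param grid_shape integer vector `c(ny, nx)`.
#' @return list with `center` (`c(cx, cy)`, pixels) and `radius` (pixels).
#' @export
inscribed_disk <- function(grid_shape) {
  list(center = (grid_shape[c(2, 1)] + 1) / 2, radius = min(grid_shape) / 2)
}

#' Disk circumscribing the grid
#'
#' Maps every pixel inside the unit disk (`radius` = half-diagonal).  Used
#' for aberration masks that must stay bounded over the whole grid: Noll
#' polynomials extrapolated beyond the fit disk grow like powers of rho and
#' would otherwise amplify small fitted coefficients at the corners.
#'
#' @param grid_shape integer vector `c(ny, nx)`.
#' @return list with `center` and `radius` (pixels).
#' @export
circumscribed_disk <- function(grid_shape) {
  list(center = (grid_shape[c(2, 1)] + 1) / 2,
       radius = sqrt(sum((grid_shape / 2)^2)))
}

#' Least-squares Zernike decomposition of a phase map
#'
#' Projects a phase map onto the first `n_terms` Noll-ordered Zernike
#' polynomials over a disk, returning the coefficients and the evaluated
#' aberration surface over the whole grid (radial polynomials are
#' extrapolated outside the disk; the fit itself uses only disk pixels).
#' The residual on the disk is orthogonal to the fitted basis, so
#' re-fitting the reconstructed surface reproduces the coefficients.
#'
#' @param phase_map numeric matrix, rad.
#' @param n_terms number of Noll terms (>= 1); the default 15 reaches
#'   primary spherical aberration.
#' @param disk disk mapping as from [inscribed_disk()].
#' @return object of class `zernike_fit`: `coefficients` (named, rad),
#'   `surface` (matrix), `disk`, `residual_rms` (disk pixels, rad).
#' @export
fit_zernike <- function(phase_map, n_terms = 15L, disk = NULL) {
  stopifnot(is.matrix(phase_map), n_terms >= 1L)
  if (is.null(disk)) disk <- inscribed_disk(dim(phase_map))
  if (disk$radius <= 0) stop("disk radius must be positive", call. = FALSE)
  pol <- .disk_polar(dim(phase_map), disk)
  on_disk <- pol$rho <= 1
  if (n_terms > sum(on_disk))
    stop("ill-posed: more Zernike terms than disk pixels", call. = FALSE)
  basis_disk <- vapply(seq_len(n_terms),
                       function(j) .zernike_term(j, pol$rho[on_disk], pol$theta[on_disk]),
                       numeric(sum(on_disk)))
  co <- qr.coef(qr(basis_disk), phase_map[on_disk])
  co[is.na(co)] <- 0
  surface <- matrix(0, nrow(phase_map), ncol(phase_map))
  for (j in seq_len(n_terms))
    surface <- surface + co[j] * .zernike_term(j, pol$rho, pol$theta)
  res <- phase_map[on_disk] - basis_disk %*% co
  structure(
    list(coefficients = setNames(as.numeric(co), paste0("Z", seq_len(n_terms))),
         surface = surface, disk = disk,
         residual_rms = sqrt(mean(res^2))),
    class = "zernike_fit"
  )
}

#' Evaluate a Zernike expansion on a grid
#'
#' @param object a `zernike_fit` (or list with `coefficients` and `disk`).
#' @param grid_shape dimensions of the output grid; defaults to the fitted one.
#' @return numeric matrix, rad.
#' @export
zernike_surface <- function(object, grid_shape = dim(object$surface)) {
  pol <- .disk_polar(grid_shape, object$disk)
  out <- matrix(0, grid_shape[1], grid_shape[2])
  for (j in seq_along(object$coefficients))
    out <- out + object$coefficients[j] * .zernike_term(j, pol$rho, pol$theta)
  out
}

#' @export
print.zernike_fit <- function(x, ...) {
  cat(sprintf("<zernike_fit> %d Noll terms, residual RMS %.3g rad\n",
              length(x$coefficients), x$residual_rms))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.zernike_fit <- function(object, ...) object$coefficients
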