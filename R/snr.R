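# Analytic phase-noise / SNR machinery for particle suspensions: the mean
# phase-noise statistic of a refocused stack, the concentration and
# chamber-height noise model L*(k1*c^2 + k2*c) + phi_N0, the thin-object
# phase signal 2*pi*d*(nS - nM)/lambda, their ratio (SNR), least-squares
# fitting of (k1, k2), and suspension stock arithmetic.

#' Mean phase noise of a refocused stack
#'
#' For every plane z the RMS deviation of the phase about its plane mean is
#' computed, `s_z = sqrt(sum((phi_z - <phi_z>)^2) / N_xy)`; the statistic is
#' the average of `s_z` over planes, in rad.  A variance variant (average
#' of `s_z^2`, rad^2) is available behind `variance = TRUE`.
#'
#' @param vol a [phase_volume()].
#' @param variance return the mean per-plane variance instead of the mean
#'   per-plane RMS.
#' @return scalar, rad (or rad^2).
#' @export
mean_phase_noise <- function(vol, variance = FALSE) {
  stopifnot(inherits(vol, "phase_volume"))
  nz <- dim(vol$phase)[3]
  if (nz < 1L) stop("empty volume", call. = FALSE)
  s <- vapply(seq_len(nz), function(k) {
    p <- vol$phase[, , k]
    mean((p - mean(p))^2)
  }, numeric(1))
  if (variance) mean(s) else mean(sqrt(s))
}

#' Theoretical phase signal of a thin particle
#'
#' `2 pi d (n_S - n_M) / lambda`: the peak phase shift a particle of
#' thickness `d` and index `n_S` imparts in a medium of index `n_M`.
#'
#' @param d particle thickness, um.
#' @param n_s particle refractive index.
#' @param n_m medium refractive index.
#' @param wavelength vacuum wavelength, um.
#' @return phase, rad.
#' @export
phase_signal <- function(d, n_s, n_m = .holo_defaults$medium_index,
                         wavelength = .holo_defaults$wavelength) {
  stopifnot(d > 0, wavelength > 0)
  2 * pi * d * (n_s - n_m) / wavelength
}

#' Noise-model parameters (k1, k2, phi_N0)
#'
#' Parameters of the fitted noise model
#' `<phi_N>(c, L) = L (k1 c^2 + k2 c) + phi_N0` with `c` in particles/um^3
#' and `L` in um.  The defaults are the constants fitted on microsphere
#' dilution series: `k1 = -55` rad um^5/particles^2,
#' `k2 = 0.78` rad um^2/particle, `phi_N0 = 0.1` rad.  At construction the
#' prediction is checked to stay positive over `[0, c_max]` for `L_max`.
#'
#' @param k1,k2,phi_n0 model constants (units above); `phi_n0 >= 0`.
#' @param c_max declared validity bound for the concentration,
#'   particles/um^3.
#' @param L_max chamber height used for the validity check, um.
#' @return object of class `noise_params`.
#' @export
noise_params <- function(k1 = -55, k2 = 0.78, phi_n0 = 0.1,
                         c_max = 2e-4, L_max = 800) {
  if (phi_n0 < 0) stop("`phi_n0` must be >= 0", call. = FALSE)
  cc <- seq(0, c_max, length.out = 201)
  if (any(L_max * (k1 * cc^2 + k2 * cc) + phi_n0 <= 0))
    stop("noise model non-positive inside declared validity range", call. = FALSE)
  structure(list(k1 = k1, k2 = k2, phi_n0 = phi_n0, c_max = c_max),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("<noise_params> k1 = %.4g rad um^5, k2 = %.4g rad um^2, phi_N0 = %.4g rad\n",
              x$k1, x$k2, x$phi_n0))
  invisible(x)
}

# cells/mL -> particles/um^3
.per_ml_to_per_um3 <- function(c_per_ml) c_per_ml / 1e12

#' Predicted mean phase noise
#'
#' @param c concentration, particles/um^3 (vectorised).  Use
#'   `cells_per_ml/1e12` to convert.
#' @param L chamber height, um (> 0).
#' @param params a [noise_params()].
#' @return predicted noise, rad.
#' @export
predict_noise <- function(c, L, params = noise_params()) {
  stopifnot(inherits(params, "noise_params"))
  if (any(c < 0)) stop("`c` must be >= 0", call. = FALSE)
  if (any(L <= 0)) stop("`L` must be > 0", call. = FALSE)
  out <- L * (params$k1 * c^2 + params$k2 * c) + params$phi_n0
  if (any(out <= 0))
    stop("noise model out of validity: non-positive prediction", call. = FALSE)
  out
}

#' Predicted signal-to-noise ratio of suspended particles
#'
#' Ratio of the theoretical phase signal to the predicted phase noise.
#' Attenuation relative to the zero-concentration baseline is reported both
#' in dB (`20 log10(SNR(c)/SNR(0))`) and percent (`100 (1 - SNR(c)/SNR(0))`).
#'
#' @param d,n_s,n_m,wavelength see [phase_signal()].
#' @param c concentration, particles/um^3.
#' @param L chamber height, um.
#' @param params a [noise_params()].
#' @return list with `snr`, `attenuation_db`, `attenuation_pct`,
#'   `phase_signal` and `phase_noise`.
#' @export
predict_snr <- function(d, n_s, n_m = .holo_defaults$medium_index,
                        wavelength = .holo_defaults$wavelength,
                        c, L, params = noise_params()) {
  if (n_s < n_m) warning("n_s < n_m: negative phase signal")
  sig <- phase_signal(d, n_s, n_m, wavelength)
  noi <- predict_noise(c, L, params)
  snr <- sig / noi
  snr0 <- sig / params$phi_n0
  list(snr = snr,
       attenuation_db = 20 * log10(snr / snr0),
       attenuation_pct = 100 * (1 - snr / snr0),
       phase_signal = sig, phase_noise = noi)
}

#' Fit the noise model to measured mean phase noise
#'
#' Least-squares fit of `<phi_N> - phi_n0 = L (k1 c^2 + k2 c)`, linear in
#' `(k1, k2)`.  The base level `phi_n0` is measured independently on an
#' empty chamber and held fixed by default; joint fitting of the intercept
#' is available behind `fit_phi_n0 = TRUE`.
#'
#' @param observations data frame with columns `c` (particles/um^3), `L`
#'   (um) and `noise` (rad).
#' @param phi_n0 fixed base-level phase noise, rad.
#' @param fit_phi_n0 also estimate `phi_n0` as a free intercept.
#' @return object of class `noise_fit` with `print`, `coef`, `predict`,
#'   `summary` and `residuals` methods; `coef` returns
#'   `(k1, k2, phi_n0)`, and the object carries `r_squared` of the fit.
#' @export
fit_noise_params <- function(observations, phi_n0 = 0.1, fit_phi_n0 = FALSE) {
  stopifnot(is.data.frame(observations),
            all(c("c", "L", "noise") %in% names(observations)))
  obs <- observations
  if (length(unique(obs$c[obs$c > 0])) < 2L)
    stop("underdetermined: need at least two distinct non-zero concentrations",
         call. = FALSE)
  obs$x1 <- obs$L * obs$c^2
  obs$x2 <- obs$L * obs$c
  fit <- if (fit_phi_n0) lm(noise ~ x1 + x2, data = obs)
         else            lm(I(noise - phi_n0) ~ 0 + x1 + x2, data = obs)
  if (any(!is.finite(coef(fit))) || fit$rank < length(coef(fit)))
    stop("underdetermined: rank-deficient design", call. = FALSE)
  b <- coef(fit)
  est <- if (fit_phi_n0) c(k1 = unname(b["x1"]), k2 = unname(b["x2"]),
                           phi_n0 = unname(b["(Intercept)"]))
         else            c(k1 = unname(b["x1"]), k2 = unname(b["x2"]),
                           phi_n0 = phi_n0)
  fitted_noise <- est["k1"] * obs$x1 + est["k2"] * obs$x2 + est["phi_n0"]
  ss_res <- sum((obs$noise - fitted_noise)^2)
  ss_tot <- sum((obs$noise - mean(obs$noise))^2)
  structure(
    list(coefficients = est, lm = fit, observations = observations,
         fitted = fitted_noise, residuals = obs$noise - fitted_noise,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         phi_n0_fixed = !fit_phi_n0),
    class = "noise_fit"
  )
}

#' @export
coef.noise_fit <- function(object, ...) object$coefficients

#' @export
residuals.noise_fit <- function(object, ...) object$residuals

#' @export
print.noise_fit <- function(x, ...) {
  cat(sprintf("<noise_fit> k1 = %.4g, k2 = %.4g, phi_N0 = %.4g%s  (R^2 = %.4f, n = %d)\n",
              x$coefficients["k1"], x$coefficients["k2"], x$coefficients["phi_n0"],
              if (x$phi_n0_fixed) " [fixed]" else "",
              x$r_squared, nrow(x$observations)))
  invisible(x)
}

#' @export
summary.noise_fit <- function(object, ...) {
  print(object)
  cat(sprintf("residual RMS %.4g rad over %d observations\n",
              sqrt(mean(object$residuals^2)), length(object$residuals)))
  invisible(object)
}

#' @export
predict.noise_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  b <- object$coefficients
  with(newdata, L * (b[["k1"]] * c^2 + b[["k2"]] * c) + b[["phi_n0"]])
}

#' As-fitted noise parameters of a noise_fit
#' @param fit a [fit_noise_params()] result.
#' @param ... passed to [noise_params()] (e.g. `c_max`).
#' @export
as_noise_params <- function(fit, ...) {
  b <- coef(fit)
  noise_params(k1 = b[["k1"]], k2 = b[["k2"]], phi_n0 = b[["phi_n0"]], ...)
}

#' Stock concentration of a mass-fraction particle suspension
#'
#' Number concentration of an ideal monodisperse sphere suspension:
#' `(grams of solute per mL) / (density * (pi/6) d^3)`.
#'
#' @param diameter sphere diameter, um.
#' @param density particle material density, g/cm^3.
#' @param w_v_pct mass concentration, % w/v (grams per 100 mL).
#' @return particles/mL.
#' @export
stock_concentration <- function(diameter = 0.985, density = 1.85,
                                w_v_pct = 5) {
  if (diameter <= 0 || density <= 0)
    stop("`diameter` and `density` must be > 0", call. = FALSE)
  mass_per_ml <- w_v_pct / 100                      # g/mL
  particle_mass <- density * 1e-12 * pi / 6 * diameter^3  # g (1 um^3 = 1e-12 cm^3)
  mass_per_ml / particle_mass
}
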