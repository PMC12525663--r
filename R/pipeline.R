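# End-to-end orchestration: configuration presets tying the acquisition,
# chamber and particle parameters together, the per-hologram processing
# chain (reconstruct -> correct -> refocus -> segment -> filter -> count),
# replicate statistics, and the in-silico dilution study.

#' Pipeline configuration
#'
#' Bundles the acquisition defaults, chamber preset, particle preset and
#' the segmentation/gating parameters of the counting chain.  Chamber
#' presets follow the measurement procedure: the hologram is captured at
#' the chamber mid-plane and refocused over the chamber height plus a
#' 25 um margin on both sides (200 um chamber -> z in [-125, 125] um) at a
#' 0.5 um step.
#'
#' @param chamber_height chamber height L, um (200 or 400 are the standard
#'   presets; any positive value is accepted).
#' @param particle a preset name for [particle_preset()] or a
#'   [particle_spec()].
#' @param grid,pitch,wavelength acquisition geometry; the default 256 px at
#'   0.117 um/pixel is a ~30 um sub-field of the instrument's 120 x 120 um
#'   area (use `grid = 1024` for the full field).
#' @param carrier_frac off-axis carrier as a fraction of the sampling
#'   frequency `1/pitch`.
#' @param medium_index suspension medium index.
#' @param step axial refocus step, um.
#' @param refocus_margin extra refocus range beyond the chamber, um.
#' @param tau segmentation threshold, rad; `NULL` = half the particle's
#'   predicted phase signal.
#' @param element_size structuring element size, um; `NULL` = particle
#'   diameter.
#' @param f_low,f_high statistical volume gates, see [filter_components()].
#' @param n_terms Zernike terms for aberration correction.
#' @param filter_order super-Gaussian order of the demodulation window.
#' @param max_wrap_failure frames whose residual-wrap score exceeds this
#'   are excluded from statistics.
#' @param min_snr frames whose estimated SNR (particle phase signal over
#'   the measured mean phase noise of the stack) falls below this are
#'   excluded from statistics; the default 5 is the Rose criterion for
#'   reliable detection.  Set to 0 to disable.
#' @param min_peak_frac components whose peak phase stays below this
#'   fraction of the predicted particle phase signal are discarded as
#'   background.
#' @param edge_guard lateral guard band, um; components with centroids
#'   inside it are discarded and the measurement volume is reduced to the
#'   guarded field.
#' @param base_noise_rms,noise_corr_length base-level phase screen of
#'   simulated scenes, rad / um.
#' @param ringing_correct subtract the propagated-reference ringing phase.
#' @param seed base seed for simulations.
#' @return object of class `holo_config`.
#' @export
holo_config <- function(chamber_height = 200, particle = "microsphere",
                        grid = 256L, pitch = .holo_defaults$pitch,
                        wavelength = .holo_defaults$wavelength,
                        carrier_frac = 0.3,
                        medium_index = .holo_defaults$medium_index,
                        step = .holo_defaults$step, refocus_margin = 25,
                        tau = NULL, element_size = NULL,
                        f_low = 0.3, f_high = 3.0, n_terms = 15L,
                        filter_order = 6L, max_wrap_failure = 0.01,
                        min_snr = 5, min_peak_frac = 0.75, edge_guard = 1.5,
                        base_noise_rms = 0.1, noise_corr_length = 1,
                        ringing_correct = TRUE, seed = 1L) {
  if (is.character(particle)) particle <- particle_preset(particle)
  stopifnot(inherits(particle, "particle_spec"), chamber_height > 0)
  cfg <- list(chamber_height = chamber_height, particle = unclass(particle),
              grid = as.integer(grid), pitch = pitch, wavelength = wavelength,
              carrier_frac = carrier_frac, medium_index = medium_index,
              step = step, refocus_margin = refocus_margin,
              tau = tau, element_size = element_size,
              f_low = f_low, f_high = f_high, n_terms = as.integer(n_terms),
              filter_order = as.integer(filter_order),
              max_wrap_failure = max_wrap_failure, min_snr = min_snr,
              min_peak_frac = min_peak_frac, edge_guard = edge_guard,
              base_noise_rms = base_noise_rms,
              noise_corr_length = noise_corr_length,
              ringing_correct = ringing_correct, seed = as.integer(seed))
  # internal consistency: carrier below Nyquist, refocus range covers chamber
  if (carrier_frac >= 0.5) stop("carrier at or above Nyquist", call. = FALSE)
  structure(cfg, class = "holo_config")
}

#' @export
print.holo_config <- function(x, ...) {
  cat(sprintf(
    "<holo_config> L = %g um (refocus +/-%g um @ %g um), %s, grid %d @ %.4g um/px\n",
    x$chamber_height, x$chamber_height / 2 + x$refocus_margin, x$step,
    x$particle$shape, x$grid, x$pitch))
  invisible(x)
}

#' Save / load a pipeline configuration as YAML
#' @param config a [holo_config()].
#' @param path YAML file path.
#' @return `load_config` returns a `holo_config`; round-trips exactly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "holo_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  p <- raw$particle
  raw$particle <- particle_spec(p$shape, p$diameter, p$length, p$n,
                                orientation = unlist(p$orientation))
  do.call(holo_config, raw)
}

# derived quantities of a config
.cfg_acq <- function(config) {
  acquisition_spec(grid = config$grid, pitch = config$pitch,
                   wavelength = config$wavelength,
                   carrier = config$carrier_frac / config$pitch)
}

.cfg_tau <- function(config) {
  if (!is.null(config$tau)) return(config$tau)
  p <- config$particle
  0.5 * phase_signal(p$diameter, p$n, config$medium_index, config$wavelength)
}

.cfg_element <- function(config) {
  # default element: half the particle diameter.  At the default threshold
  # (half the peak phase) a spherical profile stays above threshold over
  # ~0.87 d; the opening element must fit inside that core at any sub-pixel
  # alignment, so it is sized comfortably below it.
  list(shape = if (config$particle$shape == "rod") "cube" else "sphere",
       size = if (!is.null(config$element_size)) config$element_size
              else config$particle$diameter / 2)
}

# full single-hologram chain; returns all intermediates
.process_hologram <- function(holo, config) {
  field <- isolate_real_image(holo, filter_spec(order = config$filter_order),
                              medium_index = config$medium_index)
  field <- correct_aberrations(field, n_terms = config$n_terms)
  wrap_failure <- attr(field, "wrap_failure")
  half <- config$chamber_height / 2 + config$refocus_margin
  vol <- refocus_stack(field, -half, half, config$step,
                       ringing_correct = config$ringing_correct)
  el <- .cfg_element(config)
  comps <- segment_volume(vol, .cfg_tau(config), el$shape, el$size)
  # physical culls: no particle sits outside the chamber, and the lateral
  # guard band is corrupted by the periodic spectral processing; the
  # measurement volume shrinks to match
  fov_full <- config$grid * config$pitch
  g <- config$edge_guard
  lat <- c(-fov_full / 2 + g, fov_full / 2 - g)
  zl <- config$chamber_height / 2 + config$step
  comps <- clip_components(comps, lat, lat, c(-zl, zl))
  p <- config$particle
  sig <- phase_signal(p$diameter, p$n, config$medium_index, config$wavelength)
  comps <- filter_components(comps, config$f_low, config$f_high,
                             min_peak = config$min_peak_frac * sig)
  fov <- rep(fov_full - 2 * g, 2)
  result <- count_and_concentration(comps, fov = fov,
                                    z_extent = config$chamber_height)
  noise <- mean_phase_noise(vol)
  snr_est <- sig / noise
  list(field = field, volume = vol, components = comps, result = result,
       wrap_failure = wrap_failure, noise = noise, snr_est = snr_est)
}

# frame-level quality gate: residual wraps or sub-Rose SNR
.frame_excluded <- function(run, config) {
  run$wrap_failure > config$max_wrap_failure ||
    (config$min_snr > 0 && run$snr_est < config$min_snr)
}

# population CV in percent (SD about the mean over n, per the replicate
# statistics convention used for count tables)
.cv_pct <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * sqrt(mean((x - m)^2)) / m
}

#' Run the counting pipeline on one or more holograms
#'
#' Per hologram: demodulate the real image, compensate aberrations, refocus
#' through the chamber, segment, gate, count and convert to concentration.
#' Frames whose residual-wrap score exceeds `config$max_wrap_failure` are
#' excluded from the replicate statistics and listed in the report.
#'
#' @param holos a [hologram()], a list of them, or a character vector of
#'   TIFF paths written by [write_hologram()].
#' @param config a [holo_config()].
#' @param keep_intermediates keep the field, stack and components of every
#'   frame in the report (memory-hungry).
#' @return object of class `count_report`: per-frame table (`count`,
#'   `concentration_per_ml`, `wrap_failure`, `excluded`), replicate summary
#'   (mean, SD, CV%), and the per-frame [count_and_concentration()] results.
#' @export
run_count_pipeline <- function(holos, config = holo_config(),
                               keep_intermediates = FALSE) {
  if (inherits(holos, "hologram")) holos <- list(holos)
  if (is.character(holos)) {
    missing <- holos[!file.exists(holos)]
    if (length(missing)) stop("file not found: ", missing[1], call. = FALSE)
    holos <- lapply(holos, read_hologram)
  }
  runs <- lapply(holos, .process_hologram, config = config)
  frames <- data.frame(
    frame = seq_along(runs),
    count = vapply(runs, function(r) r$result$adjusted_count, numeric(1)),
    concentration_per_ml = vapply(runs, function(r) r$result$concentration_per_ml, numeric(1)),
    mean_phase_noise = vapply(runs, `[[`, numeric(1), "noise"),
    snr_est = vapply(runs, `[[`, numeric(1), "snr_est"),
    wrap_failure = vapply(runs, `[[`, numeric(1), "wrap_failure"))
  frames$excluded <- vapply(runs, .frame_excluded, logical(1), config = config)
  ok <- frames[!frames$excluded, , drop = FALSE]
  summary <- data.frame(
    n_frames = nrow(ok),
    mean_count = if (nrow(ok)) mean(ok$count) else NA_real_,
    sd_count = if (nrow(ok) > 1) sd(ok$count) else 0,
    cv_pct = if (nrow(ok)) .cv_pct(ok$count) else NA_real_,
    mean_concentration_per_ml = if (nrow(ok)) mean(ok$concentration_per_ml) else NA_real_)
  structure(
    list(frames = frames, summary = summary,
         results = lapply(runs, `[[`, "result"),
         intermediates = if (keep_intermediates) runs else NULL,
         config = config),
    class = "count_report"
  )
}

#' @export
print.count_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<count_report> %d frame(s) (%d excluded): mean count %.3g, CV %.3g%%, %.4g /mL\n",
    nrow(x$frames), sum(x$frames$excluded), s$mean_count, s$cv_pct,
    s$mean_concentration_per_ml))
  invisible(x)
}

#' Simulated dilution study
#'
#' Reproduces the dilution-series experiment in silico: for every dilution
#' factor and replicate a scene is drawn at `stock / dilution` particles/mL,
#' a hologram is simulated and run through the counting pipeline.  The
#' study tabulates measured vs. true concentration, the per-dilution
#' replicate CV, the mean phase noise of every acquisition, and fits the
#' concentration/chamber-height noise model to the noise table.
#'
#' @param config a [holo_config()].
#' @param dilution_factors numeric vector (>= 2 values for a noise fit).
#' @param n_replicates seeded replicates per dilution; a scalar or one
#'   value per dilution (sparse dilutions benefit from more replicates to
#'   stabilise the pooled Poisson statistics).
#' @param stock_per_ml undiluted stock concentration, particles/mL.
#' @param seed base seed; each (dilution, replicate) derives its own.
#' @return object of class `dilution_study` with elements `counts`
#'   (per-acquisition table), `by_dilution` (pooled concentration, CV),
#'   `noise` (per-acquisition noise table), `fit` (a [fit_noise_params()]
#'   result, or `NULL` with `fit_note` when underdetermined), and the
#'   log-log regression `slope`/`r_squared` of measured on true
#'   concentration.
#' @export
run_dilution_study <- function(config = holo_config(),
                               dilution_factors = c(100, 800, 2400, 8000),
                               n_replicates = 3L,
                               stock_per_ml = stock_concentration(),
                               seed = config$seed) {
  stopifnot(length(dilution_factors) >= 1L, all(n_replicates >= 1L))
  n_replicates <- rep_len(n_replicates, length(dilution_factors))
  acq <- .cfg_acq(config)
  fov <- config$grid * config$pitch
  template <- do.call(particle_spec, config$particle[c("shape", "diameter",
                                                       "length", "n")])
  rows <- list()
  for (di in seq_along(dilution_factors)) {
    D <- dilution_factors[di]
    c_ml <- stock_per_ml / D
    for (r in seq_len(n_replicates[di])) {
      sc <- generate_scene(.per_ml_to_per_um3(c_ml), fov, fov,
                           config$chamber_height, template,
                           config$medium_index, config$base_noise_rms,
                           config$noise_corr_length,
                           seed = seed + 7873L * di + r)
      holo <- simulate_hologram(sc, acq)
      run <- .process_hologram(holo, config)
      rows[[length(rows) + 1L]] <- data.frame(
        dilution = D, replicate = r,
        true_per_ml = c_ml, true_count = nrow(sc$particles),
        count = run$result$adjusted_count,
        measured_per_ml = run$result$concentration_per_ml,
        volume_nl = run$result$measurement_volume_nl,
        mean_phase_noise = run$noise, snr_est = run$snr_est,
        wrap_failure = run$wrap_failure,
        excluded = .frame_excluded(run, config))
    }
  }
  counts <- do.call(rbind, rows)
  ok <- counts[!counts$excluded, , drop = FALSE]
  by_dil <- do.call(rbind, lapply(split(ok, ok$dilution), function(g) {
    data.frame(dilution = g$dilution[1], true_per_ml = g$true_per_ml[1],
               n = nrow(g),
               pooled_per_ml = sum(g$count) / (sum(g$volume_nl) * 1e-6),
               mean_per_ml = mean(g$measured_per_ml),
               cv_pct = .cv_pct(g$count))
  }))
  by_dil <- by_dil[order(by_dil$dilution), , drop = FALSE]
  slope <- r2 <- NA_real_
  pos <- by_dil[by_dil$pooled_per_ml > 0, , drop = FALSE]
  if (nrow(pos) >= 2L) {
    reg <- lm(log10(pooled_per_ml) ~ log10(true_per_ml), data = pos)
    slope <- unname(coef(reg)[2])
    r2 <- summary(reg)$r.squared
  }
  fit <- NULL; fit_note <- NULL
  # the noise statistic is measurable on any frame with resolvable wraps,
  # including frames too dense for reliable counting
  nok <- counts[counts$wrap_failure <= config$max_wrap_failure, , drop = FALSE]
  noise <- data.frame(c = .per_ml_to_per_um3(nok$true_per_ml),
                      L = config$chamber_height, noise = nok$mean_phase_noise)
  fit <- tryCatch(fit_noise_params(noise, phi_n0 = config$base_noise_rms),
                  error = function(e) { fit_note <<- conditionMessage(e); NULL })
  structure(
    list(counts = counts, by_dilution = by_dil, noise = noise,
         fit = fit, fit_note = fit_note, slope = slope, r_squared = r2,
         config = config, stock_per_ml = stock_per_ml),
    class = "dilution_study"
  )
}

#' @export
print.dilution_study <- function(x, ...) {
  cat(sprintf("<dilution_study> %d dilutions x %d acquisitions; log-log slope %.3f (R^2 %.3f)\n",
              nrow(x$by_dilution), nrow(x$counts), x$slope, x$r_squared))
  print(x$by_dilution, row.names = FALSE)
  if (!is.null(x$fit)) print(x$fit) else if (!is.null(x$fit_note))
    cat("noise fit: ", x$fit_note, "\n")
  invisible(x)
}
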