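# Segmentation and enumeration of the refocused phase volume: threshold,
# 3D morphological opening with a shape-matched structuring element,
# 26-connected component labelling, median-anchored volume gating, and
# cluster splitting by the mean single-cell volume.

# offsets (dy, dx, dz) of a structuring element built in physical units:
# lateral radii in pitch units, axial radius in step units
.element_offsets <- function(shape, size, pitch, step) {
  # largest element not exceeding the physical size: the element must fit
  # inside the smallest structure that should survive the opening
  rl <- max(1L, floor(size / 2 / pitch))
  rz <- max(1L, floor(size / 2 / step))
  dy <- -rl:rl; dx <- -rl:rl; dz <- -rz:rz
  g <- expand.grid(dy = dy, dx = dx, dz = dz)
  if (shape == "sphere") {
    keep <- (g$dy / rl)^2 + (g$dx / rl)^2 + (g$dz / rz)^2 <= 1 + 1e-9
    g <- g[keep, , drop = FALSE]
  }
  as.matrix(g)
}

#' Segment a phase volume into particle candidates
#'
#' Thresholds the phase at `tau`, opens the binary volume with a volumetric
#' structuring element of shape and size matched to the target particle
#' (spherical for spheres, cube-shaped for rods; physical size converted to
#' voxels using the lateral pitch and the axial step), and labels
#' 26-connected components.
#'
#' @param vol a [phase_volume()].
#' @param tau phase threshold, rad (> 0).  A sensible default is half the
#'   predicted particle phase signal, see [phase_signal()].
#' @param element `"sphere"` or `"cube"`.
#' @param element_size physical element diameter/edge, um (default 1, the
#'   particle scale of interest).
#' @return object of class `holo_components`: a data frame with one row per
#'   component (`voxels`, `volume_um3`, centred physical centroid `x`, `y`,
#'   `z` in um, `peak_phase` in rad), with `pitch` and `step` attributes.
#' @export
segment_volume <- function(vol, tau, element = c("sphere", "cube"),
                           element_size = 1.0) {
  stopifnot(inherits(vol, "phase_volume"))
  element <- match.arg(element)
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  d <- dim(vol$phase)
  step <- .vol_step(vol)
  rl <- max(1, floor(element_size / 2 / vol$pitch))
  rz <- max(1, floor(element_size / 2 / step))
  if (2 * rl + 1 > min(d[1:2]) || 2 * rz + 1 > d[3])
    stop("structuring element larger than the volume", call. = FALSE)
  off <- .element_offsets(element, element_size, vol$pitch, step)
  bin <- vol$phase >= tau
  storage.mode(bin) <- "logical"
  dims <- as.integer(d)
  opened <- .dilate3d(.erode3d(as.logical(bin), dims, off), dims, off)
  lab <- .label3d(opened, dims)
  n <- attr(lab, "n")
  comps <- data.frame(label = integer(0), voxels = integer(0),
                      volume_um3 = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), peak_phase = numeric(0))
  if (n > 0L) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    co <- arrayInd(idx, d)
    vox <- tabulate(l, nbins = n)
    ys <- .centered_coords(d[1], vol$pitch)
    xs <- .centered_coords(d[2], vol$pitch)
    sums <- rowsum(cbind(ys[co[, 1]], xs[co[, 2]], vol$z_positions[co[, 3]]),
                   l, reorder = TRUE)
    pk <- vapply(split(vol$phase[idx], l), max, numeric(1))
    comps <- data.frame(
      label = seq_len(n), voxels = vox,
      volume_um3 = vox * vol$pitch^2 * step,
      x = sums[, 2] / vox, y = sums[, 1] / vox, z = sums[, 3] / vox,
      peak_phase = as.numeric(pk))
  }
  structure(comps, class = c("holo_components", "data.frame"),
            pitch = vol$pitch, step = step)
}

#' Restrict components to a physical region
#'
#' Drops components whose centroid lies outside the given lateral/axial
#' box.  Used by the pipeline to cull (a) components outside the chamber
#' (no particle can sit beyond the chamber walls; the refocus margin exists
#' only to capture focus curves) and (b) components inside a lateral guard
#' band, where the periodic spectral processing corrupts the reconstruction.
#' The measurement volume must be reduced accordingly by the caller.
#'
#' @param comps a [holo_components] data frame.
#' @param xlim,ylim,zlim centred physical limits, um (`NULL` = no cut).
#' @return filtered `holo_components`.
#' @export
clip_components <- function(comps, xlim = NULL, ylim = NULL, zlim = NULL) {
  keep <- rep(TRUE, nrow(comps))
  if (!is.null(xlim)) keep <- keep & comps$x >= xlim[1] & comps$x <= xlim[2]
  if (!is.null(ylim)) keep <- keep & comps$y >= ylim[1] & comps$y <= ylim[2]
  if (!is.null(zlim)) keep <- keep & comps$z >= zlim[1] & comps$z <= zlim[2]
  out <- comps[keep, , drop = FALSE]
  attr(out, "pitch") <- attr(comps, "pitch")
  attr(out, "step") <- attr(comps, "step")
  class(out) <- class(comps)
  out
}

#' Statistical volume filter and cluster flagging
#'
#' Components far below the median component volume are discarded as debris
#' (`volume < f_low * median`); components far above it
#' (`volume > f_high * median`) are retained but flagged as clusters of
#' multiple particles.  The mean volume of the remaining single-particle
#' components is attached as `V_avg` for cluster splitting.
#'
#' @param comps a [segment_volume()] result.
#' @param f_low relative lower volume gate (default 0.3).
#' @param f_high relative upper (cluster) gate.  The default 3.0 reflects
#'   that single-particle component volumes at a fixed threshold vary
#'   severalfold with the local coherent background, so only components
#'   clearly larger than the median are treated as clusters.
#' @param min_peak minimum component peak phase, rad (default 0 = off).
#'   The pipeline anchors this at a fraction of the predicted particle
#'   phase signal: a region whose peak never approaches the signal a real
#'   particle must produce is background, whatever its volume.
#' @return `holo_components` with a logical `cluster` column and attribute
#'   `V_avg` (um^3; `NA` when no components survive).
#' @export
filter_components <- function(comps, f_low = 0.3, f_high = 3.0, min_peak = 0) {
  stopifnot(inherits(comps, "holo_components"))
  if (min_peak > 0 && nrow(comps))
    comps <- comps[comps$peak_phase >= min_peak, , drop = FALSE]
  if (nrow(comps) == 0L) {
    comps$cluster <- logical(0)
    attr(comps, "V_avg") <- NA_real_
    class(comps) <- c("holo_components", "data.frame")
    return(comps)
  }
  v_med <- median(comps$volume_um3)
  keep <- comps$volume_um3 >= f_low * v_med
  out <- comps[keep, , drop = FALSE]
  out$cluster <- out$volume_um3 > f_high * v_med
  attr(out, "V_avg") <- if (any(!out$cluster)) mean(out$volume_um3[!out$cluster]) else NA_real_
  attr(out, "pitch") <- attr(comps, "pitch")
  attr(out, "step") <- attr(comps, "step")
  class(out) <- c("holo_components", "data.frame")
  out
}

#' Counts and concentration from labelled components
#'
#' Each component contributes `round(volume / V_avg)` particles (at least
#' one), so clusters are split by the mean single-cell volume.  The
#' measurement volume is `width * height * z_extent`.
#'
#' @param comps filtered [holo_components].
#' @param V_avg mean single-particle volume, um^3 (> 0); default the
#'   `V_avg` attribute of `comps`.
#' @param fov lateral field of view `c(width, height)`, um.
#' @param z_extent axial extent of the measurement volume, um (typically
#'   the chamber height).
#' @return object of class `count_result`: raw and cluster-adjusted counts,
#'   measurement volume in nL, concentration in particles/mL.
#' @export
count_and_concentration <- function(comps, V_avg = attr(comps, "V_avg"),
                                    fov, z_extent) {
  if (is.null(V_avg) || !is.finite(V_avg) || V_avg <= 0) {
    if (nrow(comps) == 0L) V_avg <- NA_real_
    else stop("`V_avg` must be positive", call. = FALSE)
  }
  per <- if (nrow(comps)) pmax(1L, as.integer(round(comps$volume_um3 / V_avg))) else integer(0)
  vol_um3 <- fov[1] * fov[2] * z_extent
  vol_nl <- vol_um3 / 1e6          # 1 nL = 1e6 um^3
  vol_ml <- vol_um3 / 1e12         # 1 mL = 1e12 um^3
  structure(
    list(raw_count = nrow(comps), adjusted_count = sum(per),
         per_component = per, V_avg = V_avg,
         measurement_volume_nl = vol_nl,
         concentration_per_ml = sum(per) / vol_ml),
    class = "count_result"
  )
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf(
    "<count_result> %d components -> %d particles in %.3g nL  (%.4g /mL)\n",
    x$raw_count, x$adjusted_count, x$measurement_volume_nl,
    x$concentration_per_ml))
  invisible(x)
}
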