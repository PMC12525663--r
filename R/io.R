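# File formats: holograms as 16-bit grayscale TIFF with a YAML metadata
# sidecar, complex fields as 2-plane 32-bit float TIFF, phase stacks as
# multi-page 32-bit float TIFF (z grid in the sidecar), component tables as
# CSV and count reports as JSON.

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

# tiff::writeTIFF stores values in [0,1]; keep an affine scale in the sidecar
.norm01 <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) list(data = m * 0, offset = rng[1], scale = 1)
  else list(data = (m - rng[1]) / diff(rng), offset = rng[1], scale = diff(rng))
}

#' Write a hologram as 16-bit TIFF plus YAML sidecar
#'
#' @param holo a [hologram()]; simulated holograms also write their
#'   ground-truth particle table as `<path>_truth.csv`.
#' @param path output TIFF path; metadata goes to `<path>.yaml`.
#' @return invisibly, the sidecar path.
#' @export
write_hologram <- function(holo, path) {
  stopifnot(inherits(holo, "hologram"))
  nz <- .norm01(holo$intensity)
  tiff::writeTIFF(nz$data, path, bits.per.sample = 16L)
  acq <- holo$acq
  meta <- list(pitch = acq$pitch, wavelength = acq$wavelength,
               carrier = as.numeric(acq$carrier), grid = acq$grid,
               ref_ratio = acq$ref_ratio,
               intensity_offset = nz$offset, intensity_scale = nz$scale)
  yaml::write_yaml(meta, .sidecar_path(path))
  truth <- attr(holo, "truth")
  if (!is.null(truth) && nrow(truth$particles))
    write.csv(truth$particles,
              paste0(tools::file_path_sans_ext(path), "_truth.csv"),
              row.names = FALSE)
  invisible(.sidecar_path(path))
}

#' Read a hologram written by [write_hologram()]
#'
#' @param path TIFF path; the YAML sidecar `<path>.yaml` must exist.
#' @return a [hologram()].
#' @export
read_hologram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta_path <- .sidecar_path(path)
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path, call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  img <- tiff::readTIFF(path)
  I <- img * meta$intensity_scale + meta$intensity_offset
  acq <- acquisition_spec(grid = meta$grid, pitch = meta$pitch,
                          wavelength = meta$wavelength,
                          carrier = meta$carrier, ref_ratio = meta$ref_ratio,
                          snap_carrier = FALSE)
  hologram(pmax(I, 0), acq)
}

#' Write a complex field as a 2-plane 32-bit float TIFF
#' @param field a [sampled_field()].
#' @param path output path; metadata sidecar `<path>.yaml`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "sampled_field"))
  re <- .norm01(Re(field$amplitude)); im <- .norm01(Im(field$amplitude))
  tiff::writeTIFF(list(re$data, im$data), path, bits.per.sample = 32L)
  yaml::write_yaml(list(pitch = field$pitch, wavelength = field$wavelength,
                        medium_index = field$medium_index,
                        re_offset = re$offset, re_scale = re$scale,
                        im_offset = im$offset, im_scale = im$scale),
                   .sidecar_path(path))
  invisible(path)
}

#' Read a field written by [write_field()]
#' @param path TIFF path.
#' @return a [sampled_field()].
#' @export
read_field <- function(path) {
  meta <- yaml::read_yaml(.sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  amp <- complex(real = pages[[1]] * meta$re_scale + meta$re_offset,
                 imaginary = pages[[2]] * meta$im_scale + meta$im_offset)
  sampled_field(matrix(amp, nrow(pages[[1]])), meta$pitch, meta$wavelength,
                meta$medium_index)
}

#' Write a phase volume as multi-page 32-bit float TIFF
#' @param vol a [phase_volume()].
#' @param path output path; the z grid goes to the YAML sidecar.
#' @export
write_phase_volume <- function(vol, path) {
  stopifnot(inherits(vol, "phase_volume"))
  rng <- range(vol$phase)
  sc <- if (diff(rng) == 0) 1 else diff(rng)
  pages <- lapply(seq_len(dim(vol$phase)[3]),
                  function(k) (vol$phase[, , k] - rng[1]) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(z_positions = as.numeric(vol$z_positions),
                        pitch = vol$pitch, offset = rng[1], scale = sc),
                   .sidecar_path(path))
  invisible(path)
}

#' Read a phase volume written by [write_phase_volume()]
#' @param path TIFF path.
#' @return a [phase_volume()].
#' @export
read_phase_volume <- function(path) {
  meta <- yaml::read_yaml(.sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * meta$scale + meta$offset
  phase_volume(arr, meta$z_positions, meta$pitch)
}

#' Write a component table as CSV
#' @param comps a [holo_components] data frame.
#' @param path output CSV path.
#' @export
write_components_csv <- function(comps, path) {
  write.csv(as.data.frame(comps), path, row.names = FALSE)
  invisible(path)
}

#' Write a count result as JSON
#' @param result a [count_and_concentration()] result (or any list).
#' @param path output JSON path.
#' @export
write_count_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
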