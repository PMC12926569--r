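# On-disk format for multispectral stacks: one multi-page TIFF per frame
# (one 32-bit grayscale page per wavelength, ordered as in the metadata
# wavelength list) plus a JSON metadata sidecar. TIFF storage is 32-bit with
# values scaled into [0, 1] by a power-of-two `intensity_scale` recorded in
# the metadata; round-trip quantization error is below 1e-9 of full scale.

#' Write a multispectral stack to disk
#'
#' @param stack An [ms_stack()].
#' @param dir Output directory (created if needed). Writes
#'   `frame_0001.tif`, ... and `metadata.json`.
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "spa_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$frames)
  mx <- max(stack$frames)
  scale <- if (mx > 0) 2^ceiling(log2(mx)) else 1
  for (f in seq_len(d[1])) {
    pages <- purrr::map(seq_len(d[2]), function(w) {
      matrix(stack$frames[f, w, , ] / scale, d[3], d[4])
    })
    tiff::writeTIFF(pages, file.path(dir, sprintf("frame_%04d.tif", f)),
                    bits.per.sample = 32L)
  }
  meta <- list(
    wavelengths_nm = stack$wavelengths_nm,
    n_frames = d[1],
    height = d[3],
    width = d[4],
    fluence_normalized = stack$fluence_normalized,
    intensity_scale = scale,
    pixel_size_mm = stack$pixel_size_mm,
    beam_area_cm2 = stack$config$beam_area_cm2,
    frame_step_mm = stack$config$frame_step_mm,
    gruneisen = stack$config$gruneisen,
    coordinate_convention = "row-major; pixel (1,1) top-left; depth increases with row"
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a multispectral stack from disk
#'
#' @param dir Directory produced by [write_stack()].
#' @return An [ms_stack()].
#' @export
read_stack <- function(dir) {
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(meta_path)) {
    spa_abort(sprintf("No metadata.json in %s.", dir), "spa_format_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.tif$", full.names = TRUE))
  if (length(files) != meta$n_frames) {
    spa_abort(
      sprintf("Metadata declares %d frames but found %d TIFF files.",
              meta$n_frames, length(files)),
      "spa_format_error")
  }
  W <- length(meta$wavelengths_nm)
  frames <- array(0, dim = c(meta$n_frames, W, meta$height, meta$width))
  for (f in seq_along(files)) {
    pages <- tiff::readTIFF(files[f], all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != W) {
      spa_abort(
        sprintf("Frame file %s has %d pages but metadata declares %d wavelengths.",
                basename(files[f]), length(pages), W),
        "spa_format_error")
    }
    for (w in seq_len(W)) {
      frames[f, w, , ] <- pages[[w]] * meta$intensity_scale
    }
  }
  cfg <- acquisition_config(
    beam_area_cm2 = meta$beam_area_cm2,
    wavelengths_nm = meta$wavelengths_nm,
    frame_step_mm = meta$frame_step_mm,
    gruneisen = meta$gruneisen)
  ms_stack(frames, wavelengths_nm = meta$wavelengths_nm, config = cfg,
           fluence_normalized = meta$fluence_normalized,
           pixel_size_mm = meta$pixel_size_mm)
}

#' Read or write a per-pulse laser energy log
#'
#' CSV with header `pulse_index,wavelength_nm,energy_mJ`, one row per
#' recorded laser pulse.
#'
#' @param path CSV file path.
#' @return `read_energy_log()` returns a tibble of pulse records.
#' @export
read_energy_log <- function(path) {
  log <- readr::read_csv(path, col_types = readr::cols(
    pulse_index = readr::col_integer(),
    wavelength_nm = readr::col_double(),
    energy_mJ = readr::col_double()))
  if (any(!is.finite(log$energy_mJ)) || any(log$energy_mJ < 0)) {
    spa_abort("Energy log contains non-finite or negative energies.",
              "spa_validation_error")
  }
  log
}

#' @rdname read_energy_log
#' @param pulses A tibble of pulse records (`pulse_index`, `wavelength_nm`,
#'   `energy_mJ`).
#' @export
write_energy_log <- function(pulses, path) {
  readr::write_csv(pulses[, c("pulse_index", "wavelength_nm", "energy_mJ")], path)
  invisible(path)
}
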