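# Multispectral photoacoustic stacks, pulse-energy logs and fluence
# normalization.
#
# Photoacoustic signal scales with the local light fluence, which differs
# between wavelengths (the laser's pulse energy is wavelength dependent).
# Each per-wavelength image is therefore divided by the scan-averaged fluence
# at that wavelength before unmixing, so only chromophore absorption -- not
# delivered energy -- drives the spectral shape of each pixel.

#' Acquisition configuration
#'
#' Fixed acquisition constants used by fluence estimation and the synthetic
#' generators.
#'
#' @param beam_area_cm2 Area of the laser beam at the focal point, cm^2
#'   (default 0.51); divides pulse energy to give fluence.
#' @param wavelengths_nm Ordered imaging wavelengths (nm).
#' @param frame_step_mm Scan-motor step between frames, mm (default 0.032).
#' @param gruneisen Dimensionless Grueneisen parameter; assumed constant and
#'   absorbed into the arbitrary signal units (default 1).
#' @return A list of class `spa_config`.
#' @export
acquisition_config <- function(beam_area_cm2 = 0.51,
                               wavelengths_nm = default_wavelengths(),
                               frame_step_mm = 0.032,
                               gruneisen = 1.0) {
  assert_number(beam_area_cm2, "beam_area_cm2", positive = TRUE)
  assert_number(frame_step_mm, "frame_step_mm", positive = TRUE)
  assert_number(gruneisen, "gruneisen", positive = TRUE)
  structure(
    list(beam_area_cm2 = beam_area_cm2,
         wavelengths_nm = as.numeric(wavelengths_nm),
         frame_step_mm = frame_step_mm,
         gruneisen = gruneisen),
    class = "spa_config")
}

#' Per-pulse fluence
#'
#' Converts measured pulse energies to fluence by dividing by the beam area
#' at the focal point.
#'
#' @param energy_mJ Measured pulse energy or energies, mJ (>= 0).
#' @param beam_area_cm2 Beam area at the focal point, cm^2 (default 0.51).
#' @return Fluence in mJ cm^-2, same length as `energy_mJ`.
#' @examples
#' pulse_fluence(0.51) # 1 mJ/cm^2
#' @export
pulse_fluence <- function(energy_mJ, beam_area_cm2 = 0.51) {
  assert_number(beam_area_cm2, "beam_area_cm2", positive = TRUE)
  if (any(!is.finite(energy_mJ)) || any(energy_mJ < 0)) {
    spa_abort("Pulse energies must be finite and >= 0.", "spa_domain_error")
  }
  energy_mJ / beam_area_cm2
}

#' Scan-averaged fluence per wavelength
#'
#' Averages the per-pulse fluence over all pulses of each imaging wavelength
#' recorded across a 3D scan.
#'
#' @param pulses A data frame of pulse records with columns `pulse_index`,
#'   `wavelength_nm` and `energy_mJ`.
#' @param config An [acquisition_config()]; declares the imaging wavelengths
#'   and beam area.
#' @return A tibble with one row per imaging wavelength: `wavelength_nm`,
#'   `mean_fluence_mJ_cm2`, `n_pulses`.
#' @export
mean_fluence <- function(pulses, config = acquisition_config()) {
  needed <- c("wavelength_nm", "energy_mJ")
  if (!all(needed %in% names(pulses))) {
    spa_abort("`pulses` must have columns wavelength_nm and energy_mJ.",
              "spa_validation_error")
  }
  missing_wl <- setdiff(config$wavelengths_nm, unique(pulses$wavelength_nm))
  if (length(missing_wl) > 0L) {
    spa_abort(
      sprintf("No pulses recorded for declared wavelength(s): %s nm.",
              paste(missing_wl, collapse = ", ")),
      "spa_missing_fluence_error")
  }
  out <- pulses |>
    dplyr::filter(.data$wavelength_nm %in% config$wavelengths_nm) |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::summarise(
      mean_fluence_mJ_cm2 = mean(pulse_fluence(.data$energy_mJ, config$beam_area_cm2)),
      n_pulses = dplyr::n(),
      .groups = "drop") |>
    dplyr::arrange(match(.data$wavelength_nm, config$wavelengths_nm))
  bad <- out$mean_fluence_mJ_cm2 <= 0
  if (any(bad)) {
    spa_abort(
      sprintf("Zero mean fluence at wavelength(s) %s nm; cannot normalize.",
              paste(out$wavelength_nm[bad], collapse = ", ")),
      "spa_zero_fluence_error")
  }
  out
}

#' Construct a multispectral photoacoustic stack
#'
#' Container for co-registered per-wavelength image frames. Pixel values are
#' non-negative photoacoustic signal intensities in arbitrary units; frames
#' are indexed `[frame, wavelength, row, col]` with pixel (row 1, col 1) at
#' the top-left and depth increasing with row index.
#'
#' @param frames 4-D numeric array `F x W x H x Wd` (frame, wavelength, row,
#'   col), all values finite and >= 0.
#' @param wavelengths_nm Length-`W` wavelength list matching dim 2.
#' @param config An [acquisition_config()].
#' @param fluence_normalized Has the stack already been fluence normalized?
#' @param pixel_size_mm Isotropic pixel size, mm.
#' @return An object of class `spa_stack`.
#' @export
ms_stack <- function(frames, wavelengths_nm = default_wavelengths(),
                     config = acquisition_config(wavelengths_nm = wavelengths_nm),
                     fluence_normalized = FALSE, pixel_size_mm = 0.032) {
  if (!is.array(frames) || length(dim(frames)) != 4L) {
    spa_abort("`frames` must be a 4-D array (frame, wavelength, row, col).",
              "spa_validation_error")
  }
  if (dim(frames)[2] != length(wavelengths_nm)) {
    spa_abort(
      sprintf("Stack has %d wavelength planes but %d wavelengths declared.",
              dim(frames)[2], length(wavelengths_nm)),
      "spa_format_error")
  }
  if (any(!is.finite(frames))) {
    spa_abort("Stack intensities must all be finite.", "spa_validation_error")
  }
  if (any(frames < 0)) {
    idx <- which(frames < 0, arr.ind = TRUE)[1L, ]
    spa_abort(
      sprintf("Negative pixel intensity at frame %d, wavelength %g nm.",
              idx[1], wavelengths_nm[idx[2]]),
      "spa_validation_error")
  }
  structure(
    list(frames = frames,
         wavelengths_nm = as.numeric(wavelengths_nm),
         fluence_normalized = isTRUE(fluence_normalized),
         config = config,
         pixel_size_mm = pixel_size_mm),
    class = "spa_stack")
}

#' @export
print.spa_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<spa_stack> %d frame(s), %d wavelengths (%s nm), %d x %d px, %s\n",
              d[1], d[2], paste(x$wavelengths_nm, collapse = "/"), d[3], d[4],
              if (x$fluence_normalized) "fluence-normalized" else "raw"))
  invisible(x)
}

#' @export
dim.spa_stack <- function(x) dim(x$frames)

#' Fluence-normalize a multispectral stack
#'
#' Divides every pixel at wavelength `w` by the scan-averaged fluence at `w`,
#' removing wavelength-to-wavelength laser energy variation. The input stack
#' is not modified.
#'
#' @param stack An [ms_stack()] that has not yet been normalized.
#' @param fluences Output of [mean_fluence()]: columns `wavelength_nm`,
#'   `mean_fluence_mJ_cm2`.
#' @return A new `spa_stack` with `fluence_normalized = TRUE`.
#' @export
fluence_normalize <- function(stack, fluences) {
  stopifnot(inherits(stack, "spa_stack"))
  if (stack$fluence_normalized) {
    spa_abort("Stack is already fluence-normalized.", "spa_state_error")
  }
  phi <- fluences$mean_fluence_mJ_cm2[match(stack$wavelengths_nm,
                                            fluences$wavelength_nm)]
  if (anyNA(phi)) {
    missing_wl <- stack$wavelengths_nm[is.na(phi)]
    spa_abort(
      sprintf("No fluence estimate for wavelength(s) %s nm.",
              paste(missing_wl, collapse = ", ")),
      "spa_missing_fluence_error")
  }
  if (any(phi <= 0)) {
    spa_abort("Fluence must be > 0 for every wavelength.", "spa_zero_fluence_error")
  }
  frames <- stack$frames
  for (w in seq_along(phi)) {
    frames[, w, , ] <- frames[, w, , , drop = FALSE] / phi[w]
  }
  out <- stack
  out$frames <- frames
  out$fluence_normalized <- TRUE
  out
}
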