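# ggplot2 graphics for spectra, concentration maps, calibration and cohorts.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot chromophore spectra
#'
#' Line plot of (normalized or raw) spectra with the imaging wavelengths
#' marked.
#'
#' @param spectra Output of [load_reference_spectra()] or
#'   [minmax_normalize()].
#' @param wavelengths_nm Imaging wavelengths to mark (default
#'   [default_wavelengths()]; `NULL` for none).
#' @return A ggplot.
#' @export
plot_spectra <- function(spectra, wavelengths_nm = default_wavelengths()) {
  value_col <- if ("value" %in% names(spectra)) "value" else "absorptivity"
  p <- ggplot2::ggplot(spectra, ggplot2::aes(
    x = .data$wavelength_nm, y = .data[[value_col]],
    colour = .data$chromophore)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)",
                  y = if (value_col == "value") "Normalized absorptivity"
                      else "Absorptivity",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(wavelengths_nm)) {
    p <- p + ggplot2::geom_vline(xintercept = wavelengths_nm,
                                 linetype = "dashed", alpha = 0.4)
  }
  p
}

#' Plot a chromophore concentration map
#'
#' @param object An `spa_conc_map`.
#' @param chromophore Channel to display (default `"collagen"`).
#' @param frame Frame index (default 1).
#' @param ... Unused.
#' @return A ggplot raster of the channel in a.u.; degenerate pixels are
#'   blanked.
#' @export
autoplot.spa_conc_map <- function(object, chromophore = "collagen",
                                  frame = 1, ...) {
  df <- tidy.spa_conc_map(object, frames = frame)
  df <- df[df$chromophore == chromophore, ]
  df$au[df$degenerate] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$au)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(title = sprintf("%s, frame %d", chromophore, frame),
                  fill = "a.u.", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a histology calibration fit
#'
#' @param object An `spa_calibration_fit`.
#' @param ... Unused.
#' @return A ggplot of photoacoustic collagen estimates against histology
#'   area fractions with the fitted line.
#' @export
autoplot.spa_calibration_fit <- function(object, ...) {
  g <- glance.spa_calibration_fit(object)
  ggplot2::ggplot(object$data, ggplot2::aes(
    x = .data$area_fraction, y = .data$mean_collagen_au)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$organ)) +
    ggplot2::geom_abline(slope = g$slope, intercept = g$intercept) +
    ggplot2::labs(
      x = "Trichrome collagen area fraction",
      y = "sPA mean collagen (a.u.)",
      subtitle = sprintf("R² = %.3f, p = %.3g (n = %d)",
                         g$r_squared, g$p_value, g$n)) +
    ggplot2::theme_minimal()
}

#' Plot cohort age trends
#'
#' Age against mean collagen per organ, split by group, with per-group OLS
#' lines.
#'
#' @param cohort A cohort tibble (see [validate_cohort()]).
#' @return A ggplot faceted by organ.
#' @export
plot_cohort <- function(cohort) {
  validate_cohort(cohort)
  cohort <- dplyr::mutate(
    cohort, group = ifelse(.data$prolapse, "prolapsed", "normal"))
  ggplot2::ggplot(cohort, ggplot2::aes(
    x = .data$age_months, y = .data$mean_collagen_au, colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~factor(organ, organ_levels())) +
    ggplot2::labs(x = "Age (months)", y = "Mean collagen (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
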