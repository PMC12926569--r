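# broom-style tidiers for the package's fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a design matrix into long form
#'
#' @param x An `spa_design_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `wavelength_nm`, `chromophore`, `value`.
#' @export
tidy.spa_design_matrix <- function(x, ...) {
  tibble::tibble(
    wavelength_nm = rep(attr(x, "wavelengths_nm"), times = ncol(x)),
    chromophore = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x)))
}

#' Tidy a concentration map into a long pixel table
#'
#' @param x An `spa_conc_map`.
#' @param frames Frames to include (default all).
#' @param ... Unused.
#' @return A tibble with columns `frame`, `row`, `col`, `chromophore`,
#'   `au`, `degenerate`.
#' @export
tidy.spa_conc_map <- function(x, frames = NULL, ...) {
  d <- dim(x$maps)
  frames <- frames %||% seq_len(d[1])
  purrr::map_dfr(frames, function(f) {
    purrr::map_dfr(seq_along(x$chromophores), function(ci) {
      tibble::tibble(
        frame = f,
        row = rep(seq_len(d[3]), times = d[4]),
        col = rep(seq_len(d[4]), each = d[3]),
        chromophore = x$chromophores[ci],
        au = as.vector(x$maps[f, ci, , ]),
        degenerate = as.vector(x$degenerate[f, , ]))
    })
  })
}

#' Tidy / summarize a histology calibration fit
#'
#' `tidy()` returns the coefficient table; `glance()` returns the one-row
#' model summary (slope, intercept, R^2, slope p-value, n).
#'
#' @param x An `spa_calibration_fit` from [calibrate_histology()].
#' @param ... Unused.
#' @export
tidy.spa_calibration_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = cf[, 1],
    std_error = cf[, 2],
    statistic = cf[, 3],
    p_value = cf[, 4])
}

#' @rdname tidy.spa_calibration_fit
#' @export
glance.spa_calibration_fit <- function(x, ...) {
  sm <- summary(x$fit)
  cf <- stats::coef(x$fit)
  tibble::tibble(
    slope = unname(cf[2]),
    intercept = unname(cf[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n = nrow(x$data))
}
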