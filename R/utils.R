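# Internal helpers shared across modules.

#' @importFrom rlang abort
NULL

spa_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "spacollagen_error"), ...)
}

# numeric scalar check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_number <- function(x, name, positive = FALSE) {
  if (!is_number(x)) {
    spa_abort(sprintf("`%s` must be a single finite number.", name),
              "spa_domain_error")
  }
  if (positive && x <= 0) {
    spa_abort(sprintf("`%s` must be > 0, got %g.", name, x),
              "spa_domain_error")
  }
  invisible(x)
}

# The four organ cross-sections quantified along the reproductive tract.
organ_levels <- function() c("uterus", "internal_os", "external_os", "vagina")

# Fixed global chromophore column order; prevents silent label swaps.
chromophore_levels <- function() c("collagen", "HbO2", "Hb")

#' Default imaging wavelengths
#'
#' The five NIR-I wavelengths used for acquisition, chosen around features of
#' the collagen absorption spectrum: its NIR-I maximum (690 nm), the
#' highest-fluence laser line (750 nm), a local minimum (~850 nm), a local
#' maximum (~910 nm) and a local minimum (~940 nm).
#'
#' @return Integer vector of wavelengths in nm.
#' @export
default_wavelengths <- function() c(690, 750, 850, 910, 940)
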