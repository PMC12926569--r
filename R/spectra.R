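# Reference chromophore absorption spectra and the spectral design matrix.
#
# The unmixing model treats each fluence-normalized pixel intensity as a
# non-negative mixture of collagen, oxyhemoglobin (HbO2) and deoxyhemoglobin
# (Hb) absorption. Because hemoglobin absorbs orders of magnitude more
# strongly than collagen, each spectrum is min-max normalized over the NIR-I
# window before the system matrix is assembled, so the three chromophores are
# weighted equally in the least-squares system.

#' Load the packaged reference absorption spectra
#'
#' Reads the three chromophore spectra shipped with the package (or
#' equivalently formatted files from `data_dir`): a collagen absorption
#' spectrum and molar extinction spectra for oxy- and deoxyhemoglobin, each
#' tabulated on a dense (2 nm) grid covering at least 650--1000 nm. The
#' packaged files are synthetic reconstructions of the published tabulations
#' (see the package vignette); min-max normalization makes their absolute
#' scale immaterial to unmixing.
#'
#' Files are two-column text (`wavelength_nm, value`) with `# chromophore:`
#' and `# source:` header lines.
#'
#' @param data_dir Directory containing one spectrum file per chromophore.
#'   Defaults to the spectra shipped in `inst/extdata/spectra`.
#' @return A tibble with columns `chromophore`, `wavelength_nm`,
#'   `absorptivity` and `source`, one block per chromophore in the fixed
#'   order collagen, HbO2, Hb.
#' @examples
#' spectra <- load_reference_spectra()
#' dplyr::count(spectra, chromophore)
#' @export
load_reference_spectra <- function(data_dir = NULL) {
  if (is.null(data_dir)) {
    data_dir <- system.file("extdata", "spectra", package = "spacollagen")
  }
  files <- c(
    collagen = "collagen_absorption_synthetic.txt",
    HbO2 = "hbo2_extinction_synthetic.txt",
    Hb = "hb_extinction_synthetic.txt"
  )
  spectra <- purrr::map2(files, names(files), function(fn, chrom) {
    path <- file.path(data_dir, fn)
    if (!file.exists(path)) {
      # fall back to any file in data_dir declaring this chromophore
      cand <- list.files(data_dir, full.names = TRUE)
      hit <- purrr::detect(cand, function(p) {
        h <- tryCatch(readLines(p, n = 1L), error = function(e) "")
        grepl(paste0("chromophore:\\s*", chrom, "\\s*$"), h, ignore.case = TRUE)
      })
      if (is.null(hit)) {
        spa_abort(
          sprintf("No spectrum file found for chromophore '%s' in %s.",
                  chrom, data_dir),
          "spa_load_error")
      }
      path <- hit
    }
    read_spectrum_file(path, chromophore = chrom)
  })
  out <- dplyr::bind_rows(spectra)
  validate_spectra(out)
  out
}

read_spectrum_file <- function(path, chromophore) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  src <- sub("^#\\s*source:\\s*", "", header[grepl("^#\\s*source:", header)])
  if (length(src) == 0L) src <- NA_character_
  fields <- strsplit(trimws(body), "[,[:space:]]+")
  ok <- lengths(fields) == 2L
  if (!all(ok)) {
    spa_abort(
      sprintf("Malformed spectrum file for chromophore '%s': %s (expected two columns per row).",
              chromophore, path),
      "spa_load_error")
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 2, byrow = TRUE))
  if (anyNA(vals)) {
    spa_abort(
      sprintf("Non-numeric entries in spectrum file for chromophore '%s': %s.",
              chromophore, path),
      "spa_load_error")
  }
  tibble::tibble(
    chromophore = chromophore,
    wavelength_nm = vals[, 1],
    absorptivity = vals[, 2],
    source = src[[1]]
  )
}

validate_spectra <- function(spectra) {
  stopifnot(is.data.frame(spectra))
  needed <- c("chromophore", "wavelength_nm", "absorptivity")
  if (!all(needed %in% names(spectra))) {
    spa_abort("Spectra must have columns chromophore, wavelength_nm, absorptivity.",
              "spa_validation_error")
  }
  for (chrom in unique(spectra$chromophore)) {
    s <- spectra[spectra$chromophore == chrom, ]
    if (nrow(s) < 2L) {
      spa_abort(sprintf("Spectrum '%s' needs at least 2 points.", chrom),
                "spa_validation_error")
    }
    if (any(diff(s$wavelength_nm) <= 0)) {
      spa_abort(sprintf("Wavelengths for '%s' must be strictly increasing.", chrom),
                "spa_validation_error")
    }
    if (any(!is.finite(s$absorptivity)) || any(s$absorptivity < 0)) {
      spa_abort(sprintf("Absorptivity for '%s' must be finite and >= 0.", chrom),
                "spa_validation_error")
    }
    if (min(s$wavelength_nm) > 650 || max(s$wavelength_nm) < 1000) {
      spa_abort(
        sprintf("Spectrum '%s' must cover 650-1000 nm (got %g-%g).",
                chrom, min(s$wavelength_nm), max(s$wavelength_nm)),
        "spa_validation_error")
    }
  }
  invisible(spectra)
}

#' Convert a mass-basis absorption coefficient to molar absorptivity
#'
#' Divides an absorption coefficient spectrum (cm^-1) of the pure substance
#' by its molar concentration `mass_density / molar_mass` (mol cm^-3),
#' yielding absorptivity per molar concentration (cm^2 mol^-1). Since the
#' downstream min-max normalization removes absolute scale, this conversion
#' does not change any unmixing result; it is provided so spectra tabulated
#' on either basis can be kept on a common footing.
#'
#' @param spectrum A data frame with columns `wavelength_nm` and `mu_a_cm1`
#'   (absorption coefficient, cm^-1).
#' @param mass_density Mass density of the pure substance, g cm^-3 (> 0).
#' @param molar_mass Molar mass, g mol^-1 (> 0).
#' @return A tibble with columns `wavelength_nm` and `absorptivity`
#'   (cm^2 mol^-1), wavelength grid preserved.
#' @export
mass_to_molar_absorptivity <- function(spectrum, mass_density, molar_mass) {
  assert_number(mass_density, "mass_density", positive = TRUE)
  assert_number(molar_mass, "molar_mass", positive = TRUE)
  if (!all(c("wavelength_nm", "mu_a_cm1") %in% names(spectrum))) {
    spa_abort("`spectrum` must have columns wavelength_nm and mu_a_cm1.",
              "spa_validation_error")
  }
  if (any(spectrum$mu_a_cm1 < 0)) {
    spa_abort("Absorption coefficients must be >= 0.", "spa_domain_error")
  }
  # molar concentration of the pure substance, mol cm^-3; the absorptivity is
  # mu_a per unit of this concentration (cm^2 mol^-1). Absolute scale is
  # removed by min-max normalization downstream.
  molar_conc <- mass_density / molar_mass
  out <- tibble::tibble(
    wavelength_nm = spectrum$wavelength_nm,
    absorptivity = spectrum$mu_a_cm1 / molar_conc
  )
  if ("chromophore" %in% names(spectrum)) {
    out <- dplyr::bind_cols(tibble::tibble(chromophore = spectrum$chromophore), out)
  }
  out
}

#' Min-max normalize absorption spectra
#'
#' Rescales each chromophore's spectrum so that its minimum over `range_nm`
#' maps to 0 and its maximum to 1, equalizing the weight of weak (collagen)
#' and strong (hemoglobin) absorbers in the unmixing system.
#'
#' @param spectra A data frame with columns `chromophore`, `wavelength_nm`
#'   and `absorptivity` (one or more chromophores).
#' @param range_nm Length-2 numeric `(lo, hi)`: the window over which the
#'   min and max are taken. Default 650--1000 nm (the NIR-I window).
#' @return A tibble with columns `chromophore`, `wavelength_nm`, `value`
#'   (unitless, in `[0, 1]` within the range) and attribute
#'   `normalization_range_nm`.
#' @export
minmax_normalize <- function(spectra, range_nm = c(650, 1000)) {
  validate_range <- is.numeric(range_nm) && length(range_nm) == 2L &&
    all(is.finite(range_nm)) && range_nm[1] < range_nm[2]
  if (!validate_range) {
    spa_abort("`range_nm` must be an increasing (lo, hi) pair.", "spa_domain_error")
  }
  if (!"chromophore" %in% names(spectra)) {
    spectra <- dplyr::mutate(spectra, chromophore = "spectrum")
  }
  value_col <- if ("absorptivity" %in% names(spectra)) "absorptivity" else "value"
  out <- spectra |>
    dplyr::group_by(.data$chromophore) |>
    dplyr::group_modify(function(s, key) {
      if (min(s$wavelength_nm) > range_nm[1] || max(s$wavelength_nm) < range_nm[2]) {
        spa_abort(
          sprintf("Spectrum '%s' does not cover the normalization range %g-%g nm.",
                  key$chromophore, range_nm[1], range_nm[2]),
          "spa_range_error")
      }
      inr <- s$wavelength_nm >= range_nm[1] & s$wavelength_nm <= range_nm[2]
      v <- s[[value_col]]
      lo <- min(v[inr]); hi <- max(v[inr])
      if (hi - lo <= 0) {
        spa_abort(
          sprintf("Spectrum '%s' is constant over %g-%g nm; min-max normalization is undefined.",
                  key$chromophore, range_nm[1], range_nm[2]),
          "spa_degenerate_error")
      }
      tibble::tibble(wavelength_nm = s$wavelength_nm, value = (v - lo) / (hi - lo))
    }) |>
    dplyr::ungroup()
  attr(out, "normalization_range_nm") <- range_nm
  out
}

#' Build the spectral unmixing design matrix
#'
#' Samples each normalized spectrum at the imaging wavelengths (piecewise
#' linear interpolation between tabulated points) and assembles the
#' wavelengths x chromophores system matrix `A` with
#' `A[w, c] = normalized absorptivity of chromophore c at wavelength w`.
#' Chromophore columns are kept in the fixed order collagen, HbO2, Hb.
#'
#' @param normalized Output of [minmax_normalize()]: columns `chromophore`,
#'   `wavelength_nm`, `value`.
#' @param wavelengths_nm Imaging wavelengths (default the five NIR-I
#'   wavelengths, [default_wavelengths()]).
#' @return A numeric matrix of class `spa_design_matrix` with wavelengths as
#'   rows and chromophores as columns; attribute `condition_number` records
#'   the 2-norm condition number.
#' @examples
#' A <- load_reference_spectra() |> minmax_normalize() |> build_design_matrix()
#' attr(A, "condition_number")
#' @export
build_design_matrix <- function(normalized, wavelengths_nm = default_wavelengths()) {
  chroms <- unique(normalized$chromophore)
  canon <- chromophore_levels()
  if (all(chroms %in% canon)) chroms <- canon[canon %in% chroms]
  if (length(wavelengths_nm) < length(chroms)) {
    spa_abort(
      sprintf("Need at least as many wavelengths (%d) as chromophores (%d).",
              length(wavelengths_nm), length(chroms)),
      "spa_validation_error")
  }
  cols <- purrr::map(chroms, function(chrom) {
    s <- normalized[normalized$chromophore == chrom, ]
    if (min(wavelengths_nm) < min(s$wavelength_nm) ||
        max(wavelengths_nm) > max(s$wavelength_nm)) {
      spa_abort(
        sprintf("Imaging wavelength outside the coverage of spectrum '%s' (%g-%g nm).",
                chrom, min(s$wavelength_nm), max(s$wavelength_nm)),
        "spa_range_error")
    }
    stats::approx(s$wavelength_nm, s$value, xout = wavelengths_nm)$y
  })
  A <- do.call(cbind, cols)
  dimnames(A) <- list(as.character(wavelengths_nm), chroms)
  rk <- qr(A)$rank
  if (rk < ncol(A)) {
    # identify (near-)collinear column pairs to name in the error
    cc <- stats::cor(A)
    pairs <- which(abs(cc) > 1 - 1e-8 & upper.tri(cc), arr.ind = TRUE)
    collinear <- apply(pairs, 1L, function(ij) {
      paste(colnames(A)[ij], collapse = " ~ ")
    })
    spa_abort(
      sprintf("Design matrix is rank deficient (rank %d < %d); collinear columns: %s.",
              rk, ncol(A), paste(collinear, collapse = ", ")),
      "spa_rank_error")
  }
  structure(
    A,
    class = c("spa_design_matrix", class(A)),
    wavelengths_nm = wavelengths_nm,
    chromophores = chroms,
    condition_number = kappa(A, exact = TRUE)
  )
}

#' @export
print.spa_design_matrix <- function(x, ...) {
  cat(sprintf("<spa_design_matrix> %d wavelengths x %d chromophores, condition number %.2f\n",
              nrow(x), ncol(x), attr(x, "condition_number")))
  print(unclass(x)[, , drop = FALSE], digits = 4)
  invisible(x)
}

#' Locate spectral features of a spectrum
#'
#' Finds the in-range global maximum/minimum and interior local extrema of
#' each chromophore's tabulated spectrum; used to verify the wavelength
#' selection rationale (e.g. the collagen NIR-I maximum at 690 nm).
#'
#' @inheritParams minmax_normalize
#' @return A tibble with columns `chromophore`, `feature`
#'   (`"global_max"`, `"global_min"`, `"local_max"`, `"local_min"`),
#'   `wavelength_nm` and `value`.
#' @export
spectrum_features <- function(spectra, range_nm = c(650, 1000)) {
  if (!"chromophore" %in% names(spectra)) {
    spectra <- dplyr::mutate(spectra, chromophore = "spectrum")
  }
  value_col <- if ("absorptivity" %in% names(spectra)) "absorptivity" else "value"
  spectra |>
    dplyr::group_by(.data$chromophore) |>
    dplyr::group_modify(function(s, key) {
      inr <- s$wavelength_nm >= range_nm[1] & s$wavelength_nm <= range_nm[2]
      w <- s$wavelength_nm[inr]
      v <- s[[value_col]][inr]
      d2 <- diff(sign(diff(v)))
      lmin <- which(d2 == 2) + 1L
      lmax <- which(d2 == -2) + 1L
      dplyr::bind_rows(
        tibble::tibble(feature = "global_max", wavelength_nm = w[which.max(v)],
                       value = max(v)),
        tibble::tibble(feature = "global_min", wavelength_nm = w[which.min(v)],
                       value = min(v)),
        tibble::tibble(feature = "local_max", wavelength_nm = w[lmax], value = v[lmax]),
        tibble::tibble(feature = "local_min", wavelength_nm = w[lmin], value = v[lmin])
      )
    }) |>
    dplyr::ungroup()
}
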