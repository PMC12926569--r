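# Per-pixel linear spectral unmixing.
#
# Model: the fluence-normalized intensity at wavelength w is the sum over
# chromophores of (relative concentration x normalized absorptivity), i.e.
# I = A c with A the design matrix. The default solver follows the published
# procedure: ordinary least squares on the W x C system, negative
# concentrations replaced by 0, then the vector rescaled so the chromophore
# sum equals 1 (clipping is applied before the sum constraint so both
# printed constraints hold at the output). An exact non-negative
# least-squares mode ("nnls", active-set enumeration over supports) is
# available for sensitivity analysis.

solve_pixels <- function(Imat, A, solver = c("ols-clip", "nnls")) {
  solver <- match.arg(solver)
  if (any(!is.finite(Imat))) {
    spa_abort("Intensities must be finite.", "spa_domain_error")
  }
  if (any(Imat < 0)) {
    spa_abort("Intensities must be >= 0 (fluence-normalized signal).",
              "spa_domain_error")
  }
  C <- ncol(A)
  if (qr(A)$rank < C) {
    spa_abort("Design matrix is rank deficient; unmixing is not identifiable.",
              "spa_rank_error")
  }
  if (solver == "ols-clip") {
    P <- solve(crossprod(A), t(A))      # C x W
    conc <- Imat %*% t(P)               # n x C
  } else {
    # exact NNLS for small C: enumerate non-empty supports, keep the
    # feasible restricted-OLS solution with the smallest residual
    n <- nrow(Imat)
    conc <- matrix(0, n, C)
    bestr <- rep(Inf, n)
    supports <- unlist(lapply(seq_len(C), function(k) {
      utils::combn(C, k, simplify = FALSE)
    }), recursive = FALSE)
    nrm2 <- rowSums(Imat^2)
    for (S in supports) {
      As <- A[, S, drop = FALSE]
      Ps <- solve(crossprod(As), t(As))
      cs <- Imat %*% t(Ps)              # n x |S|
      fit <- cs %*% t(As)               # n x W
      res <- nrm2 - 2 * rowSums(Imat * fit) + rowSums(fit^2)
      feas <- apply(cs >= -1e-12, 1L, all) & res < bestr - 1e-15
      if (any(feas)) {
        conc[feas, ] <- 0
        conc[feas, S] <- pmax(cs[feas, , drop = FALSE], 0)
        bestr[feas] <- res[feas]
      }
    }
  }
  conc[conc < 0] <- 0
  s <- rowSums(conc)
  degenerate <- s <= 0
  conc[!degenerate, ] <- conc[!degenerate, , drop = FALSE] / s[!degenerate]
  conc[degenerate, ] <- 0
  list(conc = conc, degenerate = degenerate)
}

#' Unmix a single pixel's intensity vector
#'
#' Solves the linear mixing system for one pixel and applies the output
#' constraints: negative concentrations are replaced by 0 and the result is
#' rescaled so the chromophore sum equals 1. Pixels whose solution clips to
#' all zeros (e.g. zero signal) are flagged degenerate and returned as zeros.
#'
#' @param intensities Length-`W` fluence-normalized intensity vector.
#' @param design A [build_design_matrix()] result (`W x C`).
#' @param solver `"ols-clip"` (default, the published procedure) or
#'   `"nnls"` (exact non-negative least squares).
#' @return A list with `concentration` (named length-`C` vector of relative
#'   concentrations in `[0, 1]`, summing to 1 unless degenerate) and
#'   `degenerate` (logical).
#' @examples
#' A <- load_reference_spectra() |> minmax_normalize() |> build_design_matrix()
#' unmix_pixel(3 * A[, "collagen"], A)$concentration
#' @export
unmix_pixel <- function(intensities, design, solver = c("ols-clip", "nnls")) {
  if (length(intensities) != nrow(design)) {
    spa_abort(
      sprintf("Pixel has %d intensities but the design matrix has %d wavelengths.",
              length(intensities), nrow(design)),
      "spa_validation_error")
  }
  res <- solve_pixels(matrix(intensities, nrow = 1L), design, solver)
  conc <- drop(res$conc)
  names(conc) <- colnames(design)
  list(concentration = conc, degenerate = res$degenerate[1L])
}

#' Unmix a fluence-normalized multispectral stack
#'
#' Applies [unmix_pixel()] at every pixel of every frame and rescales the
#' relative concentrations to arbitrary units (1000 a.u. = relative
#' concentration 1).
#'
#' @param stack A fluence-normalized [ms_stack()].
#' @inheritParams unmix_pixel
#' @return An object of class `spa_conc_map`: a list with `maps`
#'   (`F x C x H x W` array in a.u.), `chromophores`, `degenerate` (logical
#'   `F x H x W` mask of pixels where unmixing was undefined; zeros there are
#'   imputed, not measured), `units` and `solver`.
#' @export
unmix_stack <- function(stack, design, solver = c("ols-clip", "nnls")) {
  stopifnot(inherits(stack, "spa_stack"))
  solver <- match.arg(solver)
  if (!stack$fluence_normalized) {
    spa_abort("Stack must be fluence-normalized before unmixing.",
              "spa_state_error")
  }
  wl <- attr(design, "wavelengths_nm")
  if (!isTRUE(all.equal(sort(wl), sort(stack$wavelengths_nm)))) {
    spa_abort("Design-matrix wavelengths do not match the stack's wavelengths.",
              "spa_validation_error")
  }
  # align design rows to stack wavelength order
  ord <- match(stack$wavelengths_nm, wl)
  A <- design[ord, , drop = FALSE]
  d <- dim(stack$frames)                 # F, W, H, Wd
  F <- d[1]; W <- d[2]; H <- d[3]; Wd <- d[4]
  C <- ncol(A)
  # pixels x wavelengths matrix, frames stacked
  Imat <- matrix(aperm(stack$frames, c(3, 4, 1, 2)), nrow = H * Wd * F, ncol = W)
  res <- solve_pixels(Imat, A, solver)
  au <- rescale_au(res$conc)
  maps <- aperm(array(au, dim = c(H, Wd, F, C)), c(3, 4, 1, 2))
  degen <- aperm(array(res$degenerate, dim = c(H, Wd, F)), c(3, 1, 2))
  structure(
    list(maps = maps,
         chromophores = colnames(A),
         degenerate = degen,
         units = "a.u. (1000 a.u. = relative concentration 1)",
         solver = solver,
         wavelengths_nm = stack$wavelengths_nm),
    class = "spa_conc_map")
}

#' @export
print.spa_conc_map <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<spa_conc_map> %d frame(s), chromophores %s, %d x %d px (%s; solver %s)\n",
              d[1], paste(x$chromophores, collapse = "/"), d[3], d[4],
              x$units, x$solver))
  cat(sprintf("  degenerate pixels: %d of %d\n", sum(x$degenerate),
              length(x$degenerate)))
  invisible(x)
}

#' @export
dim.spa_conc_map <- function(x) dim(x$maps)

#' Extract one chromophore channel of a concentration map
#'
#' @param conc An `spa_conc_map`.
#' @param chromophore One of the map's chromophore labels.
#' @return A numeric `F x H x W` array in a.u.
#' @export
conc_channel <- function(conc, chromophore = "collagen") {
  stopifnot(inherits(conc, "spa_conc_map"))
  i <- match(chromophore, conc$chromophores)
  if (is.na(i)) {
    spa_abort(
      sprintf("Unknown chromophore '%s'; available: %s.", chromophore,
              paste(conc$chromophores, collapse = ", ")),
      "spa_vocabulary_error")
  }
  d <- dim(conc$maps)
  array(conc$maps[, i, , ], dim = d[c(1, 3, 4)])
}

#' Rescale relative concentrations to arbitrary units
#'
#' Multiplies relative concentrations in `[0, 1]` by 1000, so that an a.u.
#' of 1000 equals a relative concentration of 1 (chosen to make the small
#' collagen fractions legible).
#'
#' @param relative Numeric values in `[0, 1]`.
#' @return `1000 * relative`.
#' @export
rescale_au <- function(relative) {
  if (any(!is.finite(relative)) || any(relative < 0) || any(relative > 1)) {
    spa_abort("Relative concentrations must lie in [0, 1].", "spa_domain_error")
  }
  1000 * relative
}

#' Oxygen saturation map
#'
#' Computes pixelwise blood oxygen saturation sO2 = HbO2 / (HbO2 + Hb) from
#' an unmixed concentration map; undefined (NA) where the total hemoglobin
#' signal is zero.
#'
#' @param conc An `spa_conc_map` containing `HbO2` and `Hb` channels.
#' @return A numeric `F x H x W` array of class `spa_so2_map` with values in
#'   `[0, 1]` or `NA` where undefined.
#' @export
so2_map <- function(conc) {
  hbo2 <- conc_channel(conc, "HbO2")
  hb <- conc_channel(conc, "Hb")
  tot <- hbo2 + hb
  so2 <- hbo2 / tot
  so2[tot == 0] <- NA_real_
  structure(so2, class = c("spa_so2_map", "array"),
            definition = "HbO2 / (HbO2 + Hb)")
}
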