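# Masson's trichrome color deconvolution, collagen area fraction, and the
# linear calibration of photoacoustic collagen estimates against histology.
#
# Stained-section RGB images are separated into per-stain density channels
# via the optical-density (Beer-Lambert) method: OD = -log10(I / I0) per RGB
# channel, and densities are the OD vector mapped through the inverse of the
# stain-vector basis. The fraction of tissue pixels whose blue (collagen)
# density exceeds a threshold is the histological collagen measure.

#' Default Masson's trichrome stain vectors
#'
#' The published trichrome stain basis used by the standard Fiji color
#' deconvolution plugin: a blue collagen stain, a red cytoplasm stain, and a
#' residual third vector completing the basis (unit-normalized cross
#' product).
#'
#' @return A 3x3 [stain_matrix()] with rows `collagen_blue`,
#'   `cytoplasm_red`, `residual`.
#' @export
masson_trichrome_stains <- function() {
  stain_matrix(
    rbind(collagen_blue = c(0.7995107, 0.5913521, 0.10528667),
          cytoplasm_red = c(0.09997159, 0.73738605, 0.6680326)))
}

#' Construct a stain matrix
#'
#' Rows are per-stain optical-density direction vectors (RGB components);
#' each row is rescaled to unit Euclidean norm. If only two stains are
#' given, the basis is completed with their unit-normalized cross product.
#'
#' @param vectors A 2x3 or 3x3 numeric matrix, one stain per row; row names
#'   become the stain names.
#' @return A 3x3 matrix of class `spa_stain_matrix`.
#' @export
stain_matrix <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L || !nrow(vectors) %in% c(2L, 3L)) {
    spa_abort("`vectors` must be a 2x3 or 3x3 matrix of RGB OD components.",
              "spa_validation_error")
  }
  if (is.null(rownames(vectors))) {
    rownames(vectors) <- c("stain1", "stain2", "residual")[seq_len(nrow(vectors))]
  }
  if (nrow(vectors) == 2L) {
    v1 <- vectors[1, ]; v2 <- vectors[2, ]
    cp <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    if (sqrt(sum(cp^2)) < 1e-8 * sqrt(sum(v1^2) * sum(v2^2))) {
      spa_abort("Stain matrix is singular; stain vectors are collinear.",
                "spa_matrix_error")
    }
    vectors <- rbind(vectors, residual = cp)
  }
  nrm <- sqrt(rowSums(vectors^2))
  if (any(nrm == 0)) {
    spa_abort("Stain vectors must be non-zero.", "spa_validation_error")
  }
  vectors <- vectors / nrm
  if (abs(det(vectors)) < 1e-8) {
    spa_abort("Stain matrix is singular; stain vectors are collinear.",
              "spa_matrix_error")
  }
  structure(vectors, class = c("spa_stain_matrix", class(vectors)))
}

rgb_to_od <- function(rgb_image, I0 = NULL) {
  if (!(is.array(rgb_image) && length(dim(rgb_image)) == 3L &&
        dim(rgb_image)[3] == 3L)) {
    spa_abort("`rgb_image` must be an H x W x 3 array.", "spa_validation_error")
  }
  if (is.null(I0)) I0 <- if (max(rgb_image) <= 1) 1 else 255
  if (any(rgb_image <= 0) || any(rgb_image > I0)) {
    spa_abort(
      sprintf("RGB intensities must lie in (0, %g].", I0),
      "spa_domain_error")
  }
  -log10(rgb_image / I0)
}

#' Color-deconvolve a stained RGB image
#'
#' Converts the image to per-channel optical densities (`-log10(I / I0)`,
#' with `I0 = 255` for 8-bit images or 1 for unit-scaled images) and maps
#' each pixel's OD vector through the inverse stain basis; densities are
#' clipped at 0.
#'
#' @param rgb_image `H x W x 3` array of intensities in `(0, I0]`.
#' @param stains A [stain_matrix()] (default [masson_trichrome_stains()]).
#' @return An `H x W x 3` array of per-stain densities; the third dimension
#'   is named by the stains.
#' @export
color_deconvolve <- function(rgb_image, stains = masson_trichrome_stains()) {
  stopifnot(inherits(stains, "spa_stain_matrix"))
  od <- rgb_to_od(rgb_image)
  d <- dim(od)
  odm <- matrix(od, ncol = 3L)              # pixels x RGB
  dens <- odm %*% solve(stains)             # pixels x stains  (OD = dens %*% stains)
  dens[dens < 0] <- 0
  out <- array(dens, dim = d)
  dimnames(out) <- list(NULL, NULL, rownames(stains))
  out
}

#' Tissue mask from total optical density
#'
#' A pixel is tissue if its summed RGB optical density exceeds a background
#' threshold; white background pixels have (near-)zero OD.
#'
#' @inheritParams color_deconvolve
#' @param threshold Total-OD background threshold (default 0.05).
#' @return A logical `H x W` matrix.
#' @export
tissue_mask <- function(rgb_image, threshold = 0.05) {
  od <- rgb_to_od(rgb_image)
  total <- od[, , 1] + od[, , 2] + od[, , 3]
  total > threshold
}

# Otsu's threshold on a numeric vector (256-bin histogram between-class
# variance maximization); returns a cut value, positives are values > cut.
otsu_threshold <- function(values, nbins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  h <- hist(values, breaks = seq(rng[1], rng[2], length.out = nbins + 1L),
            plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  w1 <- cumsum(counts)
  w2 <- sum(counts) - w1
  mu1 <- cumsum(counts * mids) / pmax(w1, 1)
  mu2 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (mu1 - mu2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  h$breaks[which.max(between) + 1L]
}

#' Collagen area fraction of a stained section
#'
#' Fraction of tissue pixels whose blue (collagen) stain density exceeds a
#' threshold. The default threshold is Otsu's method computed on the blue
#' densities within the tissue mask (deterministic and parameter-free); a
#' fixed numeric threshold may be supplied instead.
#'
#' @param blue_channel `H x W` matrix of blue-stain densities, e.g.
#'   `color_deconvolve(img)[, , "collagen_blue"]`.
#' @param mask Logical `H x W` tissue mask from [tissue_mask()].
#' @param threshold `"otsu"` (default) or a fixed numeric density threshold.
#' @param animal_id,organ Labels recorded in the output.
#' @return A one-row tibble: `animal_id`, `organ`, `area_fraction`,
#'   `n_tissue_pixels`, `threshold_used`.
#' @export
collagen_area_fraction <- function(blue_channel, mask, threshold = "otsu",
                                   animal_id = NA_character_,
                                   organ = NA_character_) {
  if (!any(mask)) {
    spa_abort("Tissue mask is empty; no pixels to measure.", "spa_empty_error")
  }
  vals <- blue_channel[mask]
  thr <- if (identical(threshold, "otsu")) otsu_threshold(vals) else threshold
  assert_number(thr, "threshold")
  tibble::tibble(
    animal_id = animal_id,
    organ = organ,
    area_fraction = mean(vals > thr),
    n_tissue_pixels = length(vals),
    threshold_used = thr)
}

#' Calibrate photoacoustic collagen estimates against histology
#'
#' Ordinary least-squares regression of the photoacoustic mean collagen
#' estimate (a.u.) on the histological collagen area fraction, over matched
#' (animal, organ) pairs. Reports the slope, intercept, coefficient of
#' determination and the two-sided slope p-value (t distribution, n - 2 df).
#'
#' @param spa_means Tibble of [organ_mean()] summaries: `animal_id`,
#'   `organ`, `mean_collagen_au`.
#' @param hist Tibble of [collagen_area_fraction()] measurements:
#'   `animal_id`, `organ`, `area_fraction`.
#' @return An object of class `spa_calibration_fit`; see [tidy()] and
#'   [glance()] methods.
#' @export
calibrate_histology <- function(spa_means, hist) {
  pairs <- dplyr::inner_join(
    spa_means[, c("animal_id", "organ", "mean_collagen_au")],
    hist[, c("animal_id", "organ", "area_fraction")],
    by = c("animal_id", "organ"))
  if (nrow(pairs) < 3L) {
    spa_abort(
      sprintf("Need at least 3 matched (animal, organ) pairs, got %d.",
              nrow(pairs)),
      "spa_sample_size_error")
  }
  if (stats::var(pairs$area_fraction) == 0) {
    spa_abort("Area fractions have zero variance; calibration is degenerate.",
              "spa_degenerate_error")
  }
  fit <- stats::lm(mean_collagen_au ~ area_fraction, data = pairs)
  structure(
    list(fit = fit, data = pairs),
    class = "spa_calibration_fit")
}

#' @export
print.spa_calibration_fit <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf("<spa_calibration_fit> n = %d: au = %.3g + %.3g * area_fraction\n",
              g$n, g$intercept, g$slope))
  cat(sprintf("  R^2 = %.3f, slope p = %.3g\n", g$r_squared, g$p_value))
  invisible(x)
}
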