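# Seeded synthetic-data generators with known ground truth.
#
# Everything the pipeline consumes can be generated here: multispectral
# phantoms from the forward model I(w, x) = fluence(w) * sum_c A[w, c] *
# conc(c, x) + noise, trichrome-like stained sections with a known blue area
# fraction, per-pulse energy logs consistent with the true fluences, ROI
# annotations tracing the phantom regions, and cohort tables with prescribed
# group-dependent age slopes. Same seed, same output, bit for bit.

#' Specify a multispectral tissue phantom
#'
#' The default layout places four rectangular regions named after the organ
#' cross-sections, with collagen fractions ordered uterus < internal_os <
#' external_os ~ vagina and the remaining signal fraction filled with blood
#' at 40% oxygen saturation. This is a documented fixture for pipeline
#' validation, not a claim about real tissue.
#'
#' @param image_size `(height, width)` in pixels (default 128 x 128).
#' @param n_frames Number of scan frames (default 10).
#' @param regions A tibble with columns `organ`, `x0`, `x1`, `y0`, `y1`
#'   (inclusive 0-based pixel ranges) and true fractions `collagen`, `HbO2`,
#'   `Hb` (each >= 0, summing to <= 1 per region; the remainder is null
#'   background).
#' @param fluence_mJ_cm2 Named per-wavelength true mean fluences (> 0).
#' @param noise_sigma Additive Gaussian noise s.d. on intensities (draws
#'   truncated at 0). Default 0.
#' @param energy_jitter Half-width of the multiplicative uniform per-pulse
#'   energy jitter (default 0.05); jitters are recentred so the scan-mean
#'   fluence equals the truth exactly.
#' @param seed Integer seed.
#' @return A list of class `spa_phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(128, 128), n_frames = 10,
                         regions = default_phantom_regions(image_size),
                         fluence_mJ_cm2 = c(`690` = 18, `750` = 22, `850` = 16,
                                            `910` = 13, `940` = 11),
                         noise_sigma = 0, energy_jitter = 0.05, seed = 1L) {
  frac <- regions$collagen + regions$HbO2 + regions$Hb
  if (any(regions$collagen < 0 | regions$HbO2 < 0 | regions$Hb < 0)) {
    spa_abort("Region fractions must be >= 0.", "spa_spec_error")
  }
  if (any(frac > 1 + 1e-12)) {
    spa_abort("Region chromophore fractions must sum to <= 1.", "spa_spec_error")
  }
  if (any(fluence_mJ_cm2 <= 0)) {
    spa_abort("True fluences must be > 0.", "spa_spec_error")
  }
  structure(
    list(image_size = image_size, n_frames = n_frames, regions = regions,
         fluence_mJ_cm2 = fluence_mJ_cm2, noise_sigma = noise_sigma,
         energy_jitter = energy_jitter, seed = as.integer(seed)),
    class = "spa_phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_phantom_regions <- function(image_size = c(128, 128)) {
  h <- image_size[1]; w <- image_size[2]
  band <- floor(w / 4.3)
  gap <- floor((w - 4 * band) / 5)
  x0 <- gap + (0:3) * (band + gap)
  collagen <- c(uterus = 0.10, internal_os = 0.20, external_os = 0.30,
                vagina = 0.30)
  blood <- 1 - collagen
  tibble::tibble(
    organ = names(collagen),
    x0 = x0, x1 = x0 + band - 1L,
    y0 = floor(h * 0.15), y1 = ceiling(h * 0.85),
    collagen = unname(collagen),
    HbO2 = unname(0.40 * blood),   # 40% oxygen saturation
    Hb = unname(0.60 * blood))
}

#' Generate a multispectral phantom
#'
#' Synthesizes a raw (un-normalized) stack from the forward model, a
#' per-pulse energy log whose scan means reproduce the true fluences
#' exactly, ROI annotations tracing the region polygons, and the ground
#' truth concentration map.
#'
#' @param spec A [phantom_spec()].
#' @param design A [build_design_matrix()] whose wavelengths match the
#'   spec's fluence names.
#' @return A list: `stack` (raw [ms_stack()]), `truth` (an `spa_conc_map`
#'   holding the renormalized true fractions in a.u., with background pixels
#'   flagged degenerate), `pulses` (energy-log tibble), `annotations`
#'   (list of [roi_annotation()]s, one per region per frame), `regions`
#'   (the spec's region table).
#' @export
generate_phantom <- function(spec, design) {
  stopifnot(inherits(spec, "spa_phantom_spec"))
  wl <- attr(design, "wavelengths_nm")
  fl_names <- as.numeric(names(spec$fluence_mJ_cm2))
  if (!setequal(fl_names, wl)) {
    spa_abort("Spec fluence wavelengths must match the design matrix.",
              "spa_spec_error")
  }
  phi <- unname(spec$fluence_mJ_cm2[match(wl, fl_names)])
  set.seed(spec$seed)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  W <- length(wl); C <- ncol(design); Fn <- spec$n_frames
  chroms <- colnames(design)

  # per-pixel true fractions (C x H x W), same layout in every frame
  truth_frac <- array(0, dim = c(C, h, w))
  region_polys <- purrr::pmap(spec$regions, function(organ, x0, x1, y0, y1, ...) {
    rbind(c(x0 - 0.5, y0 - 0.5), c(x1 + 0.5, y0 - 0.5),
          c(x1 + 0.5, y1 + 0.5), c(x0 - 0.5, y1 + 0.5))
  })
  for (r in seq_len(nrow(spec$regions))) {
    ann <- roi_annotation(1L, spec$regions$organ[r], region_polys[[r]])
    m <- rasterize_roi(ann, h, w)
    for (ci in seq_len(C)) {
      truth_frac[ci, , ][m] <- spec$regions[[chroms[ci]]][r]
    }
  }

  # forward model
  clean_wl <- purrr::map(seq_len(W), function(wi) {
    img <- matrix(0, h, w)
    for (ci in seq_len(C)) img <- img + design[wi, ci] * truth_frac[ci, , ]
    phi[wi] * img
  })
  frames <- array(0, dim = c(Fn, W, h, w))
  for (f in seq_len(Fn)) {
    for (wi in seq_len(W)) {
      img <- clean_wl[[wi]]
      if (spec$noise_sigma > 0) {
        img <- pmax(img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w), 0)
      }
      frames[f, wi, , ] <- img
    }
  }
  config <- acquisition_config(wavelengths_nm = wl)
  stack <- ms_stack(frames, wavelengths_nm = wl, config = config)

  # energy log: one pulse per frame per wavelength; multiplicative jitter
  # recentred so the scan mean equals the truth exactly
  pulses <- purrr::map_dfr(seq_len(W), function(wi) {
    j <- stats::runif(Fn, 1 - spec$energy_jitter, 1 + spec$energy_jitter)
    j <- j / mean(j)
    tibble::tibble(
      pulse_index = (wi - 1L) * Fn + seq_len(Fn) - 1L,
      wavelength_nm = wl[wi],
      energy_mJ = phi[wi] * config$beam_area_cm2 * j)
  })

  # ground truth as a concentration map: renormalized fractions in a.u.
  fsum <- apply(truth_frac, c(2, 3), sum)
  truth_au <- array(0, dim = c(Fn, C, h, w))
  for (ci in seq_len(C)) {
    plane <- truth_frac[ci, , ]
    plane[fsum > 0] <- plane[fsum > 0] / fsum[fsum > 0]
    for (f in seq_len(Fn)) truth_au[f, ci, , ] <- 1000 * plane
  }
  degen <- array(rep(fsum == 0, each = Fn), dim = c(Fn, h, w))
  truth <- structure(
    list(maps = truth_au, chromophores = chroms, degenerate = degen,
         units = "a.u. (1000 a.u. = relative concentration 1)",
         solver = "ground-truth", wavelengths_nm = wl),
    class = "spa_conc_map")

  annotations <- purrr::flatten(purrr::map(seq_len(Fn), function(f) {
    purrr::map(seq_len(nrow(spec$regions)), function(r) {
      roi_annotation(f, spec$regions$organ[r], region_polys[[r]])
    })
  }))

  list(stack = stack, truth = truth, pulses = pulses,
       annotations = annotations, regions = spec$regions)
}

#' Generate a synthetic trichrome-stained section
#'
#' Paints a tissue footprint with a red cytoplasm stain density, assigns
#' exactly `round(blue_fraction * n_tissue)` randomly placed tissue pixels a
#' blue collagen stain density, and renders the section through the
#' Beer-Lambert model with the given stain vectors (8-bit quantized, white
#' background). Truth masks are returned alongside the image.
#'
#' @param section_size `(height, width)` in pixels.
#' @param blue_fraction Target fraction of tissue pixels stained blue, in
#'   `[0, 1]`.
#' @param stains A [stain_matrix()] (default [masson_trichrome_stains()]).
#' @param tissue_footprint Logical `H x W` matrix; default a centered
#'   ellipse covering ~60% of the section.
#' @param blue_density,red_density Stain densities applied to blue/tissue
#'   pixels.
#' @param seed Integer seed.
#' @return A list: `rgb` (`H x W x 3` intensities in `(0, 255]`),
#'   `tissue` and `blue` truth masks, `blue_fraction_true` (the exact
#'   realized fraction), `stains`.
#' @export
generate_histology <- function(section_size = c(160, 160), blue_fraction = 0.3,
                               stains = masson_trichrome_stains(),
                               tissue_footprint = NULL,
                               blue_density = 1.0, red_density = 0.6,
                               seed = 1L) {
  if (blue_fraction < 0 || blue_fraction > 1) {
    spa_abort("`blue_fraction` must lie in [0, 1].", "spa_spec_error")
  }
  h <- section_size[1]; w <- section_size[2]
  if (is.null(tissue_footprint)) {
    yy <- matrix(seq_len(h), h, w) - (h + 1) / 2
    xx <- matrix(seq_len(w), h, w, byrow = TRUE) - (w + 1) / 2
    tissue_footprint <- (xx / (0.44 * w))^2 + (yy / (0.44 * h))^2 <= 1
  }
  n_tissue <- sum(tissue_footprint)
  if (n_tissue == 0L) {
    spa_abort("Tissue footprint is empty.", "spa_spec_error")
  }
  set.seed(seed)
  n_blue <- round(blue_fraction * n_tissue)
  blue <- matrix(FALSE, h, w)
  idx <- which(tissue_footprint)
  blue[sample(idx, n_blue)] <- TRUE

  d_blue <- ifelse(blue, blue_density, 0)
  d_red <- ifelse(tissue_footprint & !blue, red_density, 0)
  od <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    od[, , ch] <- d_blue * stains["collagen_blue", ch] +
      d_red * stains["cytoplasm_red", ch]
  }
  rgb <- pmax(round(255 * 10^(-od)), 1)
  list(rgb = rgb, tissue = tissue_footprint, blue = blue,
       blue_fraction_true = n_blue / n_tissue, stains = stains)
}

#' Specify a synthetic cohort
#'
#' Defaults emulate the study design: two groups of eight nulliparous
#' animals aged 2-12 months, four organ cross-sections each, collagen
#' increasing with age in the normal group and decreasing in the prolapsed
#' group (most steeply in the external cervical os), with shared
#' between-animal variation and residual noise.
#'
#' @param n_per_group Animals per group (>= 2; default 8).
#' @param age_range_months `(lo, hi)` age range, months.
#' @param effects A tibble with columns `organ`, `group` (`"normal"` /
#'   `"prolapsed"`), `baseline` (a.u. at age 0) and `slope` (a.u./month).
#' @param sd_animal Between-animal s.d. (a.u.), shared across an animal's
#'   organs. Default 40.
#' @param sd_resid Residual s.d. (a.u.) per record. Default 60.
#' @param seed Integer seed.
#' @return A list of class `spa_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 8, age_range_months = c(2, 12),
                        effects = default_cohort_effects(),
                        sd_animal = 40, sd_resid = 60, seed = 1L) {
  if (n_per_group < 2) {
    spa_abort("`n_per_group` must be >= 2.", "spa_spec_error")
  }
  if (sd_animal < 0 || sd_resid < 0) {
    spa_abort("Noise s.d. values must be >= 0.", "spa_spec_error")
  }
  structure(
    list(n_per_group = n_per_group, age_range_months = age_range_months,
         effects = effects, sd_animal = sd_animal, sd_resid = sd_resid,
         seed = as.integer(seed)),
    class = "spa_cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_effects <- function() {
  # Emulates the reported effect structure: collagen rises with age in the
  # normal group and falls in the prolapsed group (steepest in the external
  # cervical os). For the organs reported as not differing between groups,
  # the group trend lines cross at the middle of the age-matched window
  # (6 months), so only the external os carries a group deficit there.
  tibble::tibble(
    organ = rep(organ_levels(), each = 2),
    group = rep(c("normal", "prolapsed"), times = 4),
    baseline = c(150, 288, 230, 422, 240, 400, 260, 440),
    slope = c(15, -8, 20, -12, 40, -30, 20, -10))
}

#' Generate a synthetic cohort table
#'
#' Ages are drawn uniformly over the spec's range; each animal gets a shared
#' Gaussian animal effect, and each organ record adds
#' `baseline + slope * age + residual noise` (floored at 0 to respect the
#' non-negative concentration scale).
#'
#' @param spec A [cohort_spec()].
#' @return A list: `cohort` (tibble with `animal_id`, `genotype`,
#'   `prolapse`, `age_months`, `organ`, `mean_collagen_au`) and `truth`
#'   (the effects table and noise parameters used).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "spa_cohort_spec"))
  set.seed(spec$seed)
  groups <- tibble::tibble(
    group = rep(c("normal", "prolapsed"), each = spec$n_per_group),
    genotype = rep(c("Fbln5_het", "Fbln5_ko"), each = spec$n_per_group),
    prolapse = rep(c(FALSE, TRUE), each = spec$n_per_group))
  animals <- groups |>
    dplyr::mutate(
      animal_id = sprintf("%s%02d", ifelse(.data$prolapse, "P", "N"),
                          dplyr::row_number()),
      age_months = stats::runif(dplyr::n(), spec$age_range_months[1],
                                spec$age_range_months[2]),
      animal_effect = stats::rnorm(dplyr::n(), 0, spec$sd_animal))
  cohort <- tidyr::expand_grid(animals, organ = organ_levels()) |>
    dplyr::left_join(spec$effects, by = c("organ", "group")) |>
    dplyr::mutate(
      mean_collagen_au = pmax(
        .data$baseline + .data$slope * .data$age_months +
          .data$animal_effect + stats::rnorm(dplyr::n(), 0, spec$sd_resid),
        0)) |>
    dplyr::select("animal_id", "genotype", "prolapse", "age_months", "organ",
                  "mean_collagen_au")
  validate_cohort(cohort)
  list(cohort = cohort,
       truth = list(effects = spec$effects, sd_animal = spec$sd_animal,
                    sd_resid = spec$sd_resid))
}
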