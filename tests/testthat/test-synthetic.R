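test_that("all generators are bit-identical under a fixed seed", {
  A <- spa_test_design()
  spec <- phantom_spec(image_size = c(32, 32), n_frames = 2,
                       noise_sigma = 0.5, seed = 13)
  p1 <- generate_phantom(spec, A)
  p2 <- generate_phantom(spec, A)
  expect_identical(p1$stack$frames, p2$stack$frames)
  expect_identical(p1$pulses, p2$pulses)

  h1 <- generate_histology(section_size = c(40, 40), blue_fraction = 0.25, seed = 9)
  h2 <- generate_histology(section_size = c(40, 40), blue_fraction = 0.25, seed = 9)
  expect_identical(h1$rgb, h2$rgb)

  c1 <- generate_cohort(cohort_spec(seed = 8))
  c2 <- generate_cohort(cohort_spec(seed = 8))
  expect_identical(c1$cohort, c2$cohort)
})

test_that("the noiseless phantom round-trips through the full pipeline", {
  spec <- phantom_spec(image_size = c(48, 48), n_frames = 2, noise_sigma = 0,
                       seed = 3)
  out <- run_phantom_pipeline(spec)
  om <- organ_mean(out$conc, out$phantom$annotations, "SYN01")
  truth <- out$phantom$regions
  expect_equal(om$mean_collagen_au[match(truth$organ, om$organ)],
               1000 * truth$collagen, tolerance = 1e-6)
  # concentration maps match the truth map everywhere it is defined
  keep <- !out$phantom$truth$degenerate
  for (ci in seq_along(out$conc$chromophores)) {
    got <- out$conc$maps[, ci, , ][keep]
    want <- out$phantom$truth$maps[, ci, , ][keep]
    expect_equal(got, want, tolerance = 1e-6)
  }
  # background pixels are degenerate in the estimate too
  expect_true(all(out$conc$degenerate[out$phantom$truth$degenerate]))
})

test_that("a pure-hemoglobin region carries no collagen signal", {
  regions <- tibble::tibble(
    organ = c("uterus", "vagina"),
    x0 = c(2L, 18L), x1 = c(13L, 29L), y0 = 2L, y1 = 29L,
    collagen = c(0, 0.3), HbO2 = c(0.4, 0.28), Hb = c(0.6, 0.42))
  spec <- phantom_spec(image_size = c(32, 32), n_frames = 1,
                       regions = regions, seed = 21)
  out <- run_phantom_pipeline(spec)
  om <- organ_mean(out$conc, out$phantom$annotations, "SYN02")
  expect_equal(om$mean_collagen_au[om$organ == "uterus"], 0, tolerance = 1e-9)
  expect_equal(om$mean_collagen_au[om$organ == "vagina"], 300, tolerance = 1e-6)
  # the phantom's blood is at 40% oxygen saturation
  s <- so2_map(out$conc)
  expect_equal(mean(s, na.rm = TRUE), 0.4, tolerance = 1e-6)
})

test_that("phantom specs reject impossible mixtures", {
  bad <- tibble::tibble(organ = "uterus", x0 = 2L, x1 = 10L, y0 = 2L, y1 = 10L,
                        collagen = 0.6, HbO2 = 0.5, Hb = 0.2)
  expect_error(phantom_spec(image_size = c(16, 16), regions = bad),
               class = "spa_spec_error")
  neg <- dplyr::mutate(bad, collagen = -0.1, HbO2 = 0.4)
  expect_error(phantom_spec(image_size = c(16, 16), regions = neg),
               class = "spa_spec_error")
})

test_that("the energy log reproduces the true fluences exactly in scan mean", {
  spec <- phantom_spec(image_size = c(16, 16), n_frames = 5, seed = 31)
  ph <- generate_phantom(spec, spa_test_design())
  fl <- mean_fluence(ph$pulses, ph$stack$config)
  expect_equal(fl$mean_fluence_mJ_cm2,
               unname(spec$fluence_mJ_cm2[as.character(fl$wavelength_nm)]),
               tolerance = 1e-12)
  # jitter is real: individual pulses differ from the mean
  expect_gt(stats::sd(ph$pulses$energy_mJ[ph$pulses$wavelength_nm == 690]), 0)
})

test_that("unmixing error grows monotonically with phantom noise", {
  A <- spa_test_design()
  sigmas <- c(0, 0.2, 0.6, 1.5)
  rmse <- sapply(sigmas, function(sg) {
    errs <- sapply(1:20, function(seed) {
      spec <- phantom_spec(image_size = c(24, 24), n_frames = 1,
                           noise_sigma = sg, seed = 5000 + seed)
      out <- run_phantom_pipeline(spec)
      keep <- !out$phantom$truth$degenerate & !out$conc$degenerate
      ci <- match("collagen", out$conc$chromophores)
      sqrt(mean((out$conc$maps[, ci, , ][keep] -
                   out$phantom$truth$maps[, ci, , ][keep])^2))
    })
    mean(errs)
  })
  expect_true(all(diff(rmse) >= 0))
})

test_that("noiseless cohorts return the prescribed slopes exactly", {
  spec <- cohort_spec(n_per_group = 5, sd_animal = 0, sd_resid = 0, seed = 41)
  co <- generate_cohort(spec)
  slice <- dplyr::filter(co$cohort, organ == "external_os", !prolapse)
  res <- suppressWarnings(age_regression(slice))  # exact fit warns in summary.lm
  truth <- dplyr::filter(spec$effects, organ == "external_os", group == "normal")
  expect_equal(res$slope, truth$slope, tolerance = 1e-9)
  expect_equal(res$intercept, truth$baseline, tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
})

test_that("opposite-signed external-os age slopes are recovered under noise", {
  signs <- vapply(1:200, function(seed) {
    co <- generate_cohort(cohort_spec(seed = 40000 + seed))$cohort
    n <- age_regression(dplyr::filter(co, organ == "external_os", !prolapse))
    p <- age_regression(dplyr::filter(co, organ == "external_os", prolapse))
    n$slope > 0 && p$slope < 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("small cohorts are generated but rejected downstream", {
  co <- generate_cohort(cohort_spec(n_per_group = 2, seed = 1))$cohort
  expect_equal(nrow(co), 2 * 2 * 4)
  slice <- dplyr::filter(co, organ == "uterus", !prolapse)
  expect_error(age_regression(slice), class = "spa_sample_size_error")
  expect_error(cohort_spec(n_per_group = 1), class = "spa_spec_error")
})

test_that("histology generator hits its target fraction at the limits", {
  h0 <- generate_histology(section_size = c(60, 60), blue_fraction = 0, seed = 2)
  h1 <- generate_histology(section_size = c(60, 60), blue_fraction = 1, seed = 2)
  expect_equal(h0$blue_fraction_true, 0)
  expect_equal(h1$blue_fraction_true, 1)
  d0 <- color_deconvolve(h0$rgb, h0$stains)
  expect_equal(
    collagen_area_fraction(d0[, , "collagen_blue"], tissue_mask(h0$rgb),
                           threshold = 0.5)$area_fraction, 0)
  d1 <- color_deconvolve(h1$rgb, h1$stains)
  expect_equal(
    collagen_area_fraction(d1[, , "collagen_blue"], tissue_mask(h1$rgb),
                           threshold = 0.5)$area_fraction, 1)
  expect_error(generate_histology(blue_fraction = 1.2), class = "spa_spec_error")
})
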