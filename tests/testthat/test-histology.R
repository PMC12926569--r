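test_that("stain matrices are unit-row, completed and invertible", {
  S <- masson_trichrome_stains()
  expect_equal(rownames(S), c("collagen_blue", "cytoplasm_red", "residual"))
  expect_equal(unname(sqrt(rowSums(S^2))), rep(1, 3), tolerance = 1e-12)
  expect_gt(abs(det(S)), 1e-3)
  # third vector orthogonal to the first two (cross-product completion)
  expect_equal(sum(S[1, ] * S[3, ]), 0, tolerance = 1e-12)
  expect_equal(sum(S[2, ] * S[3, ]), 0, tolerance = 1e-12)

  expect_error(stain_matrix(rbind(c(1, 0, 0), c(1, 0, 0))),
               class = "spa_matrix_error")
  expect_error(stain_matrix(rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))),
               class = "spa_matrix_error")
})

test_that("white images deconvolve to zero density and empty tissue mask", {
  white <- array(255, dim = c(4, 5, 3))
  dens <- color_deconvolve(white)
  expect_equal(max(abs(dens)), 0)
  expect_false(any(tissue_mask(white)))
  # threshold 0 marks any absorption
  grey <- white; grey[1, 1, ] <- 200
  expect_equal(sum(tissue_mask(grey, threshold = 0)), 1L)
})

test_that("deconvolution inverts the Beer-Lambert forward model", {
  # trichrome basis: any mixture of the two physical stains is a valid image
  S <- masson_trichrome_stains()
  set.seed(31)
  h <- 6; w <- 7
  truth <- array(runif(h * w * 3, 0, 1.2), dim = c(h, w, 3))
  truth[, , 3] <- 0   # the residual direction has negative OD components,
                      # so only the two physical stains generate images
  od <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    od[, , ch] <- truth[, , 1] * S[1, ch] + truth[, , 2] * S[2, ch]
  }
  rgb <- 255 * 10^(-od)          # continuous, no quantization
  rec <- color_deconvolve(rgb, S)
  expect_equal(as.vector(rec), as.vector(truth), tolerance = 1e-9)

  # a basis with non-negative components everywhere supports arbitrary
  # non-negative densities on all three stains
  S2 <- stain_matrix(rbind(s1 = c(0.9, 0.3, 0.1), s2 = c(0.1, 0.8, 0.4),
                           s3 = c(0.2, 0.1, 0.9)))
  truth2 <- array(runif(h * w * 3, 0, 1), dim = c(h, w, 3))
  od2 <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    od2[, , ch] <- truth2[, , 1] * S2[1, ch] + truth2[, , 2] * S2[2, ch] +
      truth2[, , 3] * S2[3, ch]
  }
  rec2 <- color_deconvolve(255 * 10^(-od2), S2)
  expect_equal(as.vector(rec2), as.vector(truth2), tolerance = 1e-9)

  # single-stain pixel: known density on the blue vector only
  od1 <- array(0, dim = c(1, 1, 3))
  for (ch in 1:3) od1[, , ch] <- 0.8 * S["collagen_blue", ch]
  rec1 <- color_deconvolve(255 * 10^(-od1), S)
  expect_equal(as.numeric(rec1[1, 1, "collagen_blue"]), 0.8, tolerance = 1e-9)
  expect_equal(unname(rec1[1, 1, c("cytoplasm_red", "residual")]), c(0, 0),
               tolerance = 1e-9)
})

test_that("invalid RGB ranges are rejected", {
  img <- array(128, dim = c(2, 2, 3))
  img[1, 1, 1] <- 0
  expect_error(color_deconvolve(img), class = "spa_domain_error")
  expect_error(color_deconvolve(array(300, dim = c(2, 2, 3))),
               class = "spa_domain_error")
  expect_error(color_deconvolve(matrix(1, 2, 2)), class = "spa_validation_error")
})

test_that("tissue mask recovers the synthetic footprint", {
  hs <- generate_histology(section_size = c(80, 80), blue_fraction = 0.4,
                           seed = 5)
  tm <- tissue_mask(hs$rgb)
  expect_lt(mean(tm != hs$tissue), 0.01)
})

test_that("area fraction behaves at the saturation limits", {
  blue <- matrix(1, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  expect_equal(collagen_area_fraction(blue, mask, threshold = 0.5)$area_fraction, 1)
  expect_equal(collagen_area_fraction(matrix(0, 10, 10), mask,
                                      threshold = 0.5)$area_fraction, 0)
  expect_error(collagen_area_fraction(blue, matrix(FALSE, 10, 10)),
               class = "spa_empty_error")
})

test_that("synthetic sections are recovered at their true blue fraction", {
  for (bf in c(0.1, 0.3, 0.7)) {
    hs <- generate_histology(section_size = c(120, 120), blue_fraction = bf,
                             seed = 17)
    dens <- color_deconvolve(hs$rgb, hs$stains)
    tm <- tissue_mask(hs$rgb)
    # Otsu default on a genuinely bimodal section
    af_otsu <- collagen_area_fraction(dens[, , "collagen_blue"], tm)
    expect_equal(af_otsu$area_fraction, hs$blue_fraction_true, tolerance = 0.02)
    # fixed threshold at half the generator's blue density
    af_fix <- collagen_area_fraction(dens[, , "collagen_blue"], tm,
                                     threshold = 0.5)
    expect_equal(af_fix$area_fraction, hs$blue_fraction_true, tolerance = 0.02)
  }
})

test_that("calibration matches the closed-form OLS oracle", {
  set.seed(23)
  n <- 8
  hist <- tibble::tibble(
    animal_id = rep(c("N1", "P1"), each = 4),
    organ = rep(organ_levels(), 2),
    area_fraction = runif(n, 0.1, 0.6))
  spa <- tibble::tibble(
    animal_id = hist$animal_id, organ = hist$organ,
    mean_collagen_au = 100 + 800 * hist$area_fraction + rnorm(n, 0, 30))
  fit <- calibrate_histology(spa, hist)
  g <- glance(fit)
  orc <- oracle_ols(hist$area_fraction, spa$mean_collagen_au)
  expect_equal(g$slope, orc$slope, tolerance = 1e-10)
  expect_equal(g$intercept, orc$intercept, tolerance = 1e-10)
  expect_equal(g$r_squared, orc$r2, tolerance = 1e-10)
  expect_equal(g$p_value, orc$p, tolerance = 1e-10)
  expect_equal(g$n, n)
  # true slope within 3 analytic standard errors
  expect_lt(abs(g$slope - 800), 3 * orc$se)
  # textbook identity: r^2 = (Pearson r)^2
  expect_equal(g$r_squared,
               cor(hist$area_fraction, spa$mean_collagen_au)^2,
               tolerance = 1e-12)

  # perfectly linear pairs
  exact <- dplyr::mutate(spa, mean_collagen_au = 50 + 900 * hist$area_fraction)
  expect_equal(suppressWarnings(glance(calibrate_histology(exact, hist)))$r_squared, 1,
               tolerance = 1e-12)
})

test_that("calibration guards sample size and degenerate predictors", {
  hist <- tibble::tibble(animal_id = c("N1", "N1"), organ = c("uterus", "vagina"),
                         area_fraction = c(0.2, 0.4))
  spa <- tibble::tibble(animal_id = hist$animal_id, organ = hist$organ,
                        mean_collagen_au = c(200, 400))
  expect_error(calibrate_histology(spa, hist), class = "spa_sample_size_error")
  hist3 <- tibble::tibble(animal_id = c("N1", "N1", "N1"),
                          organ = organ_levels()[1:3],
                          area_fraction = 0.3)
  spa3 <- tibble::tibble(animal_id = hist3$animal_id, organ = hist3$organ,
                         mean_collagen_au = c(1, 2, 3))
  expect_error(calibrate_histology(spa3, hist3), class = "spa_degenerate_error")
})
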