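test_that("the unpaired t-test matches the closed-form pooled formula", {
  df <- tibble::tibble(
    y = c(5.1, 4.8, 6.0, 5.5, 3.9, 4.2, 3.5, 4.8),
    g = rep(c("a", "b"), each = 4))
  res <- unpaired_ttest(df, "y", "g")
  orc <- oracle_ttest(df$y[df$g == "a"], df$y[df$g == "b"])
  expect_equal(res$t_statistic, orc$t, tolerance = 1e-10)
  expect_equal(res$df, orc$df)
  expect_equal(res$p_value, orc$p, tolerance = 1e-10)

  # identical groups: t = 0, p = 1
  same <- tibble::tibble(y = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  null <- unpaired_ttest(same, "y", "g")
  expect_equal(null$t_statistic, 0)
  expect_equal(null$p_value, 1)

  # p decreases monotonically in the group shift
  ps <- sapply(c(0.5, 1, 2, 4, 8), function(delta) {
    d <- tibble::tibble(y = c(1, 2, 3, 1 + delta, 2 + delta, 3 + delta),
                        g = rep(c("a", "b"), each = 3))
    unpaired_ttest(d, "y", "g")$p_value
  })
  expect_true(all(diff(ps) < 0))

  # swapping groups negates t, leaves p unchanged
  swapped <- dplyr::mutate(df, g = ifelse(g == "a", "b", "a"))
  res2 <- unpaired_ttest(swapped, "y", "g")
  expect_equal(res2$t_statistic, -res$t_statistic)
  expect_equal(res2$p_value, res$p_value)

  # Welch variant differs when variances do
  hetero <- tibble::tibble(y = c(1, 2, 3, 10, 30, 50), g = rep(c("a", "b"), each = 3))
  expect_false(isTRUE(all.equal(
    unpaired_ttest(hetero, "y", "g")$p_value,
    unpaired_ttest(hetero, "y", "g", var_equal = FALSE)$p_value)))
})

test_that("t-test guards degenerate inputs", {
  expect_error(
    unpaired_ttest(tibble::tibble(y = c(1, 2), g = c("a", "b")), "y", "g"),
    class = "spa_sample_size_error")
  expect_error(
    unpaired_ttest(tibble::tibble(y = rep(1, 6), g = rep(c("a", "b"), 3)),
                   "y", "g"),
    class = "spa_degenerate_error")
})

test_that("two-way ANOVA matches a hand-built SS decomposition on balanced data", {
  set.seed(55)
  df <- tidyr::expand_grid(a = c("a1", "a2"), b = c("b1", "b2"), rep = 1:4) |>
    dplyr::mutate(y = 2 + (a == "a2") * 1.5 - (b == "b2") * 0.7 +
                    (a == "a2" & b == "b2") * 0.9 + rnorm(16))
  res <- twoway_anova(df, "y", "a", "b")
  orc <- oracle_balanced_anova(df$y, df$a, df$b)
  got <- res[match(c("a", "b", "a:b"), res$term), ]
  expect_equal(got$sum_sq, unname(orc$ss[c("a", "b", "ab")]), tolerance = 1e-10)
  expect_equal(got$f_statistic, unname(orc$f), tolerance = 1e-10)
  expect_equal(got$p_value, unname(orc$p), tolerance = 1e-10)

  # Types I/II/III coincide for balanced designs
  for (type in c("I", "III")) {
    alt <- twoway_anova(df, "y", "a", "b", ss_type = type)
    alt <- alt[match(c("a", "b", "a:b"), alt$term), ]
    expect_equal(alt$f_statistic, got$f_statistic, tolerance = 1e-10)
    expect_equal(alt$p_value, got$p_value, tolerance = 1e-10)
  }

  # location invariance
  shifted <- twoway_anova(dplyr::mutate(df, y = y + 100), "y", "a", "b")
  expect_equal(shifted$f_statistic, res$f_statistic, tolerance = 1e-9)
})

test_that("one-factor two-level balanced ANOVA reproduces the t-test (F = t^2)", {
  set.seed(66)
  df <- tibble::tibble(y = rnorm(12, rep(c(0, 1), each = 6)),
                       g = rep(c("a", "b"), each = 6))
  tt <- unpaired_ttest(df, "y", "g")
  av <- anova(lm(y ~ g, data = df))  # independent route
  expect_equal(av$`F value`[1], tt$t_statistic^2, tolerance = 1e-10)
  expect_equal(av$`Pr(>F)`[1], tt$p_value, tolerance = 1e-10)
})

test_that("ANOVA guards empty cells and saturated designs", {
  df <- tibble::tibble(a = c("a1", "a1", "a2", "a2"),
                       b = c("b1", "b1", "b1", "b1"),
                       y = 1:4)
  expect_error(twoway_anova(df, "y", "a", "b"), class = "spa_validation_error")
  df2 <- tidyr::expand_grid(a = c("a1", "a2"), b = c("b1", "b2")) |>
    dplyr::mutate(y = rnorm(4))
  expect_error(twoway_anova(df2, "y", "a", "b"), class = "spa_saturation_error")
  df3 <- df2[-1, ]
  expect_error(twoway_anova(df3, "y", "a", "b"), class = "spa_design_error")
})

test_that("age regression matches the OLS oracle and its guards", {
  set.seed(44)
  df <- tibble::tibble(age_months = runif(10, 2, 12),
                       mean_collagen_au = 200 + 40 * runif(10, 2, 12))
  df$mean_collagen_au <- 200 + 40 * df$age_months + rnorm(10, 0, 25)
  res <- age_regression(df)
  orc <- oracle_ols(df$age_months, df$mean_collagen_au)
  expect_equal(res$slope, orc$slope, tolerance = 1e-10)
  expect_equal(res$r_squared, orc$r2, tolerance = 1e-10)
  expect_equal(res$p_value, orc$p, tolerance = 1e-10)

  exact <- tibble::tibble(age_months = 1:5,
                          mean_collagen_au = 100 + 30 * (1:5))
  expect_equal(suppressWarnings(age_regression(exact))$r_squared, 1, tolerance = 1e-12)
  expect_error(age_regression(exact[1:2, ]), class = "spa_sample_size_error")
  flat <- tibble::tibble(age_months = rep(5, 4), mean_collagen_au = rnorm(4))
  expect_error(age_regression(flat), class = "spa_degenerate_error")
})

test_that("slope estimates achieve nominal confidence-interval coverage", {
  # Monte-Carlo oracle: 95% CI coverage over repeated synthetic cohorts
  slope_true <- 40
  covered <- vapply(1:200, function(seed) {
    set.seed(seed + 3000)
    age <- runif(8, 2, 12)
    y <- 200 + slope_true * age + rnorm(8, 0, 70)
    fit <- lm(y ~ age)
    ci <- confint(fit)[2, ]
    ci[1] <= slope_true && slope_true <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("the study bundle is order invariant and symmetric under group swap", {
  # ages drawn inside the matched window so both groups are fully present
  co <- generate_cohort(cohort_spec(age_range_months = c(4, 8), seed = 2))$cohort
  st <- run_study_tables(co)
  shuffled <- run_study_tables(co[sample(nrow(co)), ])
  expect_equal(shuffled$ttests, st$ttests)
  expect_equal(shuffled$age_regressions, st$age_regressions)
  expect_equal(shuffled$anova_prolapse_organ, st$anova_prolapse_organ)

  swapped <- dplyr::mutate(co, prolapse = !prolapse,
                           genotype = ifelse(prolapse, "Fbln5_ko", "Fbln5_het"))
  st2 <- run_study_tables(swapped)
  expect_equal(st2$ttests$t_statistic, -st$ttests$t_statistic, tolerance = 1e-10)
  expect_equal(st2$ttests$p_value, st$ttests$p_value, tolerance = 1e-10)
})

test_that("empty or partial cohorts degrade gracefully", {
  empty <- tibble::tibble(animal_id = character(), genotype = character(),
                          prolapse = logical(), age_months = numeric(),
                          organ = character(), mean_collagen_au = numeric())
  st <- run_study_tables(empty)
  expect_equal(st$notes, "empty cohort")
  expect_equal(nrow(st$ttests), 0L)

  partial <- generate_cohort(cohort_spec(seed = 4))$cohort |>
    dplyr::filter(organ != "vagina")
  st2 <- run_study_tables(partial)
  expect_false("vagina" %in% st2$ttests$organ)
  expect_true(any(grepl("vagina", st2$notes)))
})

test_that("an injected external-os deficit is detected organ-specifically", {
  # power simulation at the configured effect size: age-matched design,
  # 4 animals per group
  hits <- matrix(NA, 200, 4, dimnames = list(NULL, organ_levels()))
  for (r in 1:200) {
    co <- generate_cohort(cohort_spec(
      n_per_group = 4, age_range_months = c(4, 8), seed = 20000 + r))$cohort
    tt <- run_study_tables(co)$ttests
    hits[r, tt$organ] <- tt$p_value < 0.05
  }
  expect_gte(mean(hits[, "external_os"]), 0.90)
  for (org in c("uterus", "internal_os", "vagina")) {
    expect_lte(mean(hits[, org]), 0.10)
  }
})
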