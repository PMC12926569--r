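# Cohort-level statistics: unpaired t-tests per organ, two-way ANOVAs and
# age regressions.
#
# The study design these serve: two genotype groups (normal carriers vs
# knockouts that develop prolapse), four organ cross-sections per animal,
# one mean collagen estimate (a.u.) per animal x organ. Group comparisons
# use the age-matched slice (4-8 months); age regressions use the full
# cohort, split by group. Raw p-values are reported per organ (no
# multiple-testing correction by default, Holm optionally).

#' Validate a cohort table
#'
#' @param cohort A data frame with columns `animal_id`, `genotype`,
#'   `prolapse` (logical), `age_months` in `(0, 12]`, `organ`,
#'   `mean_collagen_au` (>= 0); one record per animal x organ.
#' @return The cohort, invisibly, or an error.
#' @export
validate_cohort <- function(cohort) {
  needed <- c("animal_id", "genotype", "prolapse", "age_months", "organ",
              "mean_collagen_au")
  miss <- setdiff(needed, names(cohort))
  if (length(miss) > 0L) {
    spa_abort(sprintf("Cohort is missing column(s): %s.", paste(miss, collapse = ", ")),
              "spa_validation_error")
  }
  if (nrow(cohort) > 0L) {
    if (any(cohort$age_months <= 0 | cohort$age_months > 12)) {
      spa_abort("Ages must lie in (0, 12] months.", "spa_validation_error")
    }
    if (any(cohort$mean_collagen_au < 0)) {
      spa_abort("Mean collagen values must be >= 0.", "spa_validation_error")
    }
    if (anyDuplicated(cohort[, c("animal_id", "organ")])) {
      spa_abort("Cohort must have one record per animal x organ.",
                "spa_validation_error")
    }
  }
  invisible(cohort)
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance unpaired t-test by default (the generic
#' "unpaired t-test"); Welch's unequal-variance form by flag.
#'
#' @param data A data frame.
#' @param response Name of the numeric response column.
#' @param group Name of the two-level grouping column.
#' @param var_equal Pooled-variance Student's test (default `TRUE`); `FALSE`
#'   gives Welch's test.
#' @return A one-row tibble: group labels, means, sizes, `t_statistic`,
#'   `df`, `p_value` (two-sided).
#' @export
unpaired_ttest <- function(data, response, group, var_equal = TRUE) {
  g <- data[[group]]
  y <- data[[response]]
  # deterministic orientation: factor order if declared, else sorted labels
  levels <- if (is.factor(g)) levels(droplevels(g)) else sort(unique(g))
  if (length(levels) != 2L) {
    spa_abort(sprintf("`%s` must have exactly 2 levels, got %d.",
                      group, length(levels)),
              "spa_validation_error")
  }
  ya <- y[g == levels[1]]
  yb <- y[g == levels[2]]
  if (length(ya) < 2L || length(yb) < 2L) {
    spa_abort("Each group needs at least 2 observations.", "spa_sample_size_error")
  }
  if (stats::var(ya) + stats::var(yb) == 0) {
    spa_abort("Zero variance in both groups; t-test is degenerate.",
              "spa_degenerate_error")
  }
  ht <- stats::t.test(ya, yb, var.equal = var_equal)
  tibble::tibble(
    group_a = as.character(levels[1]), group_b = as.character(levels[2]),
    mean_a = mean(ya), mean_b = mean(yb),
    n_a = length(ya), n_b = length(yb),
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    variant = if (var_equal) "student" else "welch")
}

#' Two-way ANOVA
#'
#' Fits `response ~ a * b` and reports the F test for each factor and the
#' interaction. Sums of squares are Type II by default (for the balanced
#' designs this package targets, Types I/II/III coincide); either factor may
#' also be a continuous covariate, giving an ANCOVA-style table.
#'
#' @param data A data frame.
#' @param response,factor_a,factor_b Column names.
#' @param ss_type `"II"` (default), `"I"` or `"III"`.
#' @return A tibble with one row per term: `term`, `df`, `sum_sq`,
#'   `f_statistic`, `p_value`, plus `ss_type`.
#' @export
twoway_anova <- function(data, response, factor_a, factor_b, ss_type = "II") {
  for (fac in c(factor_a, factor_b)) {
    v <- data[[fac]]
    if (!is.numeric(v) && length(unique(v)) < 2L) {
      spa_abort(sprintf("Factor `%s` needs at least 2 levels.", fac),
                "spa_validation_error")
    }
  }
  # empty-cell check only applies when both are categorical
  va <- data[[factor_a]]; vb <- data[[factor_b]]
  if (!is.numeric(va) && !is.numeric(vb)) {
    if (any(table(va, vb) == 0L)) {
      spa_abort("Design has empty cells; the interaction is not estimable.",
                "spa_design_error")
    }
  }
  fml <- stats::reformulate(sprintf("%s * %s", factor_a, factor_b),
                            response = response)
  # Type III tests are only meaningful (and only coincide with I/II on
  # balanced data) under sum-to-zero contrasts
  contr <- NULL
  if (ss_type == "III") {
    cats <- c(factor_a, factor_b)[!vapply(data[c(factor_a, factor_b)],
                                          is.numeric, logical(1))]
    if (length(cats) > 0L) {
      data <- dplyr::mutate(data, dplyr::across(dplyr::all_of(cats), as.factor))
      contr <- stats::setNames(as.list(rep("contr.sum", length(cats))), cats)
    }
  }
  fit <- stats::lm(fml, data = data, contrasts = contr)
  if (stats::df.residual(fit) < 1L) {
    spa_abort("Residual degrees of freedom is 0; the design is saturated.",
              "spa_saturation_error")
  }
  tab <- if (ss_type == "I") {
    a <- stats::anova(fit)
    data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
               f_statistic = a$`F value`, p_value = a$`Pr(>F)`)
  } else {
    a <- car::Anova(fit, type = ss_type)
    data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
               f_statistic = a$`F value`, p_value = a$`Pr(>F)`)
  }
  tab <- tab[tab$term != "(Intercept)", ]
  tibble::as_tibble(tab) |>
    dplyr::mutate(ss_type = ss_type)
}

#' Age regression of collagen estimates
#'
#' Ordinary least squares of the mean collagen estimate on age, with the
#' coefficient of determination and the two-sided slope p-value
#' (t distribution, n - 2 df).
#'
#' @param data A data frame (typically one organ x group cohort slice).
#' @param response Response column (default `"mean_collagen_au"`).
#' @param age Age column (default `"age_months"`).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
age_regression <- function(data, response = "mean_collagen_au",
                           age = "age_months") {
  n <- nrow(data)
  if (n < 3L) {
    spa_abort(sprintf("Regression needs at least 3 points, got %d.", n),
              "spa_sample_size_error")
  }
  if (stats::var(data[[age]]) == 0) {
    spa_abort("Zero variance in age; regression is degenerate.",
              "spa_degenerate_error")
  }
  fml <- stats::reformulate(age, response = response)
  fit <- stats::lm(fml, data = data)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = if (nrow(sm$coefficients) > 1L) sm$coefficients[2, 4] else NA_real_,
    n = n)
}

#' Run the full study analysis bundle
#'
#' For a cohort table, computes per organ: the normal-vs-prolapsed unpaired
#' t-test on the age-matched slice; per-group (and optionally pooled) age
#' regressions over the full cohort; and the two-way ANOVAs: prolapse x
#' anatomical position on the age-matched slice, and the two age ANOVAs (age
#' with prolapse, age with anatomical position), with age treated as a
#' continuous covariate by default or binned into a factor.
#'
#' @param cohort A validated cohort table (see [validate_cohort()]).
#' @param age_match Inclusive age window in months for the age-matched
#'   group-comparison slice (default `c(4, 8)`).
#' @param age_mode Treat age as `"continuous"` (ANCOVA-style, default) or
#'   `"binned"` (median-split factor) in the age ANOVAs.
#' @param split_groups Fit age regressions per group (default `TRUE`);
#'   `FALSE` pools both groups.
#' @param holm Apply Holm correction across the per-organ t-tests (default
#'   `FALSE`, matching per-organ raw p-value reporting).
#' @return A list of class `spa_study_tables` with tibbles `ttests`,
#'   `age_regressions`, `anova_prolapse_organ`, `anova_age_prolapse`,
#'   `anova_age_organ` and a character vector `notes`.
#' @export
run_study_tables <- function(cohort, age_match = c(4, 8),
                             age_mode = c("continuous", "binned"),
                             split_groups = TRUE, holm = FALSE) {
  age_mode <- match.arg(age_mode)
  validate_cohort(cohort)
  notes <- character()
  empty_t <- tibble::tibble()
  if (nrow(cohort) == 0L) {
    return(structure(
      list(ttests = empty_t, age_regressions = empty_t,
           anova_prolapse_organ = empty_t, anova_age_prolapse = empty_t,
           anova_age_organ = empty_t, notes = "empty cohort"),
      class = "spa_study_tables"))
  }
  cohort <- dplyr::mutate(cohort, group = ifelse(.data$prolapse, "prolapsed", "normal"))
  matched <- dplyr::filter(cohort, .data$age_months >= age_match[1],
                           .data$age_months <= age_match[2])

  ttests <- purrr::map(organ_levels(), function(org) {
    slice <- dplyr::filter(matched, .data$organ == org)
    if (nrow(slice) == 0L) {
      notes <<- c(notes, sprintf("no age-matched records for organ '%s'", org))
      return(NULL)
    }
    res <- tryCatch(
      unpaired_ttest(slice, "mean_collagen_au", "group"),
      spacollagen_error = function(e) {
        notes <<- c(notes, sprintf("t-test skipped for organ '%s': %s",
                                   org, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) dplyr::mutate(res, organ = org, .before = 1) else NULL
  }) |> purrr::compact() |> dplyr::bind_rows()
  if (holm && nrow(ttests) > 0L) {
    ttests <- dplyr::mutate(ttests, p_holm = stats::p.adjust(.data$p_value, "holm"))
  }

  groups <- if (split_groups) sort(unique(cohort$group)) else "pooled"
  regs <- tidyr::expand_grid(organ = organ_levels(), group = groups) |>
    purrr::pmap(function(organ, group) {
      slice <- if (identical(group, "pooled")) {
        cohort[cohort$organ == organ, ]
      } else {
        cohort[cohort$organ == organ & cohort$group == group, ]
      }
      if (nrow(slice) == 0L) {
        notes <<- c(notes, sprintf("no records for organ '%s' group '%s'",
                                   organ, group))
        return(NULL)
      }
      res <- tryCatch(
        age_regression(slice),
        spacollagen_error = function(e) {
          notes <<- c(notes, sprintf("regression skipped for '%s'/'%s': %s",
                                     organ, group, conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) {
        dplyr::bind_cols(tibble::tibble(organ = organ, group = group), res)
      } else NULL
    }) |> purrr::compact() |> dplyr::bind_rows()

  safe_anova <- function(data, fa, fb, label) {
    tryCatch(
      twoway_anova(data, "mean_collagen_au", fa, fb),
      spacollagen_error = function(e) {
        notes <<- c(notes, sprintf("ANOVA '%s' skipped: %s", label,
                                   conditionMessage(e)))
        empty_t
      })
  }
  aov_po <- safe_anova(matched, "group", "organ", "prolapse x organ")
  age_data <- cohort
  if (age_mode == "binned") {
    age_data <- dplyr::mutate(
      age_data,
      age_bin = ifelse(.data$age_months <= stats::median(.data$age_months),
                       "younger", "older"))
    aov_ap <- safe_anova(age_data, "age_bin", "group", "age x prolapse")
    aov_ao <- safe_anova(age_data, "age_bin", "organ", "age x organ")
  } else {
    aov_ap <- safe_anova(age_data, "age_months", "group", "age x prolapse")
    aov_ao <- safe_anova(age_data, "age_months", "organ", "age x organ")
  }

  structure(
    list(ttests = ttests, age_regressions = regs,
         anova_prolapse_organ = aov_po, anova_age_prolapse = aov_ap,
         anova_age_organ = aov_ao, notes = notes),
    class = "spa_study_tables")
}

#' @export
print.spa_study_tables <- function(x, ...) {
  cat("<spa_study_tables>\n")
  cat("Per-organ unpaired t-tests (age-matched slice):\n")
  print(x$ttests)
  cat("\nAge regressions:\n")
  print(x$age_regressions)
  cat("\nTwo-way ANOVA, prolapse x anatomical position:\n")
  print(x$anova_prolapse_organ)
  if (length(x$notes) > 0L) {
    cat("\nNotes:\n")
    cat(paste0("  - ", x$notes, collapse = "\n"), "\n")
  }
  invisible(x)
}
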