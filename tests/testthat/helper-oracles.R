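# Shared fixtures and independent oracles. Oracles are deliberately written
# with different algorithms than the implementation they check (brute-force
# grids, closed-form textbook formulas, third-party point-in-polygon).

# cached packaged design matrix
spa_test_design <- local({
  A <- NULL
  function() {
    if (is.null(A)) {
      A <<- build_design_matrix(minmax_normalize(load_reference_spectra()))
    }
    A
  }
})

# brute-force scale-free grid search over the concentration simplex:
# minimizes ||k * A c - y|| over directions c (simplex grid) and k >= 0
# (closed form), coarse grid then local refinement at `fine` resolution
simplex_grid <- function(step) {
  N <- round(1 / step)
  ij <- expand.grid(i = 0:N, j = 0:N)
  ij <- ij[ij$i + ij$j <= N, ]
  cbind(ij$i, ij$j, N - ij$i - ij$j) / N
}

oracle_unmix <- function(A, y, coarse = 0.01, fine = 0.001) {
  res2 <- function(G) {
    AG <- A %*% t(G)
    num <- pmax(colSums(AG * y), 0)
    sum(y^2) - num^2 / colSums(AG^2)
  }
  local_grid <- function(c0, halo, step) {
    d <- seq(-halo, halo, by = step)
    loc <- expand.grid(d1 = d, d2 = d)
    G <- cbind(c0[1] + loc$d1, c0[2] + loc$d2, c0[3] - loc$d1 - loc$d2)
    G[G[, 1] >= 0 & G[, 2] >= 0 & G[, 3] >= 0, , drop = FALSE]
  }
  # coarse sweep of the whole simplex, then staged local refinement down to
  # the fine resolution (the least-squares valley is elongated, so halos are
  # generous relative to the previous step)
  G <- simplex_grid(coarse)
  c0 <- G[which.min(res2(G)), ]
  G <- local_grid(c0, halo = 0.04, step = 0.004)
  c0 <- G[which.min(res2(G)), ]
  G <- local_grid(c0, halo = 0.012, step = fine)
  rf <- res2(G)
  list(c = unname(G[which.min(rf), ]), resid2 = min(rf))
}

# scale-free residual of a given direction (for comparing solver vs oracle)
direction_resid2 <- function(A, c_dir, y) {
  v <- as.vector(A %*% c_dir)
  sum(y^2) - max(sum(v * y), 0)^2 / sum(v^2)
}

# closed-form pooled-variance two-sample t-test
oracle_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# closed-form simple OLS with slope t-test
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  se <- sqrt(sse / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept, r2 = 1 - sse / sst,
       se = se, p = 2 * pt(-abs(t), n - 2))
}

# hand-built sums-of-squares decomposition for a balanced two-way layout
oracle_balanced_anova <- function(y, a, b) {
  n <- length(y)
  gm <- mean(y)
  na <- tapply(y, a, length); nb <- tapply(y, b, length)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  reps <- n / (length(ma) * length(mb))
  ss_a <- sum(na * (ma - gm)^2)
  ss_b <- sum(nb * (mb - gm)^2)
  cell_dev <- outer(ma - gm, mb - gm, "+") + gm
  ss_ab <- reps * sum((mab - cell_dev)^2)
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_a - ss_b - ss_ab
  df_a <- length(ma) - 1; df_b <- length(mb) - 1
  df_ab <- df_a * df_b
  df_res <- n - length(ma) * length(mb)
  f <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / (ss_res / df_res)
  p <- pf(f, c(df_a, df_b, df_ab), df_res, lower.tail = FALSE)
  list(ss = c(a = ss_a, b = ss_b, ab = ss_ab, res = ss_res),
       f = f, p = p)
}

# small end-to-end phantom runner
run_phantom_pipeline <- function(spec, design = spa_test_design(),
                                 solver = "ols-clip") {
  ph <- generate_phantom(spec, design)
  fl <- mean_fluence(ph$pulses, ph$stack$config)
  norm <- fluence_normalize(ph$stack, fl)
  conc <- unmix_stack(norm, design, solver = solver)
  list(phantom = ph, conc = conc)
}
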