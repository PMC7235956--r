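# Independent brute-force oracles. These deliberately use naive loops and
# lm()/cor() so they share no code path with the package implementation.

# Per-edge Pearson correlation and two-sided t p-value, one cor.test per edge.
oracle_edge_corr <- function(edges, behavior) {
  r <- numeric(ncol(edges))
  p <- numeric(ncol(edges))
  for (e in seq_len(ncol(edges))) {
    ct <- stats::cor.test(edges[, e], behavior)
    r[e] <- unname(ct$estimate)
    p[e] <- ct$p.value
  }
  list(r = r, p = p)
}

# Partial correlation by explicit residualization: regress each member of the
# pair on all remaining columns (with intercept) and correlate the residuals.
oracle_partial_corr <- function(ts) {
  K <- ncol(ts)
  P <- diag(0, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      others <- ts[, -c(i, j), drop = FALSE]
      ri <- if (ncol(others)) stats::resid(stats::lm(ts[, i] ~ others)) else ts[, i]
      rj <- if (ncol(others)) stats::resid(stats::lm(ts[, j] ~ others)) else ts[, j]
      P[i, j] <- P[j, i] <- stats::cor(ri, rj)
    }
  }
  P
}

# Residualize-then-correlate oracle for covariate-adjusted edge correlation.
oracle_adjusted_corr <- function(edges, behavior, covariates) {
  yr <- stats::resid(stats::lm(behavior ~ covariates))
  vapply(seq_len(ncol(edges)), function(e) {
    stats::cor(stats::resid(stats::lm(edges[, e] ~ covariates)), yr)
  }, numeric(1))
}

# Closed-form simple OLS.
oracle_ols <- function(x, y) {
  slope <- stats::cov(x, y) / stats::var(x)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Node degree via the adjacency-matrix row-sum identity.
oracle_degree <- function(mask, K) {
  A <- cpmr::edge_matrix(as.numeric(mask), K)
  as.integer(rowSums(A))
}

# Small planted-signal dataset used by several tests.
make_planted <- function(n = 120, K = 20, n_pos = 10, n_neg = 10, beta = 0.5,
                         families = 3, seed = 1) {
  coh <- simulate_cohort(n, family_sizes = rep(families, n / families), seed = seed)
  sim <- simulate_edges(coh, K, n_pos, n_neg, beta = beta, seed = seed)
  list(cohort = coh, edges = sim$edges, truth = sim$truth)
}
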