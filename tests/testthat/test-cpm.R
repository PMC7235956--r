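test_that("edge-behavior correlation matches the brute-force oracle", {
  set.seed(7)
  # hand-enterable n = 5 toy
  edges5 <- cbind(c(1, 2, 3, 4, 5), c(2, 1, 3, 5, 4), c(5, 4, 3, 2, 1))
  y5 <- c(10, 12, 11, 15, 14)
  ce <- correlate_edges(edges5, y5)
  or <- oracle_edge_corr(edges5, y5)
  expect_equal(ce$r, or$r, tolerance = 1e-12)
  expect_equal(ce$p, or$p, tolerance = 1e-12)

  # randomized instances
  for (i in 1:3) {
    edges <- matrix(rnorm(30 * 25), 30, 25)
    y <- rnorm(30)
    ce <- correlate_edges(edges, y)
    or <- oracle_edge_corr(edges, y)
    expect_equal(ce$r, or$r, tolerance = 1e-10)
    expect_equal(ce$p, or$p, tolerance = 1e-10)
  }

  # an edge equal to behavior correlates perfectly
  edges <- cbind(y5, rnorm(5))
  expect_equal(correlate_edges(edges, y5)$r[1], 1)

  # zero-variance edges give NA and are never selected
  ce0 <- correlate_edges(cbind(rep(2, 10), rnorm(10)), rnorm(10))
  expect_true(is.na(ce0$r[1]))
  sel <- select_edges(ce0$r, ce0$p, 0.5)
  expect_false(sel$positive[1] || sel$negative[1])

  expect_error(correlate_edges(matrix(rnorm(20), 10), rep(1, 10)), "constant")
  expect_error(correlate_edges(matrix(rnorm(6), 3), rnorm(3)), "at least 4")
})

test_that("covariate-adjusted correlation is a residual correlation", {
  set.seed(8)
  n <- 80
  covs <- cbind(age = rnorm(n), motion = rnorm(n))
  y <- rnorm(n)
  edges <- matrix(rnorm(n * 10), n, 10)

  # residualize-then-correlate oracle
  adj <- correlate_edges(edges, y, covs)
  expect_equal(adj$r, oracle_adjusted_corr(edges, y, covs), tolerance = 1e-10)
  expect_equal(adj$df, n - 2 - 2)

  # covariates orthogonal to both edge and behavior leave r unchanged
  q <- qr(cbind(1, y, edges))
  ortho <- qr.resid(q, covs)  # exactly orthogonal to y, all edges, intercept
  plain <- correlate_edges(edges, y)
  adj0 <- correlate_edges(edges, y, ortho)
  expect_equal(adj0$r, plain$r, tolerance = 1e-10)

  # zero covariate columns reduce exactly to the unadjusted estimator
  none <- correlate_edges(edges, y, matrix(numeric(0), n, 0))
  expect_equal(none$r, plain$r)
  expect_equal(none$df, plain$df)

  # behavior fully explained by a covariate: degenerate residual
  expect_error(correlate_edges(edges, y, cbind(y)), "constant after covariate")
  # rank-deficient covariates
  expect_error(correlate_edges(edges, y, cbind(a = covs[, 1], b = covs[, 1])),
               "rank deficient")
})

test_that("adjustment removes a planted confound", {
  set.seed(9)
  n <- 150
  conf <- rnorm(n)
  y <- 2 * conf + 0.1 * rnorm(n)
  edges <- cbind(conf + 0.1 * rnorm(n), rnorm(n))
  plain <- correlate_edges(edges, y)
  adj <- correlate_edges(edges, y, cbind(conf))
  expect_gt(abs(plain$r[1]), 0.9)
  expect_lt(abs(adj$r[1]), 0.2)
  expect_equal(adj$r, oracle_adjusted_corr(edges, y, cbind(conf)), tolerance = 1e-10)
})

test_that("edge selection splits tails by sign at the threshold", {
  sel <- select_edges(r = c(0.3, -0.4, 0.1), p = c(0.005, 0.001, 0.5),
                      threshold = 0.01)
  expect_equal(which(sel$positive), 1L)
  expect_equal(which(sel$negative), 2L)
  expect_error(select_edges(0.1, 0.1, 1.0), "between 0 and 1")
  tiny <- select_edges(r = runif(50, -1, 1), p = runif(50), threshold = 1e-12)
  expect_equal(sum(tiny$positive) + sum(tiny$negative), 0)
  set.seed(10)
  for (i in 1:5) {
    r <- runif(200, -1, 1); p <- runif(200)
    s <- select_edges(r, p, 0.2)
    expect_false(any(s$positive & s$negative))
    expect_true(all(r[s$positive] > 0 & p[s$positive] < 0.2))
    expect_true(all(r[s$negative] < 0 & p[s$negative] < 0.2))
  }
})

test_that("summary scores sum masked weights linearly", {
  v <- c(0.2, 0.3, -0.1, 0.4)
  mask <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(summary_score(v, mask), 0.5)
  expect_equal(summary_score(v, rep(FALSE, 4)), 0)
  v2 <- c(1, -1, 2, 0.5)
  expect_equal(summary_score(v + v2, mask),
               summary_score(v, mask) + summary_score(v2, mask))
  m <- rbind(v, v2)
  expect_equal(unname(summary_score(m, mask)), c(0.5, 0))
})

test_that("per-tail linear model is exact OLS with a degenerate fallback", {
  # exact linear relationship
  s <- c(1, 2, 3, 4, 5)
  m <- cpmr:::fit_tail_model(s, 2 * s + 1, "positive")
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 1)
  expect_false(m$degenerate)

  # constant scores: intercept-only fallback
  d <- cpmr:::fit_tail_model(rep(0, 6), c(1, 2, 3, 4, 5, 6), "positive")
  expect_true(d$degenerate)
  expect_equal(d$slope, 0)
  expect_equal(d$intercept, 3.5)

  # random toy against the closed-form oracle
  set.seed(11)
  x <- rnorm(6); y <- rnorm(6)
  m2 <- cpmr:::fit_tail_model(x, y, "negative")
  or <- oracle_ols(x, y)
  expect_equal(m2$slope, unname(or["slope"]), tolerance = 1e-12)
  expect_equal(m2$intercept, unname(or["intercept"]), tolerance = 1e-12)
  # residuals orthogonal to scores
  res <- y - (m2$intercept + m2$slope * x)
  expect_lt(abs(sum(res * x)), 1e-10)
})

test_that("cpm fit recovers planted signal and predicts linearly", {
  d <- make_planted(n = 120, K = 20, beta = 0.8, seed = 13)
  fit <- cpm(d$edges, d$cohort$behavior, threshold = 0.01)
  expect_s3_class(fit, "cpm")
  # positive tail slope positive, negative tail slope negative
  expect_gt(fit$models$positive$slope, 0)
  expect_lt(fit$models$negative$slope, 0)
  # selected positive edges overlap the planted ones
  expect_gt(sum(which(fit$selection$positive) %in% d$truth$positive_edges), 0)

  # predict() reproduces OLS fitted values on the training data
  pr <- predict(fit)
  s <- fit$scores[, "positive"]
  or <- oracle_ols(s, d$cohort$behavior)
  expect_equal(unname(pr[, "positive"]),
               unname(or["intercept"] + or["slope"] * s),
               tolerance = 1e-10)
  co <- coef(fit)
  expect_equal(dim(co), c(2, 2))
  expect_equal(unname(co["positive", "slope"]), fit$models$positive$slope)
  expect_output(print(fit), "Connectome-based")
  expect_output(print(summary(fit)), "positive network")
})
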