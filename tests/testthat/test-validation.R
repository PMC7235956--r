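test_that("family folds form a leakage-free partition", {
  fp <- family_folds(c("A", "A", "B"))
  expect_length(fp, 2)
  expect_equal(fp[[1]]$train, 3L)
  expect_equal(fp[[1]]$test, c(1L, 2L))

  # singleton families reduce to leave-one-subject-out
  fp1 <- family_folds(as.character(1:7))
  expect_length(fp1, 7)
  expect_equal(sort(unlist(lapply(fp1, `[[`, "test"))), 1:7)

  set.seed(20)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    fams <- sample(letters[1:6], n, replace = TRUE)
    while (length(unique(fams)) < 2) fams <- sample(letters[1:6], n, replace = TRUE)
    fp <- family_folds(fams)
    tests <- lapply(fp, `[[`, "test")
    expect_equal(sort(unlist(tests)), seq_len(n))            # partition
    expect_equal(sum(lengths(tests)), n)                     # disjoint
    for (f in fp) {                                          # no straddling
      expect_length(intersect(fams[f$train], fams[f$test]), 0)
    }
  }
  expect_error(family_folds(rep("A", 5)), "at least 2 families")
  expect_error(family_folds(c("A", NA)), "family label")
})

test_that("noiseless linear behavior is predicted perfectly", {
  set.seed(42)
  n <- 30
  y <- rnorm(n, 32, 6)
  # behavior is an exact linear function of three fixed edges (and their
  # negatives); remaining edges are constant, hence never selectable
  edges <- cbind(0.5 * y, 0.3 * y, 0.2 * y,
                 -0.5 * y, -0.3 * y, -0.2 * y,
                 matrix(1.7, n, 3))
  fam <- rep(1:10, each = 3)
  cv <- cpm_cv(edges, y, fam, threshold = 0.01)
  expect_lt(abs(cv$r[["positive"]] - 1), 1e-10)
  expect_lt(abs(cv$r[["negative"]] - 1), 1e-10)
  expect_equal(unname(cv$predictions[, "positive"]), y, tolerance = 1e-10)

  pt <- cpm_permtest(edges, y, fam, threshold = 0.01, n_perm = 100, seed = 1)
  expect_equal(unname(pt$p), c(0, 0))  # minimum achievable under the count/m rule
  pts <- cpm_permtest(edges, y, fam, threshold = 0.01, n_perm = 100, seed = 1,
                      smooth = TRUE)
  expect_equal(unname(pts$p),
               unname((colSums(sweep(pts$null_r, 2, pts$r_true, ">="),
                               na.rm = TRUE) + 1) /
                      (colSums(!is.na(pts$null_r)) + 1)))
})

test_that("predictions are family-clean and evaluated per subject", {
  d <- make_planted(n = 60, K = 10, n_pos = 5, n_neg = 5, beta = 0.6, seed = 17)
  cv <- cpm_cv(d$edges, d$cohort$behavior, d$cohort$family_id)
  expect_false(anyNA(cv$predictions))       # every subject predicted once
  expect_equal(nrow(cv$predictions), 60)
  expect_equal(nrow(cv$fold_info), length(unique(d$cohort$family_id)))
  expect_output(print(cv), "cross-validation")
  expect_output(print(summary(cv)), "positive tail")
})

test_that("prediction evaluation is the plain Pearson correlation", {
  y <- c(3, 1, 4, 1, 5)
  expect_equal(evaluate_predictions(y, y), 1)
  expect_equal(evaluate_predictions(y, -y), -1)
  p <- c(2, 7, 1, 8, 2)
  expect_equal(evaluate_predictions(y, p), cor(y, p), tolerance = 1e-12)
  expect_true(is.na(evaluate_predictions(y, rep(2, 5))))
  expect_error(evaluate_predictions(y, 1:3), "mismatch")
})

test_that("the vectorized permutation engine equals the per-shuffle loop", {
  d <- make_planted(n = 45, K = 12, n_pos = 6, n_neg = 6, beta = 0.4, seed = 23)
  cache <- cpmr:::cv_prepare(d$edges, d$cohort$family_id)
  set.seed(99)
  Y <- vapply(1:6, function(i) sample(d$cohort$behavior), numeric(45))
  multi <- cpmr:::cv_run_multi(cache, Y, 0.01)
  single <- t(vapply(1:6, function(j) cpmr:::cv_run(cache, Y[, j], 0.01)$r,
                     numeric(2)))
  expect_equal(unname(multi), unname(single), tolerance = 1e-12)

  # with covariates too
  covs <- cbind(d$cohort$age, d$cohort$motion)
  cache2 <- cpmr:::cv_prepare(d$edges, d$cohort$family_id, covs)
  multi2 <- cpmr:::cv_run_multi(cache2, Y, 0.05)
  single2 <- t(vapply(1:6, function(j) cpmr:::cv_run(cache2, Y[, j], 0.05)$r,
                      numeric(2)))
  expect_equal(unname(multi2), unname(single2), tolerance = 1e-12)
})

test_that("permutation p follows the greater-or-equal counting rule", {
  d <- make_planted(n = 45, K = 12, n_pos = 8, n_neg = 8, beta = 0.7, seed = 29)
  pt <- cpm_permtest(d$edges, d$cohort$behavior, d$cohort$family_id,
                     n_perm = 80, seed = 5)
  for (tl in c("positive", "negative")) {
    nv <- pt$null_r[, tl]
    nv <- nv[!is.na(nv)]
    expect_equal(pt$p[[tl]], sum(nv >= pt$r_true[[tl]]) / length(nv))
  }
  # reproducible given the seed
  pt2 <- cpm_permtest(d$edges, d$cohort$behavior, d$cohort$family_id,
                      n_perm = 80, seed = 5)
  expect_identical(pt$null_r, pt2$null_r)
})

test_that("permutation p is stable in m and invariant to subject relabeling", {
  coh <- simulate_cohort(60, family_sizes = rep(3, 20), seed = 33)
  sim <- simulate_edges(coh, 12, 4, 4, beta = 0.25, seed = 33)
  p1 <- cpm_permtest(sim$edges, coh$behavior, coh$family_id,
                     n_perm = 300, seed = 101)$p
  p2 <- cpm_permtest(sim$edges, coh$behavior, coh$family_id,
                     n_perm = 300, seed = 202)$p
  expect_lt(max(abs(p1 - p2), na.rm = TRUE), 3 / sqrt(300))

  # relabeling subjects (consistent row permutation) preserves r_true
  ord <- sample(60)
  pt_a <- cpm_permtest(sim$edges, coh$behavior, coh$family_id,
                       n_perm = 50, seed = 7)
  pt_b <- cpm_permtest(sim$edges[ord, ], coh$behavior[ord], coh$family_id[ord],
                       n_perm = 50, seed = 7)
  expect_equal(pt_a$r_true, pt_b$r_true, tolerance = 1e-10)
})

test_that("null cross-validated correlations center near zero", {
  # config chosen so folds select edges routinely: with (nearly) no selected
  # edges, intercept-only predictions anti-correlate with the left-out scores
  # and the null CV r drifts negative — a known property of CV correlations
  # that the permutation test accounts for.
  rs <- vapply(1:40, function(i) {
    coh <- simulate_cohort(100, n_families = 50, seed = 700 + i)
    sim <- simulate_edges(coh, 30, 0, 0, beta = 0, seed = 700 + i)
    cpm_cv(sim$edges, coh$behavior, coh$family_id, threshold = 0.05)$r
  }, numeric(2))
  m <- rowMeans(rs, na.rm = TRUE)
  expect_lt(abs(m[1]), 0.1)
  expect_lt(abs(m[2]), 0.1)
  # sign test: neither sign should dominate
  for (tl in 1:2) {
    x <- rs[tl, !is.na(rs[tl, ])]
    bt <- binom.test(sum(x > 0), length(x))
    expect_gt(bt$p.value, 0.01)
  }
})

test_that("constant behavior within a training fold is a hard error", {
  edges <- matrix(rnorm(40), 10, 4)
  y <- c(rep(1, 8), 2, 3)
  fam <- c(rep("a", 4), rep("b", 4), "c", "c")
  # leaving out family c makes the training behavior constant
  expect_error(cpm_cv(edges, y, fam), "constant within a training fold")
})
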