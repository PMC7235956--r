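#' Leave-one-family-out fold plan
#'
#' One fold per distinct family: its members form the test set and everyone
#' else the training set, so no family ever straddles the train/test split
#' and every subject is predicted exactly once.
#'
#' @param family_ids length-`n` family labels (character or factor).
#' @return object of class `"fold_plan"`: list of folds, each with
#'   `family`, `train` and `test` index vectors.
#' @export
family_folds <- function(family_ids) {
  if (anyNA(family_ids)) stop("every subject needs a family label", call. = FALSE)
  fams <- unique(as.character(family_ids))
  if (length(fams) < 2L) {
    stop("cross-validation needs at least 2 families (one family leaves no training data)",
         call. = FALSE)
  }
  idx <- seq_along(family_ids)
  folds <- lapply(fams, function(f) {
    te <- idx[family_ids == f]
    list(family = f, train = idx[-te], test = te)
  })
  structure(folds, class = "fold_plan", n = length(family_ids))
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x, function(f) length(f$test), integer(1))
  cat(sprintf("Leave-one-family-out plan: %d folds over %d subjects (test sizes %d-%d)\n",
              length(x), attr(x, "n"), min(sizes), max(sizes)))
  invisible(x)
}

# Precompute per-fold quantities that do not depend on the behavior vector:
# covariate QR, residualized + column-standardized training edges (for the
# selection correlations) and the raw train/test edges (for summary scores).
# Permutation testing reuses this cache, so only the O(n*E) correlation
# crossproduct is repeated per shuffle.
cv_prepare <- function(edges, family_ids, covariates = NULL) {
  edges <- as_edge_matrix_input(edges)
  n <- nrow(edges)
  if (length(family_ids) != n) stop("'family_ids' length must match subjects", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != n) stop("'covariates' rows must match subjects", call. = FALSE)
  }
  folds <- family_folds(family_ids)
  prep <- lapply(folds, function(f) {
    tr <- f$train
    Etr <- edges[tr, , drop = FALSE]
    q <- NULL
    Esel <- Etr
    nc <- 0L
    if (!is.null(covariates)) {
      X <- cbind(1, covariates[tr, , drop = FALSE])
      q <- qr(X)
      if (q$rank < ncol(X)) {
        stop(sprintf("covariates rank deficient in fold for family %s", f$family),
             call. = FALSE)
      }
      nc <- ncol(X) - 1L
      Esel <- qr.resid(q, Etr)
    }
    ntr <- length(tr)
    if (ntr < max(4L, nc + 4L)) {
      stop(sprintf("training set for family %s too small (%d subjects)", f$family, ntr),
           call. = FALSE)
    }
    cm <- colMeans(Esel)
    Z <- sweep(Esel, 2L, cm, check.margin = FALSE)
    ss <- colSums(Z^2)
    ok <- ss > 0
    Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2L, sqrt(ss[ok]), "/", check.margin = FALSE)
    list(family = f$family, train = tr, test = f$test,
         Z = Z, ok = ok, qr = q, df = ntr - 2L - nc, ntr = ntr,
         Etr = Etr, Ete = edges[f$test, , drop = FALSE])
  })
  list(folds = folds, prep = prep, n = n, E = ncol(edges),
       adjusted = !is.null(covariates))
}

# Run the CPM cross-validation for one behavior vector on a prepared cache.
# fixed_masks (list(positive=, negative=)) bypasses within-fold selection —
# only used by the deliberately leaky negative-control variant.
cv_run <- function(cache, behavior, threshold, fixed_masks = NULL) {
  behavior <- as.numeric(behavior)
  n <- cache$n
  pred <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("positive", "negative")))
  nf <- length(cache$prep)
  fam <- character(nf); ntest <- integer(nf)
  npos <- integer(nf); nneg <- integer(nf)
  degp <- logical(nf); degn <- logical(nf)
  k <- 0L
  for (fp in cache$prep) {
    ytr <- behavior[fp$train]
    if (stats::sd(ytr) == 0) stop("behavior constant within a training fold", call. = FALSE)
    if (is.null(fixed_masks)) {
      ysel <- ytr
      if (!is.null(fp$qr)) {
        ysel <- qr.resid(fp$qr, ysel)
        if (stats::sd(ysel) < 1e-12) {
          stop("behavior constant after covariate adjustment in a training fold",
               call. = FALSE)
        }
      }
      yz <- ysel - mean(ysel)
      yz <- yz / sqrt(sum(yz^2))
      r <- as.numeric(crossprod(fp$Z, yz))
      r[!fp$ok] <- NA_real_
      tcrit <- stats::qt(1 - threshold / 2, fp$df)
      rcrit <- tcrit / sqrt(fp$df + tcrit^2)
      pos <- !is.na(r) & r > rcrit
      neg <- !is.na(r) & r < -rcrit
    } else {
      pos <- fixed_masks$positive
      neg <- fixed_masks$negative
    }
    mm <- cbind(as.numeric(pos), as.numeric(neg))
    str <- fp$Etr %*% mm
    ste <- fp$Ete %*% mm
    mp <- fit_tail_model(str[, 1L], ytr, "positive")
    mn <- fit_tail_model(str[, 2L], ytr, "negative")
    pred[fp$test, 1L] <- mp$intercept + mp$slope * ste[, 1L]
    pred[fp$test, 2L] <- mn$intercept + mn$slope * ste[, 2L]
    k <- k + 1L
    fam[k] <- fp$family; ntest[k] <- length(fp$test)
    npos[k] <- sum(pos); nneg[k] <- sum(neg)
    degp[k] <- mp$degenerate; degn[k] <- mn$degenerate
  }
  info <- data.frame(family = fam, n_test = ntest,
                     positive_edges = npos, negative_edges = nneg,
                     degenerate_positive = degp, degenerate_negative = degn,
                     stringsAsFactors = FALSE)
  r <- c(positive = evaluate_predictions(behavior, pred[, 1L]),
         negative = evaluate_predictions(behavior, pred[, 2L]))
  list(predictions = pred, r = r, fold_info = info)
}

# Vectorized variant of cv_run for many behavior vectors at once (one column
# of Y per permutation): per fold, the edge correlations for all columns are
# a single crossproduct and the per-tail OLS fits are closed-form column
# operations. Produces the same prediction correlations as looping cv_run
# over the columns (asserted in the test suite). Columns whose training
# behavior is constant (possible only in tiny toys) select no edges and fall
# back to the intercept-only model instead of erroring.
cv_run_multi <- function(cache, Y, threshold, fixed_masks = NULL) {
  Y <- as.matrix(Y)
  n <- cache$n
  m <- ncol(Y)
  pred_p <- matrix(NA_real_, n, m)
  pred_n <- matrix(NA_real_, n, m)
  eps <- 1e-12
  for (fp in cache$prep) {
    Ytr <- Y[fp$train, , drop = FALSE]
    ntr <- fp$ntr
    if (is.null(fixed_masks)) {
      Ysel <- if (!is.null(fp$qr)) qr.resid(fp$qr, Ytr) else Ytr
      cmy <- colMeans(Ysel)
      Yz <- sweep(Ysel, 2L, cmy, check.margin = FALSE)
      ssy <- colSums(Yz^2)
      ssy[ssy < eps] <- Inf   # constant behavior -> zero correlations
      Yz <- sweep(Yz, 2L, sqrt(ssy), "/", check.margin = FALSE)
      R <- crossprod(fp$Z, Yz)                     # E x m correlations
      R[!fp$ok, ] <- 0
      tcrit <- stats::qt(1 - threshold / 2, fp$df)
      rcrit <- tcrit / sqrt(fp$df + tcrit^2)
      POS <- (R > rcrit) + 0
      NEG <- (R < -rcrit) + 0
    } else {
      POS <- matrix(as.numeric(fixed_masks$positive), length(fixed_masks$positive), m)
      NEG <- matrix(as.numeric(fixed_masks$negative), length(fixed_masks$negative), m)
    }
    for (tail in 1:2) {
      MK <- if (tail == 1L) POS else NEG
      Str <- fp$Etr %*% MK                         # ntr x m summary scores
      Ste <- fp$Ete %*% MK
      ms <- colMeans(Str)
      my <- colMeans(Ytr)
      sxy <- colSums(Str * Ytr) - ntr * ms * my
      sxx <- colSums(Str^2) - ntr * ms^2
      deg <- sxx < eps * pmax(1, ms^2)
      slope <- ifelse(deg, 0, sxy / ifelse(deg, 1, sxx))
      intercept <- my - slope * ms
      P <- sweep(sweep(Ste, 2L, slope, "*", check.margin = FALSE),
                 2L, intercept, "+", check.margin = FALSE)
      if (tail == 1L) pred_p[fp$test, ] <- P else pred_n[fp$test, ] <- P
    }
  }
  col_r <- function(P) {
    vapply(seq_len(m), function(j) evaluate_predictions(Y[, j], P[, j]), numeric(1))
  }
  cbind(positive = col_r(pred_p), negative = col_r(pred_n))
}

#' Pearson correlation between actual and predicted scores
#'
#' The CPM performance measure. Constant predictions (for example when every
#' fold was degenerate) give `NA`, which downstream significance reporting
#' treats as not significant.
#'
#' @param actual,predicted equal-length numeric vectors (length >= 3).
#' @return correlation coefficient, or `NA` if either vector is constant.
#' @export
evaluate_predictions <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch", call. = FALSE)
  if (length(actual) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (anyNA(predicted) || stats::sd(predicted) < 1e-14 || stats::sd(actual) == 0) {
    return(NA_real_)
  }
  stats::cor(actual, predicted)
}

#' Leave-one-family-out cross-validated CPM
#'
#' Runs the full CPM pipeline with grouped cross-validation: within each
#' training fold (all subjects outside one family) edges are selected and
#' the per-tail linear models fitted, then the left-out family's scores are
#' predicted. Feature selection therefore never sees any member of a test
#' subject's family. Folds whose selection is empty fall back to an
#' intercept-only model and are flagged in the fold diagnostics.
#'
#' @inheritParams cpm
#' @param family_ids length-`n` family labels defining the folds.
#' @return object of class `"cpm_cv"`: per-subject predictions per tail,
#'   the actual scores, the prediction correlation `r` per tail, and
#'   per-fold diagnostics.
#' @examples
#' coh <- simulate_cohort(60, n_families = 20, seed = 3)
#' sim <- simulate_edges(coh, n_nodes = 15, n_pos = 8, n_neg = 8,
#'                       beta = 0.5, seed = 3)
#' cv <- cpm_cv(sim$edges, coh$behavior, coh$family_id)
#' cv
#' @export
cpm_cv <- function(edges, behavior, family_ids, threshold = 0.01,
                   covariates = NULL) {
  stopifnot_scalar_prob(threshold, "threshold")
  cache <- cv_prepare(edges, family_ids, covariates)
  res <- cv_run(cache, behavior, threshold)
  structure(list(predictions = res$predictions, actual = as.numeric(behavior),
                 r = res$r, fold_info = res$fold_info, threshold = threshold,
                 folds = cache$folds, adjusted = cache$adjusted,
                 n = cache$n, n_edges = cache$E),
            class = "cpm_cv")
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat("Leave-one-family-out CPM cross-validation\n")
  cat(sprintf("  %d subjects, %d families, %d edges, P < %g%s\n",
              x$n, nrow(x$fold_info), x$n_edges, x$threshold,
              if (x$adjusted) " (adjusted selection)" else ""))
  cat(sprintf("  r(actual, predicted): positive %s, negative %s\n",
              format(x$r["positive"], digits = 3),
              format(x$r["negative"], digits = 3)))
  ndeg <- sum(x$fold_info$degenerate_positive) + sum(x$fold_info$degenerate_negative)
  if (ndeg > 0) cat(sprintf("  %d degenerate tail-fold fits (no edges selected)\n", ndeg))
  invisible(x)
}

#' @export
summary.cpm_cv <- function(object, ...) {
  fi <- object$fold_info
  out <- list(r = object$r, n = object$n, n_families = nrow(fi),
              threshold = object$threshold,
              mean_edges = c(positive = mean(fi$positive_edges),
                             negative = mean(fi$negative_edges)),
              degenerate_folds = c(positive = sum(fi$degenerate_positive),
                                   negative = sum(fi$degenerate_negative)))
  class(out) <- "summary.cpm_cv"
  out
}

#' @export
print.summary.cpm_cv <- function(x, ...) {
  cat(sprintf("CPM CV: n = %d, %d families, P < %g\n", x$n, x$n_families, x$threshold))
  cat(sprintf("  positive tail: r = %s, mean %.1f edges/fold, %d degenerate\n",
              format(x$r["positive"], digits = 3), x$mean_edges["positive"],
              x$degenerate_folds["positive"]))
  cat(sprintf("  negative tail: r = %s, mean %.1f edges/fold, %d degenerate\n",
              format(x$r["negative"], digits = 3), x$mean_edges["negative"],
              x$degenerate_folds["negative"]))
  invisible(x)
}

#' @export
plot.cpm_cv <- function(x, tail = c("positive", "negative"), ...) {
  tail <- match.arg(tail)
  graphics::plot(x$actual, x$predictions[, tail],
                 xlab = "actual behavior score",
                 ylab = "predicted behavior score",
                 main = sprintf("CPM prediction (%s network), r = %.3f",
                                tail, x$r[tail]),
                 ...)
  graphics::abline(stats::lm(x$predictions[, tail] ~ x$actual), lty = 2)
  invisible(x)
}

#' Permutation test for the cross-validated prediction correlation
#'
#' Builds the empirical null by shuffling the correspondence between the
#' connectivity matrices and the behavior scores and rerunning the entire
#' cross-validated pipeline (including within-fold edge selection) for each
#' shuffle. The empirical p-value per tail is the proportion of permutations
#' whose prediction correlation is greater than or equal to the true one
#' (ties count toward the numerator); permutations whose correlation is
#' undefined (all folds degenerate) are excluded from both numerator and
#' denominator and reported in `n_invalid`.
#'
#' @inheritParams cpm_cv
#' @param n_perm number of permutations (the original design uses 5000).
#' @param seed integer seed for the shuffles.
#' @param smooth if `TRUE`, report the smoothed estimate
#'   `(count + 1) / (n_valid + 1)` instead of `count / n_valid`.
#' @param leak_full_sample_selection **negative control only**: select edges
#'   once on the full unpermuted sample and keep that mask fixed across
#'   folds and permutations. This reproduces a known CPM implementation bug
#'   (feature selection before cross-validation) and yields anticonservative
#'   p-values; it exists so the inflation can be demonstrated.
#' @return object of class `"cpm_perm"`: `r_true`, `null_r`
#'   (`n_perm x 2` matrix), `p` per tail, counts and settings.
#' @export
cpm_permtest <- function(edges, behavior, family_ids, threshold = 0.01,
                         covariates = NULL, n_perm = 1000, seed = 1,
                         smooth = FALSE, leak_full_sample_selection = FALSE) {
  stopifnot_scalar_prob(threshold, "threshold")
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("'n_perm' must be >= 1", call. = FALSE)
  behavior <- as.numeric(behavior)
  cache <- cv_prepare(edges, family_ids, covariates)
  fixed_masks <- NULL
  if (leak_full_sample_selection) {
    ce <- correlate_edges(edges, behavior, covariates)
    sel <- select_edges(ce$r, ce$p, threshold)
    fixed_masks <- list(positive = sel$positive, negative = sel$negative)
  }
  true_res <- cv_run(cache, behavior, threshold, fixed_masks)
  perm_idx <- with_seed(sub_seed(seed, 4L), {
    vapply(seq_len(n_perm), function(i) sample.int(cache$n), integer(cache$n))
  })
  Y <- matrix(behavior[perm_idx], cache$n, n_perm)
  null_r <- cv_run_multi(cache, Y, threshold, fixed_masks)
  p <- vapply(c("positive", "negative"), function(tl) {
    rt <- true_res$r[[tl]]
    if (is.na(rt)) return(NA_real_)
    nv <- null_r[, tl]
    nv <- nv[!is.na(nv)]
    if (length(nv) == 0L) return(NA_real_)
    cnt <- sum(nv >= rt)
    if (smooth) (cnt + 1) / (length(nv) + 1) else cnt / length(nv)
  }, numeric(1))
  structure(list(r_true = true_res$r, null_r = null_r, p = p,
                 n_perm = n_perm,
                 n_invalid = colSums(is.na(null_r)),
                 threshold = threshold, seed = seed, smooth = smooth,
                 leaky = leak_full_sample_selection,
                 fold_info = true_res$fold_info,
                 predictions = true_res$predictions),
            class = "cpm_perm")
}

#' @export
print.cpm_perm <- function(x, ...) {
  cat(sprintf("CPM permutation test (%d permutations%s%s)\n", x$n_perm,
              if (x$smooth) ", smoothed p" else "",
              if (x$leaky) ", LEAKY full-sample selection (negative control)" else ""))
  for (tl in c("positive", "negative")) {
    cat(sprintf("  %s network: r = %s, empirical p = %s\n", tl,
                format(x$r_true[[tl]], digits = 3), format(x$p[[tl]], digits = 3)))
  }
  if (any(x$n_invalid > 0)) {
    cat(sprintf("  invalid permutations excluded: positive %d, negative %d\n",
                x$n_invalid[1], x$n_invalid[2]))
  }
  invisible(x)
}
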