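#' Edge-wise correlation with a behavior score
#'
#' Pearson correlation between each edge (column) and the behavior vector,
#' with a two-sided p-value from `t = r * sqrt(df / (1 - r^2))`. With
#' covariates, both the edges and the behavior are first residualized on the
#' covariate matrix (with intercept) and the residuals are correlated — the
#' sample partial correlation — with `df = n - 2 - c` instead of `n - 2`.
#' Zero-variance edges yield `NA` and are never selected downstream.
#'
#' @param edges numeric `n x E` matrix, one row per subject, one column per
#'   edge (Fisher-z units).
#' @param behavior numeric length-`n` score.
#' @param covariates optional numeric `n x c` matrix/data.frame of nuisance
#'   variables (e.g. age, gender, intelligence, head motion).
#' @return list with `r` and `p`, each length `E`, plus `df`.
#' @export
correlate_edges <- function(edges, behavior, covariates = NULL) {
  edges <- as_edge_matrix_input(edges)
  behavior <- as.numeric(behavior)
  n <- nrow(edges)
  if (length(behavior) != n) stop("'behavior' length must match nrow(edges)", call. = FALSE)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (stats::sd(behavior) == 0) stop("'behavior' is constant", call. = FALSE)
  nc <- 0L
  if (!is.null(covariates)) {
    X <- cbind(1, as.matrix(covariates))
    storage.mode(X) <- "double"
    nc <- ncol(X) - 1L
    if (nrow(X) != n) stop("'covariates' rows must match subjects", call. = FALSE)
    q <- qr(X)
    if (q$rank < ncol(X)) {
      bad <- colnames(X)[-1][!(seq_len(ncol(X))[-1] %in% q$pivot[seq_len(q$rank)])]
      stop(sprintf("covariate matrix is rank deficient (collinear: %s)",
                   paste(if (length(bad)) bad else "unnamed column", collapse = ", ")),
           call. = FALSE)
    }
    if (n <= nc + 3L) stop("need n > c + 3 subjects for adjusted correlation", call. = FALSE)
    behavior <- qr.resid(q, behavior)
    if (stats::sd(behavior) < 1e-12) {
      stop("behavior is (numerically) constant after covariate adjustment", call. = FALSE)
    }
    edges <- qr.resid(q, edges)
  }
  df <- n - 2L - nc
  y <- behavior - mean(behavior)
  y <- y / sqrt(sum(y^2))
  cm <- colMeans(edges)
  ss <- colSums(edges^2) - n * cm^2
  ok <- ss > 0
  r <- rep(NA_real_, ncol(edges))
  num <- as.numeric(crossprod(edges, y)) - cm * sum(y)  # sum(y)=0, kept for clarity
  r[ok] <- num[ok] / sqrt(ss[ok])
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(r = r, p = p, df = df)
}

#' Split edges into positive and negative predictive networks
#'
#' Edges whose correlation with behavior passes the significance threshold
#' are assigned to the positive network if `r > 0` and the negative network
#' if `r < 0`; the masks are disjoint by construction (an edge is either a
#' positive or a negative predictor). Edges with undefined `r` are never
#' selected.
#'
#' @param r,p equal-length correlation and p-value vectors, as returned by
#'   [correlate_edges()].
#' @param threshold selection significance level in (0, 1); the main
#'   analysis uses 0.01, with 0.05 and 0.001 as sensitivity settings.
#' @return object of class `"edge_selection"`: list with logical masks
#'   `positive`, `negative`, the inputs `r`, `p` and `threshold`.
#' @export
select_edges <- function(r, p, threshold = 0.01) {
  if (length(r) != length(p)) stop("'r' and 'p' must have the same length", call. = FALSE)
  stopifnot_scalar_prob(threshold, "threshold")
  ok <- !is.na(r) & !is.na(p)
  pos <- ok & p < threshold & r > 0
  neg <- ok & p < threshold & r < 0
  structure(list(positive = pos, negative = neg, r = r, p = p,
                 threshold = threshold),
            class = "edge_selection")
}

#' @export
print.edge_selection <- function(x, ...) {
  cat(sprintf("Edge selection at P < %g: %d positive, %d negative of %d edges\n",
              x$threshold, sum(x$positive), sum(x$negative), length(x$r)))
  invisible(x)
}

#' Single-subject network summary score
#'
#' Sums the edge weights inside a network mask for each subject; an empty
#' mask gives 0.
#'
#' @param edges length-`E` edge vector or `n x E` matrix.
#' @param mask logical length-`E` mask.
#' @return scalar (vector input) or length-`n` vector (matrix input), in
#'   summed Fisher-z units.
#' @export
summary_score <- function(edges, mask) {
  mask <- as.logical(mask)
  if (is.matrix(edges)) {
    if (ncol(edges) != length(mask)) stop("mask length must match edge count", call. = FALSE)
    if (!any(mask)) return(numeric(nrow(edges)))
    rowSums(edges[, mask, drop = FALSE])
  } else {
    if (length(edges) != length(mask)) stop("mask length must match edge count", call. = FALSE)
    sum(edges[mask])
  }
}

# OLS of behavior on a network summary score; degenerate (constant) scores
# fall back to an intercept-only model so strict thresholds on small folds
# never abort a run.
fit_tail_model <- function(scores, behavior, tail) {
  n <- length(scores)
  if (n < 3L) stop("need at least 3 training subjects", call. = FALSE)
  if (stats::sd(scores) < 1e-12) {
    return(list(tail = tail, slope = 0, intercept = mean(behavior),
                degenerate = TRUE, n_train = n))
  }
  sx <- scores - mean(scores)
  slope <- sum(sx * behavior) / sum(sx^2)
  intercept <- mean(behavior) - slope * mean(scores)
  list(tail = tail, slope = slope, intercept = intercept,
       degenerate = FALSE, n_train = n)
}

#' Fit a connectome-based predictive model
#'
#' The core CPM fit on a training sample: correlate every edge with the
#' behavior score (optionally adjusting for covariates), threshold into
#' positive and negative predictive networks, sum each subject's selected
#' edge weights into per-tail summary scores, and regress behavior on each
#' score with ordinary least squares. Each tail is modeled independently.
#'
#' @param edges numeric `n x E` training edge matrix (Fisher-z units).
#' @param behavior numeric length-`n` behavior score.
#' @param threshold edge-selection significance level (default 0.01).
#' @param covariates optional nuisance matrix for adjusted selection.
#' @return object of class `"cpm"`: the edge selection, per-tail linear
#'   models, training scores and data summaries.
#' @examples
#' coh <- simulate_cohort(80, n_families = 40, seed = 2)
#' sim <- simulate_edges(coh, n_nodes = 20, n_pos = 10, n_neg = 10,
#'                       beta = 0.4, seed = 2)
#' fit <- cpm(sim$edges, coh$behavior)
#' fit
#' @export
cpm <- function(edges, behavior, threshold = 0.01, covariates = NULL) {
  edges <- as_edge_matrix_input(edges)
  ce <- correlate_edges(edges, behavior, covariates)
  sel <- select_edges(ce$r, ce$p, threshold)
  scores <- cbind(positive = summary_score(edges, sel$positive),
                  negative = summary_score(edges, sel$negative))
  models <- list(
    positive = fit_tail_model(scores[, "positive"], behavior, "positive"),
    negative = fit_tail_model(scores[, "negative"], behavior, "negative"))
  structure(list(selection = sel, models = models, threshold = threshold,
                 scores = scores, behavior = behavior,
                 n = nrow(edges), n_edges = ncol(edges),
                 adjusted = !is.null(covariates), call = match.call()),
            class = "cpm")
}

#' @export
print.cpm <- function(x, ...) {
  cat("Connectome-based predictive model\n")
  cat(sprintf("  %d subjects, %d edges, selection at P < %g%s\n",
              x$n, x$n_edges, x$threshold,
              if (x$adjusted) " (covariate-adjusted)" else ""))
  for (tl in c("positive", "negative")) {
    m <- x$models[[tl]]
    cat(sprintf("  %s network: %4d edges, slope %.4f, intercept %.3f%s\n",
                tl, sum(x$selection[[tl]]), m$slope, m$intercept,
                if (m$degenerate) " [degenerate: intercept-only]" else ""))
  }
  invisible(x)
}

#' @export
summary.cpm <- function(object, ...) {
  out <- list(
    n = object$n, n_edges = object$n_edges, threshold = object$threshold,
    edges_selected = c(positive = sum(object$selection$positive),
                       negative = sum(object$selection$negative)),
    coefficients = coef(object),
    fit_r = vapply(c("positive", "negative"), function(tl) {
      s <- object$scores[, tl]
      if (stats::sd(s) < 1e-12) NA_real_ else stats::cor(s, object$behavior)
    }, numeric(1)))
  class(out) <- "summary.cpm"
  out
}

#' @export
print.summary.cpm <- function(x, ...) {
  cat(sprintf("CPM fit: n = %d, E = %d, P < %g\n", x$n, x$n_edges, x$threshold))
  cat(sprintf("  positive network: %d edges, in-sample r = %.3f\n",
              x$edges_selected["positive"], x$fit_r["positive"]))
  cat(sprintf("  negative network: %d edges, in-sample r = %.3f\n",
              x$edges_selected["negative"], x$fit_r["negative"]))
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.cpm <- function(object, ...) {
  t(vapply(object$models, function(m) c(intercept = m$intercept, slope = m$slope),
           numeric(2)))
}

#' Predict behavior for new subjects from a fitted CPM
#'
#' @param object a fitted [cpm()] model.
#' @param newdata `n x E` edge matrix for the subjects to predict (same edge
#'   ordering as the training data); defaults to the training edges.
#' @param ... unused.
#' @return numeric matrix with columns `positive` and `negative`.
#' @export
predict.cpm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    scores <- object$scores
  } else {
    newdata <- as_edge_matrix_input(newdata)
    if (ncol(newdata) != object$n_edges) {
      stop(sprintf("'newdata' must have %d edge columns", object$n_edges), call. = FALSE)
    }
    scores <- cbind(positive = summary_score(newdata, object$selection$positive),
                    negative = summary_score(newdata, object$selection$negative))
  }
  sapply(c("positive", "negative"), function(tl) {
    m <- object$models[[tl]]
    m$intercept + m$slope * scores[, tl]
  })
}

#' @export
fitted.cpm <- function(object, ...) predict(object)

#' @export
residuals.cpm <- function(object, ...) {
  object$behavior - predict(object)
}

#' @export
plot.cpm <- function(x, tail = c("positive", "negative"), ...) {
  tail <- match.arg(tail)
  pred <- predict(x)[, tail]
  graphics::plot(x$behavior, pred,
                 xlab = "actual behavior score",
                 ylab = "fitted behavior score",
                 main = sprintf("CPM training fit (%s network)", tail), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
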