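#' Number of unique edges among K nodes
#'
#' @param K number of network nodes.
#' @return `K * (K - 1) / 2`, the length of the upper-triangle edge vector.
#' @export
n_edges <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("'K' must be an integer >= 2", call. = FALSE)
  as.integer(K * (K - 1) / 2)
}

#' Node-pair table for the edge-vector ordering
#'
#' Edges are stored row-major over the upper triangle: (1,2), (1,3), ...,
#' (1,K), (2,3), ..., (K-1,K). This is the ordering used by every function
#' in the package that flattens a connectivity matrix.
#'
#' @param K number of nodes.
#' @return integer matrix with columns `i`, `j` (1-based, `i < j`) and one
#'   row per edge.
#' @export
edge_pairs <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("'K' must be an integer >= 2", call. = FALSE)
  i <- rep.int(seq_len(K - 1L), times = (K - 1L):1L)
  j <- sequence((K - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Flatten a symmetric connectivity matrix to an edge vector
#'
#' @param m symmetric numeric `K x K` matrix.
#' @return numeric vector of length `K*(K-1)/2` in [edge_pairs()] order.
#' @seealso [edge_matrix()] for the inverse.
#' @export
edge_vector <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("'m' must be square", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) {
    stop("'m' must be symmetric", call. = FALSE)
  }
  # lower triangle of t(m) in column-major order == row-major upper triangle
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric connectivity matrix from an edge vector
#'
#' @param v numeric vector of length `K*(K-1)/2` in [edge_pairs()] order.
#' @param K number of nodes; inferred from `length(v)` when missing.
#' @return symmetric `K x K` matrix with zero diagonal.
#' @export
edge_matrix <- function(v, K = NULL) {
  E <- length(v)
  if (is.null(K)) {
    K <- (1 + sqrt(1 + 8 * E)) / 2
    if (abs(K - round(K)) > 1e-9) {
      stop(sprintf("length %d is not K*(K-1)/2 for any integer K", E),
           call. = FALSE)
    }
    K <- as.integer(round(K))
  } else {
    K <- as.integer(K)
    if (E != K * (K - 1) / 2) {
      stop(sprintf("length %d does not match K = %d (expected %d)",
                   E, K, K * (K - 1) / 2), call. = FALSE)
    }
  }
  mt <- matrix(0, K, K)
  mt[lower.tri(mt)] <- v   # column-major lower of the transpose
  m <- t(mt)
  m + t(m)
}

#' Fisher r-to-z transformation
#'
#' Variance-stabilizing transform `z = artanh(r)` applied elementwise.
#' Correlations with `|r| >= 1 - 1e-7` are clamped to `+/-(1 - 1e-7)` before
#' the transform so that exact duplicates (r = 1) stay finite; a clamp is
#' reported via a message.
#'
#' @param r correlation scalar, vector or matrix with `|r| <= 1`.
#' @return object of the same shape in Fisher-z units.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must satisfy |r| <= 1", call. = FALSE)
  }
  lim <- 1 - 1e-7
  n_clamped <- sum(abs(r) > lim, na.rm = TRUE)
  if (n_clamped > 0L) {
    message(sprintf("fisher_z: clamped %d value(s) with |r| >= 1 - 1e-7", n_clamped))
    r <- pmin(pmax(r, -lim), lim)
  }
  atanh(r)
}

check_timeseries <- function(ts, min_T = 3L) {
  ts <- as.matrix(ts)
  storage.mode(ts) <- "double"
  if (nrow(ts) < min_T) {
    stop(sprintf("need at least %d timepoints, got %d", min_T, nrow(ts)),
         call. = FALSE)
  }
  if (ncol(ts) < 2L) stop("need at least 2 nodes", call. = FALSE)
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant (zero-variance) node time series: column(s) %s",
                 paste(which(sds == 0), collapse = ", ")), call. = FALSE)
  }
  ts
}

#' Partial correlation matrix from node time series
#'
#' Correlation between each pair of node time series after removing the
#' linear influence of all remaining nodes, computed from the inverse of the
#' (optionally ridge-regularized) column correlation matrix:
#' `p_ij = -W_ij / sqrt(W_ii * W_jj)` with `W = (C + ridge * mean(diag(C)) I)^-1`.
#' Columns are demeaned and variance-normalized first, so `C` is the
#' correlation matrix and the ridge term is `ridge * I`.
#'
#' @param ts numeric `T x K` matrix of node time series (rows = timepoints).
#' @param ridge nonnegative ridge fraction added to the diagonal before
#'   inversion; `0` gives the unregularized estimator. Default `0.01`,
#'   a conventional stabilizer for K up to a few hundred.
#' @return symmetric `K x K` matrix of partial correlations, zero diagonal.
#' @examples
#' x <- matrix(rnorm(400), 100, 4)
#' p <- partial_correlation(x, ridge = 0)
#' @export
partial_correlation <- function(ts, ridge = 0.01) {
  ts <- check_timeseries(ts, min_T = 3L)
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge < 0) {
    stop("'ridge' must be a single nonnegative number", call. = FALSE)
  }
  Z <- scale(ts)
  C <- crossprod(Z) / (nrow(Z) - 1)
  R <- C + diag(ridge * mean(diag(C)), ncol(C))
  W <- tryCatch(
    chol2inv(chol(R)),
    error = function(e) {
      stop(sprintf(paste0("regularized correlation matrix is singular ",
                          "(ridge = %g); increase the ridge parameter"), ridge),
           call. = FALSE)
    })
  d <- sqrt(diag(W))
  P <- -W / tcrossprod(d)
  diag(P) <- 0
  (P + t(P)) / 2
}

#' Pearson correlation matrix from node time series
#'
#' @param ts numeric `T x K` matrix of node time series.
#' @return symmetric `K x K` product-moment correlation matrix, zero diagonal.
#' @export
pearson_correlation <- function(ts) {
  ts <- check_timeseries(ts, min_T = 3L)
  C <- stats::cor(ts)
  diag(C) <- 0
  C
}

#' Build a Fisher-z connectome from node time series
#'
#' Convenience wrapper: partial (default) or Pearson correlation followed by
#' the Fisher r-to-z transform, returning the symmetric edge-weight matrix
#' used throughout the CPM pipeline.
#'
#' @param ts numeric `T x K` matrix of node time series.
#' @param method `"partial"` or `"pearson"`.
#' @param ridge ridge fraction for the partial estimator (see
#'   [partial_correlation()]); ignored for `"pearson"`.
#' @return `K x K` symmetric matrix of Fisher-z edge weights, zero diagonal,
#'   with attributes `method` and `ridge`.
#' @export
connectome <- function(ts, method = c("partial", "pearson"), ridge = 0.01) {
  method <- match.arg(method)
  r <- if (method == "partial") partial_correlation(ts, ridge = ridge)
       else pearson_correlation(ts)
  z <- fisher_z(r)
  diag(z) <- 0
  structure(z, method = method, ridge = if (method == "partial") ridge else NA_real_)
}
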