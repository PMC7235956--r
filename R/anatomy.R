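#' Full-sample predictive networks (illustrative)
#'
#' Edge selection computed once on the entire sample, used to describe the
#' anatomy of the predictive networks (node degrees, hubs, canonical-network
#' overlap). This is deliberately *not* the cross-validated feature set:
#' full-sample selection is illustrative only and must never be fed back
#' into prediction (see the leakage negative control in [cpm_permtest()]).
#'
#' @inheritParams cpm
#' @return an `"edge_selection"` object (see [select_edges()]).
#' @export
full_sample_networks <- function(edges, behavior, threshold = 0.01,
                                 covariates = NULL) {
  ce <- correlate_edges(edges, behavior, covariates)
  select_edges(ce$r, ce$p, threshold)
}

#' Node degree within a predictive-network mask
#'
#' Degree of node v = number of selected edges incident to v. Degrees obey
#' the handshake identity: they sum to twice the number of selected edges.
#'
#' @param mask logical length-`E` edge mask (in [edge_pairs()] order).
#' @param K number of nodes.
#' @return integer length-`K` degree vector.
#' @export
node_degree <- function(mask, K) {
  K <- as.integer(K)
  mask <- as.logical(mask)
  if (length(mask) != n_edges(K)) {
    stop(sprintf("mask length %d does not match K = %d (expected %d)",
                 length(mask), K, n_edges(K)), call. = FALSE)
  }
  pairs <- edge_pairs(K)[mask, , drop = FALSE]
  tabulate(c(pairs[, 1L], pairs[, 2L]), nbins = K)
}

#' High-degree (hub) nodes of a predictive network
#'
#' @param degrees integer degree vector from [node_degree()].
#' @param min_degree minimum degree to qualify as a hub; the reference
#'   figures use 4 (and 6 for the densest network).
#' @return data.frame with `node` and `degree`, sorted by degree descending
#'   then node id ascending.
#' @export
high_degree_nodes <- function(degrees, min_degree = 4) {
  if (min_degree < 1) stop("'min_degree' must be >= 1", call. = FALSE)
  keep <- which(degrees >= min_degree)
  ord <- keep[order(-degrees[keep], keep)]
  data.frame(node = ord, degree = degrees[ord])
}

#' Canonical-network overlap of the highest-degree nodes
#'
#' Takes the `top_n` nodes by degree (ties at the boundary broken by lower
#' node id, so the summary is deterministic) and counts how many fall in
#' each canonical network label (default mode, frontoparietal, visual, ...).
#'
#' @param degrees integer degree vector from [node_degree()].
#' @param labels character vector mapping each node to a canonical-network
#'   name (length `K`), or a data.frame with columns `node` and `network`.
#' @param top_n number of highest-degree nodes to summarize (default 20).
#' @return named integer vector of counts per canonical network, summing to
#'   `top_n`, in decreasing count order.
#' @export
summarize_canonical <- function(degrees, labels, top_n = 20) {
  K <- length(degrees)
  if (is.data.frame(labels)) {
    if (!all(c("node", "network") %in% names(labels))) {
      stop("label data.frame needs columns 'node' and 'network'", call. = FALSE)
    }
    lab <- rep(NA_character_, K)
    lab[labels$node] <- as.character(labels$network)
  } else {
    lab <- as.character(labels)
    if (length(lab) != K) stop("'labels' must have one entry per node", call. = FALSE)
  }
  top_n <- as.integer(top_n)
  if (top_n < 1L || top_n > K) stop("'top_n' must be in 1..K", call. = FALSE)
  top <- order(-degrees, seq_len(K))[seq_len(top_n)]
  unlabeled <- top[is.na(lab[top])]
  if (length(unlabeled)) {
    stop(sprintf("unlabeled node(s) among the top %d: %s", top_n,
                 paste(unlabeled, collapse = ", ")), call. = FALSE)
  }
  counts <- table(lab[top])
  sort(structure(as.integer(counts), names = names(counts)), decreasing = TRUE)
}
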