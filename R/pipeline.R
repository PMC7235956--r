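#' Write a subjects-by-edges table with its edge-order sidecar
#'
#' Edge columns follow the row-major upper-triangle convention; the sidecar
#' JSON records the node pair behind every column so edge files are
#' self-describing.
#'
#' @param edges `n x E` matrix with subject IDs as rownames.
#' @param path output CSV path; the sidecar is written next to it as
#'   `<path basename>_edge_order.json`.
#' @param K number of nodes (validates `E = K*(K-1)/2`).
#' @return invisibly, the sidecar path.
#' @export
write_edges_csv <- function(edges, path, K) {
  E <- n_edges(K)
  if (ncol(edges) != E) {
    stop(sprintf("edge matrix has %d columns; K = %d implies %d", ncol(edges), K, E),
         call. = FALSE)
  }
  pairs <- edge_pairs(K)
  df <- data.frame(subject_id = rownames(edges), edges, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("subject_id", sprintf("e%d_%d", pairs[, 1], pairs[, 2]))
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- file.path(dirname(path),
                       paste0(sub("\\.csv$", "", basename(path)), "_edge_order.json"))
  jsonlite::write_json(list(ordering = "row-major upper triangle (i < j)",
                            n_nodes = K,
                            pairs = unname(apply(pairs, 1, function(x) x))),
                       sidecar, auto_unbox = TRUE)
  invisible(sidecar)
}

#' Read a subjects-by-edges CSV written by [write_edges_csv()]
#'
#' @param path CSV with a `subject_id` column followed by edge columns.
#' @return numeric matrix with subject IDs as rownames.
#' @export
read_edges_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(df)) stop("missing 'subject_id' column", call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$subject_id
  m
}

default_config <- function() {
  list(method = "cpm", threshold = 0.01, n_perm = 1000, seed = 1,
       covariates = NULL, alpha = 1.0, l1_ratio = 0.5, smooth = FALSE)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML config requires the 'yaml' package; use JSON instead", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  utils::modifyList(default_config(), config)
}

#' Run the end-to-end prediction pipeline from files
#'
#' Loads a subjects-by-edges table and a phenotype table, aligns them by
#' subject ID (never by row order), runs the requested prediction method
#' (CPM with permutation test, or the elastic-net baseline) under
#' leave-one-family-out cross-validation, and writes `predictions.csv`,
#' `null_distribution.csv` (CPM only) and `report.json` to the output
#' directory.
#'
#' @param config named list, or path to a JSON/YAML file, with entries:
#'   `edges` (CSV path), `pheno` (CSV path), `factor` (phenotype column to
#'   predict), `out` (output directory), and optionally `method`
#'   (`"cpm"`/`"elastic-net"`), `threshold`, `n_perm`, `seed`, `covariates`
#'   (character vector of phenotype columns), `alpha`, `l1_ratio`, `smooth`.
#' @return the report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  for (key in c("edges", "pheno", "factor", "out")) {
    if (is.null(cfg[[key]])) stop(sprintf("config entry '%s' is required", key), call. = FALSE)
  }
  for (f in c(cfg$edges, cfg$pheno)) {
    if (!file.exists(f)) stop(sprintf("input file not found: %s", f), call. = FALSE)
  }
  edges <- read_edges_csv(cfg$edges)
  pheno <- load_cohort(cfg$pheno,
                       required = c(cfg$factor, cfg$covariates),
                       need_family = TRUE)
  only_edges <- setdiff(rownames(edges), pheno$subject_id)
  only_pheno <- setdiff(pheno$subject_id, rownames(edges))
  if (length(only_edges) || length(only_pheno)) {
    stop(sprintf(
      "subject sets differ between edges and phenotypes%s%s",
      if (length(only_edges)) sprintf("; only in edges: %s", paste(only_edges, collapse = ", ")) else "",
      if (length(only_pheno)) sprintf("; only in phenotypes: %s", paste(only_pheno, collapse = ", ")) else ""),
      call. = FALSE)
  }
  pheno <- pheno[match(rownames(edges), pheno$subject_id), ]
  behavior <- pheno[[cfg$factor]]
  covmat <- if (length(cfg$covariates)) {
    as.matrix(pheno[, cfg$covariates, drop = FALSE])
  } else NULL
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)

  if (identical(cfg$method, "elastic-net")) {
    res <- enet_cv(edges, behavior, pheno$family_id,
                   alpha = cfg$alpha, l1_ratio = cfg$l1_ratio)
    pred_df <- data.frame(subject_id = pheno$subject_id, actual = behavior,
                          predicted = res$predictions)
    report <- list(method = "elastic-net", factor = cfg$factor,
                   alpha = cfg$alpha, l1_ratio = cfg$l1_ratio,
                   n_subjects = res$n, n_edges = res$n_edges,
                   n_families = length(res$folds),
                   r = unname(res$r),
                   mean_nonzero_coefficients = mean(res$nonzero_per_fold))
  } else {
    pt <- cpm_permtest(edges, behavior, pheno$family_id,
                       threshold = cfg$threshold, covariates = covmat,
                       n_perm = cfg$n_perm, seed = cfg$seed, smooth = cfg$smooth)
    pred_df <- data.frame(subject_id = pheno$subject_id, actual = behavior,
                          predicted_positive = pt$predictions[, "positive"],
                          predicted_negative = pt$predictions[, "negative"])
    utils::write.csv(
      data.frame(permutation = seq_len(cfg$n_perm),
                 r_positive = pt$null_r[, "positive"],
                 r_negative = pt$null_r[, "negative"]),
      file.path(cfg$out, "null_distribution.csv"), row.names = FALSE)
    report <- list(method = "cpm", factor = cfg$factor,
                   threshold = cfg$threshold, n_perm = cfg$n_perm,
                   seed = cfg$seed, smooth = cfg$smooth,
                   covariates = cfg$covariates,
                   n_subjects = nrow(edges), n_edges = ncol(edges),
                   n_families = nrow(pt$fold_info),
                   r = as.list(pt$r_true), p = as.list(pt$p),
                   edges_per_fold = list(
                     positive = pt$fold_info$positive_edges,
                     negative = pt$fold_info$negative_edges),
                   degenerate_folds = list(
                     positive = sum(pt$fold_info$degenerate_positive),
                     negative = sum(pt$fold_info$degenerate_negative)))
  }
  report$edge_order <- "row-major upper triangle (i < j)"
  report$package_version <- as.character(utils::packageVersion("cpmr"))
  utils::write.csv(pred_df, file.path(cfg$out, "predictions.csv"), row.names = FALSE)
  jsonlite::write_json(report, file.path(cfg$out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Write a simulated dataset to disk
#'
#' Convenience wrapper pairing [simulate_cohort()] and [simulate_edges()]
#' and writing `phenotypes.csv`, `edges.csv` (+ edge-order sidecar) and
#' `ground_truth.json` to a directory.
#'
#' @inheritParams simulate_cohort
#' @inheritParams simulate_edges
#' @param out output directory.
#' @return invisibly, the list from [simulate_edges()] plus the cohort.
#' @export
simulate_to_dir <- function(out, n_subjects, n_families, n_nodes, n_pos, n_neg,
                            beta, noise_sd = 1, family_effect_sd = 0, seed) {
  coh <- simulate_cohort(n_subjects, n_families, seed = seed)
  sim <- simulate_edges(coh, n_nodes, n_pos, n_neg, beta,
                        noise_sd = noise_sd, family_effect_sd = family_effect_sd,
                        seed = seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(coh, file.path(out, "phenotypes.csv"), row.names = FALSE)
  write_edges_csv(sim$edges, file.path(out, "edges.csv"), n_nodes)
  jsonlite::write_json(
    list(positive_edges = sim$truth$positive_edges,
         negative_edges = sim$truth$negative_edges,
         beta = beta, noise_sd = noise_sd,
         family_effect_sd = family_effect_sd, seed = seed),
    file.path(out, "ground_truth.json"), digits = NA)
  invisible(list(cohort = coh, edges = sim$edges, truth = sim$truth))
}
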