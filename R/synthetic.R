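#' Simulate a family-structured cohort with NEO-like behavior scores
#'
#' Generates a cohort table emulating a large resting-state fMRI sample:
#' subjects grouped into families (the unit of the grouped cross-validation),
#' an integer questionnaire-style behavior score, and the covariates used for
#' adjusted edge selection (age, binary gender, intelligence as a
#' matrix-reasoning count correct, and a scalar head-motion summary).
#'
#' Behavior is drawn Gaussian, rounded, and clipped to the 0-48 range of a
#' 12-item, 0-4 Likert factor total, so the phenotype is integer-valued like
#' a real questionnaire total. Family sizes are drawn from
#' `family_size_probs` over sizes 1..length(probs) and then adjusted so they
#' sum exactly to `n_subjects`, unless explicit `family_sizes` are given.
#'
#' @param n_subjects number of subjects.
#' @param n_families number of families; ignored when `family_sizes` is given.
#' @param family_sizes optional integer vector of family sizes summing to
#'   `n_subjects` (overrides `n_families`).
#' @param behavior_mean,behavior_sd mean and SD of the latent Gaussian
#'   behavior score, in questionnaire-total units (defaults 32 and 6).
#' @param age_range inclusive age range sampled uniformly (years).
#' @param prop_female probability of gender code 1.
#' @param iq_mean,iq_sd intelligence score (count correct, clipped to 0-24).
#' @param motion_meanlog,motion_sdlog log-normal parameters of the head
#'   motion summary (mm).
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return data.frame with columns `subject_id`, `family_id`, `behavior`,
#'   `age`, `gender`, `intelligence`, `motion`.
#' @examples
#' coh <- simulate_cohort(60, n_families = 20, seed = 1)
#' table(table(coh$family_id))
#' @export
simulate_cohort <- function(n_subjects, n_families = NULL, family_sizes = NULL,
                            behavior_mean = 32, behavior_sd = 6,
                            age_range = c(22, 37), prop_female = 0.5,
                            iq_mean = 17, iq_sd = 4.5,
                            motion_meanlog = log(0.07), motion_sdlog = 0.4,
                            seed) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1", call. = FALSE)
  if (is.null(family_sizes)) {
    if (is.null(n_families)) stop("give 'n_families' or 'family_sizes'", call. = FALSE)
    n_families <- as.integer(n_families)
    if (n_families > n_subjects) {
      stop("'n_families' cannot exceed 'n_subjects'", call. = FALSE)
    }
    if (n_families < 1L) stop("'n_families' must be >= 1", call. = FALSE)
  } else {
    family_sizes <- as.integer(family_sizes)
    if (any(family_sizes < 1L) || sum(family_sizes) != n_subjects) {
      stop("'family_sizes' must be positive and sum to 'n_subjects'", call. = FALSE)
    }
    n_families <- length(family_sizes)
  }
  with_seed(sub_seed(seed, 1L), {
    if (is.null(family_sizes)) {
      # start with one member per family, assign the remainder uniformly
      family_sizes <- rep.int(1L, n_families)
      extra <- n_subjects - n_families
      if (extra > 0L) {
        add <- sample.int(n_families, extra, replace = TRUE)
        tab <- tabulate(add, nbins = n_families)
        family_sizes <- family_sizes + tab
      }
    }
    family_id <- rep.int(sprintf("F%04d", seq_len(n_families)), family_sizes)
    latent <- stats::rnorm(n_subjects, behavior_mean, behavior_sd)
    behavior <- pmin(pmax(round(latent), 0), 48)
    out <- data.frame(
      subject_id = sprintf("S%05d", seq_len(n_subjects)),
      family_id = family_id,
      behavior = as.integer(behavior),
      age = round(stats::runif(n_subjects, age_range[1], age_range[2]), 1),
      gender = stats::rbinom(n_subjects, 1L, prop_female),
      intelligence = as.integer(pmin(pmax(round(stats::rnorm(n_subjects, iq_mean, iq_sd)), 0), 24)),
      motion = round(stats::rlnorm(n_subjects, motion_meanlog, motion_sdlog), 4),
      stringsAsFactors = FALSE
    )
    attr(out, "behavior_latent") <- latent
    out
  })
}

#' Simulate Fisher-z edge matrices with a planted linear behavioral signal
#'
#' Each edge follows `edge_e(s) = mu_e + beta_e * z(behavior_s) +
#' family_offset_{f(s),e} + eps`, where `z()` standardizes the cohort's
#' behavior scores, `beta_e = +beta` on planted positive edges, `-beta` on
#' planted negative edges and 0 elsewhere, the family offset is a Gaussian
#' shared by all members of a family (default off), and `eps` is independent
#' Gaussian edge noise. Baseline means `mu_e` are drawn once per dataset from
#' `N(0, mu_sd)` to mimic the spread of Fisher-z partial correlations.
#'
#' @param cohort data.frame from [simulate_cohort()] (needs `behavior` and
#'   `family_id`).
#' @param n_nodes number of network nodes K; edges are the
#'   `E = K*(K-1)/2` node pairs in [edge_pairs()] order.
#' @param n_pos,n_neg numbers of planted positive / negative signal edges
#'   (disjoint sets).
#' @param beta nonnegative effect size, edge-weight units per behavior SD.
#' @param noise_sd independent edge noise SD (edge-weight units).
#' @param family_effect_sd SD of the per-family shared offset (default 0;
#'   nonzero values create the familial dependence that motivates
#'   leave-one-family-out cross-validation).
#' @param mu_sd SD of the baseline edge means.
#' @param seed integer seed.
#' @return list with `edges` (n x E matrix, rownames = subject IDs) and
#'   `truth` (list: `positive_edges`, `negative_edges` (edge indices),
#'   `beta_per_edge`, `behavior_z`).
#' @export
simulate_edges <- function(cohort, n_nodes, n_pos, n_neg, beta,
                           noise_sd = 1, family_effect_sd = 0, mu_sd = 0.3,
                           seed) {
  if (nrow(cohort) < 1L) stop("cohort must be nonempty", call. = FALSE)
  K <- as.integer(n_nodes)
  E <- n_edges(K)
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  if (n_pos < 0L || n_neg < 0L || n_pos + n_neg > E) {
    stop(sprintf("n_pos + n_neg must be between 0 and E = %d", E), call. = FALSE)
  }
  if (!is.numeric(beta) || beta < 0) stop("'beta' must be >= 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("'noise_sd' must be > 0", call. = FALSE)
  n <- nrow(cohort)
  b <- cohort$behavior
  z <- if (n > 1L && stats::sd(b) > 0) as.numeric(scale(b)) else rep(0, n)
  with_seed(sub_seed(seed, 2L), {
    planted <- sample.int(E, n_pos + n_neg)
    pos <- sort(planted[seq_len(n_pos)])
    neg <- sort(planted[n_pos + seq_len(n_neg)])
    beta_e <- numeric(E)
    beta_e[pos] <- beta
    beta_e[neg] <- -beta
    mu <- stats::rnorm(E, 0, mu_sd)
    edges <- matrix(mu, n, E, byrow = TRUE) + outer(z, beta_e)
    if (family_effect_sd > 0) {
      fams <- factor(cohort$family_id)
      offs <- matrix(stats::rnorm(nlevels(fams) * E, 0, family_effect_sd),
                     nlevels(fams), E)
      edges <- edges + offs[as.integer(fams), , drop = FALSE]
    }
    edges <- edges + matrix(stats::rnorm(n * E, 0, noise_sd), n, E)
    rownames(edges) <- cohort$subject_id
    list(edges = edges,
         truth = list(positive_edges = pos, negative_edges = neg,
                      beta_per_edge = beta_e, behavior_z = z))
  })
}

#' Simulate Gaussian node time series with a known precision matrix
#'
#' Rows are i.i.d. draws from the zero-mean multivariate Gaussian whose
#' precision (inverse covariance) matrix is given, so the population partial
#' correlation between nodes i and j is `-P_ij / sqrt(P_ii * P_jj)` — a
#' closed form against which connectome estimators can be tested.
#'
#' @param n_time number of timepoints (rows).
#' @param precision symmetric positive-definite `K x K` precision matrix.
#' @param seed integer seed.
#' @return `n_time x K` numeric matrix.
#' @export
simulate_time_series <- function(n_time, precision, seed) {
  precision <- as.matrix(precision)
  K <- ncol(precision)
  if (nrow(precision) != K || max(abs(precision - t(precision))) > 1e-10) {
    stop("'precision' must be symmetric", call. = FALSE)
  }
  ch <- tryCatch(chol(precision), error = function(e) {
    stop("'precision' must be positive-definite", call. = FALSE)
  })
  # covariance = precision^-1; draw X = Z %*% t(chol(Sigma))
  Sigma <- chol2inv(ch)
  L <- chol(Sigma)
  with_seed(sub_seed(seed, 3L), {
    Z <- matrix(stats::rnorm(n_time * K), n_time, K)
    Z %*% L
  })
}

#' Calibrate the planted effect size for a target prediction correlation
#'
#' Semi-analytic calibration of `beta` (per-edge effect in [simulate_edges()])
#' so that the CPM pipeline's cross-validated prediction correlation targets
#' `target_r` under given design conditions. The calculation models the
#' selection step with the Fisher-z normal approximation to the per-edge
#' correlation test (power `pi` of passing the two-sided threshold in the
#' correct tail), takes the expected selected network as `k1 = k * pi`
#' planted plus `k0 = (E - 2k) * threshold / 2` false-positive edges per
#' tail, and evaluates the population correlation between the summed network
#' score and behavior:
#' `r = k1*b / sqrt((k1*b)^2 + k1 + k0)` with `b = beta / noise_sd`.
#' The returned `beta` solves `r = target_r` by root finding.
#'
#' @param target_r target prediction correlation (e.g. 0.3).
#' @param n training sample size.
#' @param k planted signal edges per tail.
#' @param n_nodes number of nodes K (gives `E = K*(K-1)/2`).
#' @param noise_sd edge noise SD passed to [simulate_edges()].
#' @param threshold edge-selection significance threshold.
#' @return calibrated `beta` (edge-weight units per behavior SD).
#' @export
beta_for_prediction_r <- function(target_r, n, k, n_nodes, noise_sd = 1,
                                  threshold = 0.01) {
  stopifnot_scalar_prob(threshold, "threshold")
  if (target_r <= 0 || target_r >= 1) stop("'target_r' must be in (0,1)", call. = FALSE)
  E <- n_edges(n_nodes)
  zc <- stats::qnorm(1 - threshold / 2)
  pred_r <- function(rho) {
    pow <- 1 - stats::pnorm(zc - atanh(rho) * sqrt(n - 3))
    k1 <- k * pow
    k0 <- (E - 2 * k) * threshold / 2
    b <- rho / sqrt(1 - rho^2)
    (k1 * b) / sqrt((k1 * b)^2 + k1 + k0)
  }
  f <- function(rho) pred_r(rho) - target_r
  rho <- stats::uniroot(f, c(1e-4, 0.95), tol = 1e-10)$root
  noise_sd * rho / sqrt(1 - rho^2)
}

#' Monte Carlo refinement of the planted-effect calibration
#'
#' [beta_for_prediction_r()] is a closed-form approximation; because it
#' ignores fold-to-fold heterogeneity of the selected networks it
#' undershoots the realized cross-validated prediction correlation by
#' 10-20%. This routine tunes `beta` so that the *realized* mean
#' cross-validated `r(actual, predicted)` (averaged over both tails and
#' `n_rep` fresh simulated cohorts) matches `target_r`: starting from the
#' analytic solution, it rescales `beta` along the analytic response curve
#' using the measured mean, iterating `n_iter` times. Deterministic given
#' `seed`.
#'
#' @inheritParams beta_for_prediction_r
#' @param n_families families in the simulated calibration cohorts.
#' @param n_rep simulated cohorts per evaluation (default 8).
#' @param n_iter correction iterations (default 2).
#' @param seed integer seed for the calibration simulations.
#' @return tuned `beta`, with the analytic start and the measured mean
#'   prediction r attached as attributes `analytic_beta` and `realized_r`.
#' @export
tune_beta_cv <- function(target_r, n, k, n_nodes, n_families = NULL,
                         noise_sd = 1, threshold = 0.01,
                         n_rep = 8, n_iter = 2, seed = 1) {
  if (is.null(n_families)) n_families <- max(2L, n %/% 2L)
  beta0 <- beta_for_prediction_r(target_r, n, k, n_nodes, noise_sd, threshold)
  # analytic expected r as a function of beta (inverse of the calibration)
  E <- n_edges(n_nodes)
  zc <- stats::qnorm(1 - threshold / 2)
  analytic_r <- function(beta) {
    b <- beta / noise_sd
    rho <- b / sqrt(1 + b^2)
    pow <- 1 - stats::pnorm(zc - atanh(rho) * sqrt(n - 3))
    k1 <- k * pow
    k0 <- (E - 2 * k) * threshold / 2
    (k1 * b) / sqrt((k1 * b)^2 + k1 + k0)
  }
  measure <- function(beta, stage) {
    mean(vapply(seq_len(n_rep), function(i) {
      s <- sub_seed(seed, 100L * stage + i)
      coh <- simulate_cohort(n, n_families = n_families, seed = s)
      sim <- simulate_edges(coh, n_nodes, k, k, beta = beta,
                            noise_sd = noise_sd, seed = s)
      cv <- cpm_cv(sim$edges, coh$behavior, coh$family_id, threshold = threshold)
      mean(cv$r, na.rm = TRUE)
    }, numeric(1)))
  }
  beta <- beta0
  realized <- NA_real_
  for (it in seq_len(n_iter)) {
    realized <- measure(beta, it)
    if (!is.finite(realized) || realized <= 0) break
    # move the analytic operating point by the measured shortfall
    target_adj <- target_r * analytic_r(beta) / realized
    target_adj <- min(max(target_adj, 0.02), 0.95)
    f <- function(b) analytic_r(b) - target_adj
    beta <- stats::uniroot(f, c(1e-6, noise_sd * 10), tol = 1e-10)$root
  }
  structure(beta, analytic_beta = beta0, realized_r = realized)
}
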