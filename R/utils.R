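# Internal helpers: seeded RNG scoping and argument checks.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All exported generators route through
# this, so they are pure functions of their arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one user-facing seed into per-stage sub-seeds.
# stage is a small integer counter (1 = cohort, 2 = edges, 3 = time series,
# 4 = permutations, ...); the affine map keeps distinct stages on distinct
# streams while staying inside the 32-bit integer range set.seed() accepts.
sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1103L + 7919L * stage) %% 2147483647)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("'%s' must be a single number strictly between 0 and 1", name),
         call. = FALSE)
  }
}

as_edge_matrix_input <- function(edges) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "double"
  edges
}
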