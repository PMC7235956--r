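neo_factors <- c("neuroticism", "extraversion", "openness",
                 "agreeableness", "conscientiousness")

neo_labels <- c("strongly disagree" = 0, "disagree" = 1,
                "neither agree nor disagree" = 2, "agree" = 3,
                "strongly agree" = 4)

#' Synthetic NEO-FFI item key
#'
#' The real instrument's item-to-factor assignment and reverse-coded item
#' list are copyrighted, so the scoring key is always a user-supplied input.
#' This helper builds a synthetic but structurally valid key (60 items, 12
#' per factor, a chosen number reverse-coded per factor) for testing and
#' examples; it does **not** reproduce the real questionnaire.
#'
#' @param n_reverse_per_factor reverse-coded items per factor (0-12).
#' @return data.frame with columns `item_id`, `factor`, `reverse`.
#' @export
synthetic_neo_key <- function(n_reverse_per_factor = 4) {
  if (n_reverse_per_factor < 0 || n_reverse_per_factor > 12) {
    stop("'n_reverse_per_factor' must be between 0 and 12", call. = FALSE)
  }
  fac <- rep(neo_factors, each = 12L)
  rev <- unlist(lapply(neo_factors, function(f) {
    c(rep(TRUE, n_reverse_per_factor), rep(FALSE, 12L - n_reverse_per_factor))
  }))
  data.frame(item_id = 1:60, factor = fac, reverse = rev,
             stringsAsFactors = FALSE)
}

check_neo_key <- function(key) {
  key <- as.data.frame(key)
  need <- c("item_id", "factor", "reverse")
  if (!all(need %in% names(key))) {
    stop("key needs columns item_id, factor, reverse", call. = FALSE)
  }
  if (nrow(key) != 60L || !setequal(key$item_id, 1:60)) {
    stop("key must cover items 1-60 exactly once", call. = FALSE)
  }
  if (!all(key$factor %in% neo_factors)) {
    stop(sprintf("unknown factor name(s): %s",
                 paste(setdiff(unique(key$factor), neo_factors), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(table(key$factor) == 12L)) {
    stop("each factor must have exactly 12 items", call. = FALSE)
  }
  key$reverse <- as.logical(key$reverse)
  key[order(key$item_id), ]
}

#' Score 60-item NEO-FFI responses into five factor totals
#'
#' Items are answered on a five-point Likert scale coded strongly
#' disagree = 0, disagree = 1, neither agree nor disagree = 2, agree = 3,
#' strongly agree = 4. Reverse-coded items contribute `4 - raw`; each factor
#' total is the sum of its 12 item scores, so totals lie in 0-48. Subjects
#' with any missing item are flagged for exclusion (their totals are `NA`),
#' mirroring the exclusion of participants with incomplete item-level data.
#'
#' @param responses `n x 60` matrix or data.frame of integer codes 0-4 or
#'   the five response labels; columns are items 1-60 in order (or named
#'   `item_1` ... `item_60`).
#' @param key item key data.frame with columns `item_id`, `factor`,
#'   `reverse` (see [synthetic_neo_key()]).
#' @return data.frame with one column per factor (integer totals) and a
#'   logical `excluded` column for subjects with missing items.
#' @examples
#' key <- synthetic_neo_key(0)
#' resp <- matrix(3L, 2, 60)  # every answer "agree"
#' score_neo_ffi(resp, key)   # all totals = 36
#' @export
score_neo_ffi <- function(responses, key) {
  key <- check_neo_key(key)
  resp <- as.matrix(as.data.frame(responses))
  if (ncol(resp) != 60L) stop("responses must have 60 item columns", call. = FALSE)
  if (is.character(resp)) {
    lab <- tolower(trimws(resp))
    bad <- !is.na(lab) & !(lab %in% names(neo_labels))
    if (any(bad)) {
      stop(sprintf("unrecognized response label(s): %s",
                   paste(unique(lab[bad]), collapse = ", ")), call. = FALSE)
    }
    num <- matrix(neo_labels[lab], nrow(resp), 60L)
  } else {
    num <- resp
    storage.mode(num) <- "double"
    bad <- !is.na(num) & (num < 0 | num > 4 | num != round(num))
    if (any(bad)) {
      stop("responses must be integer codes in 0..4 (or the five scale labels)",
           call. = FALSE)
    }
  }
  # reverse-coded items contribute 4 - raw
  revcols <- key$reverse
  num[, revcols] <- 4 - num[, revcols]
  excluded <- apply(num, 1L, anyNA)
  totals <- sapply(neo_factors, function(f) {
    as.integer(rowSums(num[, key$factor == f, drop = FALSE]))
  })
  totals <- as.data.frame(matrix(totals, nrow = nrow(num),
                                 dimnames = list(NULL, neo_factors)))
  totals$excluded <- excluded
  totals
}

#' Load and validate a cohort phenotype table
#'
#' Reads a headered CSV with one row per subject and validates it for a CPM
#' run: subject IDs must be unique, the requested columns present, and rows
#' with missing required values are dropped with a reported count.
#'
#' @param path CSV file path.
#' @param required columns that must be present and complete (beyond
#'   `subject_id`); defaults to `"behavior"`.
#' @param need_family require a `family_id` column (for family-aware CV).
#' @return validated data.frame; the number of dropped rows is attached as
#'   attribute `n_excluded` and reported via a message.
#' @export
load_cohort <- function(path, required = "behavior", need_family = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("cohort file is empty", call. = FALSE)
  if (!"subject_id" %in% names(df)) stop("missing 'subject_id' column", call. = FALSE)
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup)) {
    stop(sprintf("duplicate subject ID(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  if (need_family && !"family_id" %in% names(df)) {
    stop("missing 'family_id' column (required for family-aware cross-validation)",
         call. = FALSE)
  }
  cols <- c("subject_id", if (need_family) "family_id", required)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  complete <- stats::complete.cases(df[, cols, drop = FALSE])
  n_excl <- sum(!complete)
  if (n_excl > 0L) {
    message(sprintf("load_cohort: excluded %d subject(s) with incomplete data; %d remain",
                    n_excl, sum(complete)))
    df <- df[complete, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no complete rows remain", call. = FALSE)
  rownames(df) <- NULL
  attr(df, "n_excluded") <- n_excl
  df
}
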