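# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||%
#' @importFrom stats setNames
NULL

# Run `code` under a local, restored RNG state seeded with `seed`.
local_seed_eval <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Canonical column names a corpus tibble may carry.
.corpus_unit_levels <- c("day", "bout", "word", "utterance")
.corpus_required <- c("individual", "sequence", "element")

# Validate a corpus tibble: required columns, non-missing labels, and
# non-decreasing onsets within each sequence. Returns the tibble invisibly
# coerced to a plain tibble.
validate_corpus <- function(corpus, require_times = FALSE, call = rlang::caller_env()) {
  if (!is.data.frame(corpus)) {
    abort("`corpus` must be a data frame with one row per vocal element.", call = call)
  }
  missing_cols <- setdiff(.corpus_required, names(corpus))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`corpus` is missing required column(s): ",
      paste0("`", missing_cols, "`", collapse = ", "), "."
    ), call = call)
  }
  if (nrow(corpus) == 0) {
    abort("`corpus` must contain at least one element.", call = call)
  }
  if (anyNA(corpus$element)) {
    abort("`element` labels must not be missing.", call = call)
  }
  if (require_times && !all(c("onset", "offset") %in% names(corpus))) {
    if (!"onset" %in% names(corpus)) {
      abort("This operation needs element times: `onset` column is absent.", call = call)
    }
  }
  if ("onset" %in% names(corpus)) {
    bad <- corpus |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(ok = !is.unsorted(.data$onset, na.rm = TRUE), .groups = "drop")
    if (!all(bad$ok)) {
      abort(paste0(
        "Onset times must be non-decreasing within each sequence; violated in: ",
        paste(utils::head(bad$sequence[!bad$ok], 3), collapse = ", "), "."
      ), call = call)
    }
  }
  tibble::as_tibble(corpus)
}

# Convert a corpus tibble into a list of integer-coded sequences plus the
# label alphabet. Order of rows within a sequence is preserved; sequences
# appear in order of first occurrence.
corpus_to_int <- function(corpus) {
  seq_f <- factor(corpus$sequence, levels = unique(corpus$sequence))
  labels <- sort(unique(as.character(corpus$element)))
  codes <- match(as.character(corpus$element), labels)
  list(
    seqs = split(codes, seq_f),
    labels = labels
  )
}

# Draw one Dirichlet(concentration) vector of length k via gamma variates.
rdirichlet1 <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration, rate = 1)
  while (sum(g) <= 0) { # numerically possible for tiny concentration
    g <- stats::rgamma(k, shape = concentration, rate = 1)
  }
  g / sum(g)
}

# k x k column-stochastic matrix with independent Dirichlet columns.
rdirichlet_matrix <- function(k, concentration) {
  m <- vapply(seq_len(k), function(j) rdirichlet1(k, concentration), numeric(k))
  matrix(m, nrow = k, ncol = k)
}

# Is every state reachable from every other (single communicating class)?
is_ergodic <- function(transition, tol = 0) {
  k <- ncol(transition)
  adj <- transition > tol
  reach <- diag(TRUE, k) | adj
  for (i in seq_len(ceiling(log2(k)) + 1)) {
    reach <- reach | (reach %*% reach) > 0
  }
  all(reach)
}

# Stationary distribution of a column-stochastic matrix.
stationary_distribution <- function(transition) {
  eig <- eigen(transition)
  i <- which.min(abs(eig$values - 1))
  v <- Re(eig$vectors[, i])
  v / sum(v)
}
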