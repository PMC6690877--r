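#' Grassberger entropy estimate in bits
#'
#' Finite-sample entropy estimator
#' \deqn{\hat S = \ln N - \frac{1}{N} \sum_i N_i \psi(N_i)}
#' (in nats, converted to bits by dividing by \eqn{\ln 2}), where
#' \eqn{\psi} is the digamma function, \eqn{N_i} the count of category
#' \eqn{i}, and \eqn{N = \sum_i N_i}. The digamma correction reduces the
#' downward bias of the plug-in entropy under finite sampling; the estimate
#' converges to the plug-in value as \eqn{N \to \infty}.
#'
#' @param counts Numeric vector of category counts; zero counts are
#'   dropped (absent categories carry no weight in the estimator).
#' @return Entropy estimate in bits (non-negative for any count vector
#'   with all counts at least 1).
#' @examples
#' grassberger_entropy(c(A = 500, B = 500)) # close to 1 bit
#' @export
grassberger_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    abort("`counts` must contain at least one positive count.")
  }
  n <- sum(counts)
  s_nats <- log(n) - sum(counts * digamma(counts)) / n
  max(s_nats, 0) / log(2)
}

#' Distribution of element pairs at a sequential distance
#'
#' For every sequence of length `L` the pairs `(element[i], element[i + d])`
#' for `i = 1, ..., L - d` are collected; pairs never cross sequence
#' boundaries. For example, the sequence `a, b, c, d, e` contributes the
#' pairs `(a,c), (b,d), (c,e)` at distance 2.
#'
#' @param corpus A corpus tibble (or any data frame with `sequence` and
#'   `element` columns).
#' @param d Positive integer sequential distance.
#' @return A list of class `pair_sample` with elements `distance`,
#'   `x_counts`, `y_counts` (named count vectors over labels),
#'   `joint_counts` (labels-by-labels count matrix) and `n_pairs`.
#' @export
pairs_at_distance <- function(corpus, d) {
  corpus <- validate_corpus(corpus)
  if (!is.numeric(d) || length(d) != 1 || d < 1 || d != round(d)) {
    abort("`d` must be a single positive integer.")
  }
  enc <- corpus_to_int(corpus)
  counts <- pair_counts_int(enc$seqs, as.integer(d), length(enc$labels))
  k <- length(enc$labels)
  joint <- matrix(counts$joint, nrow = k, ncol = k,
                  dimnames = list(x = enc$labels, y = enc$labels))
  structure(
    list(
      distance = as.integer(d),
      x_counts = setNames(counts$x, enc$labels),
      y_counts = setNames(counts$y, enc$labels),
      joint_counts = joint,
      n_pairs = counts$n
    ),
    class = "pair_sample"
  )
}

# Fast pair counting on integer-coded sequences. Returns joint counts in
# column-major (x, y) order, marginals, and the pair count.
pair_counts_int <- function(seqs, d, k) {
  xs <- vector("list", length(seqs))
  ys <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    L <- length(s)
    if (L > d) {
      xs[[i]] <- s[seq_len(L - d)]
      ys[[i]] <- s[(d + 1L):L]
    }
  }
  x <- unlist(xs, use.names = FALSE)
  if (is.null(x)) {
    return(list(joint = numeric(k * k), x = numeric(k), y = numeric(k), n = 0L))
  }
  y <- unlist(ys, use.names = FALSE)
  joint <- tabulate((y - 1L) * k + x, nbins = k * k)
  jm <- matrix(joint, nrow = k, ncol = k)
  list(joint = joint, x = rowSums(jm), y = colSums(jm), n = length(x))
}

# MI in bits from raw count tables.
mi_from_counts <- function(counts) {
  grassberger_entropy(counts$x) + grassberger_entropy(counts$y) -
    grassberger_entropy(counts$joint)
}

#' Mutual information between paired elements
#'
#' Estimates \eqn{\hat I(X, Y) = \hat S(X) + \hat S(Y) - \hat S(X, Y)} in
#' bits, with each entropy computed by [grassberger_entropy()]. The
#' estimate can be slightly negative through estimator noise.
#'
#' @param pairs A `pair_sample` from [pairs_at_distance()].
#' @return Mutual information estimate in bits.
#' @export
mutual_information <- function(pairs) {
  if (!inherits(pairs, "pair_sample")) {
    abort("`pairs` must be a pair_sample from pairs_at_distance().")
  }
  if (pairs$n_pairs < 2) {
    abort("Mutual information is undefined for fewer than 2 pairs.")
  }
  grassberger_entropy(pairs$x_counts) + grassberger_entropy(pairs$y_counts) -
    grassberger_entropy(as.vector(pairs$joint_counts))
}

#' Shuffled-baseline mutual information at a distance
#'
#' Computes the mutual information of pairs at distance `d` after
#' independently permuting the element order of every sequence. Because a
#' finite-sample MI estimate is biased upward even for independent
#' variables, this permutation baseline estimates the lower bound that is
#' subtracted from the raw estimate to give the corrected MI.
#'
#' @inheritParams pairs_at_distance
#' @param n_reps Number of independent shuffle replicates to average.
#' @param seed Integer seed.
#' @return Mean shuffled MI in bits across replicates.
#' @export
shuffled_baseline <- function(corpus, d, n_reps = 1, seed = 1) {
  corpus <- validate_corpus(corpus)
  enc <- corpus_to_int(corpus)
  k <- length(enc$labels)
  vals <- local_seed_eval(seed, {
    vapply(seq_len(n_reps), function(r) {
      shuf <- lapply(enc$seqs, function(s) s[sample.int(length(s))])
      counts <- pair_counts_int(shuf, as.integer(d), k)
      if (counts$n < 2) {
        abort("Shuffled baseline undefined: fewer than 2 pairs at this distance.")
      }
      mi_from_counts(counts)
    }, numeric(1))
  })
  mean(vals)
}

#' Shuffle-corrected mutual information decay curve
#'
#' For each sequential distance `d = 1, ..., max_distance` this computes
#' the raw Grassberger-estimated mutual information between elements at
#' that distance, a shuffled baseline (each sequence independently
#' permuted, averaged over `n_reps` replicates), and the corrected MI
#' `mi = mi_raw - mi_shuffled`. Distances supported by fewer than
#' `min_pairs` pairs are dropped, since entropy estimates on very few
#' pairs are dominated by bias.
#'
#' @inheritParams pairs_at_distance
#' @param max_distance Largest sequential distance, default 100.
#' @param n_reps Shuffle replicates per distance, default 1.
#' @param seed Integer seed for the shuffles.
#' @param min_pairs Minimum number of pairs needed to retain a distance,
#'   default 30.
#' @return A tibble of class `mi_decay` with columns `distance`,
#'   `n_pairs`, `mi_raw`, `mi_shuffled` and `mi` (all MI values in bits),
#'   carrying attributes `seed`, `n_reps`, `min_pairs`, `alphabet_size`
#'   and `n_elements`.
#' @examples
#' g <- random_markov_grammar(4, seed = 2, length = 60, n_sequences = 20)
#' mi_decay_curve(sample_corpus(g), max_distance = 10, seed = 1)
#' @export
mi_decay_curve <- function(corpus, max_distance = 100, n_reps = 1, seed = 1,
                           min_pairs = 30) {
  corpus <- validate_corpus(corpus)
  if (max_distance < 1) abort("`max_distance` must be at least 1.")
  enc <- corpus_to_int(corpus)
  k <- length(enc$labels)
  ds <- seq_len(max_distance)

  raw <- compute_mi_profile(enc$seqs, ds, k)
  sh <- local_seed_eval(seed, {
    reps <- vapply(seq_len(n_reps), function(r) {
      shuf <- lapply(enc$seqs, function(s) s[sample.int(length(s))])
      compute_mi_profile(shuf, ds, k)$mi
    }, numeric(length(ds)))
    rowMeans(matrix(reps, nrow = length(ds)))
  })

  out <- tibble::tibble(
    distance = as.integer(ds),
    n_pairs = raw$n_pairs,
    mi_raw = raw$mi,
    mi_shuffled = sh,
    mi = raw$mi - sh
  )
  out <- dplyr::filter(out, .data$n_pairs >= min_pairs)
  if (nrow(out) == 0) {
    abort("No distance has enough pairs; lower `min_pairs` or provide longer sequences.")
  }
  new_mi_decay(out, seed = seed, n_reps = n_reps, min_pairs = min_pairs,
               alphabet_size = k, n_elements = nrow(corpus))
}

new_mi_decay <- function(data, seed, n_reps, min_pairs, alphabet_size, n_elements) {
  structure(
    data,
    seed = seed, n_reps = n_reps, min_pairs = min_pairs,
    alphabet_size = alphabet_size, n_elements = n_elements,
    class = c("mi_decay", class(tibble::tibble()))
  )
}

# Raw MI at each distance for a list of integer sequences.
compute_mi_profile <- function(seqs, ds, k) {
  mi <- numeric(length(ds))
  n_pairs <- integer(length(ds))
  for (i in seq_along(ds)) {
    counts <- pair_counts_int(seqs, ds[i], k)
    n_pairs[i] <- counts$n
    mi[i] <- if (counts$n >= 2) mi_from_counts(counts) else NA_real_
  }
  list(mi = mi, n_pairs = n_pairs)
}

#' Write / read an MI decay curve as TSV
#'
#' @param curve An `mi_decay` tibble.
#' @param path Output path.
#' @return `path` (write) or an `mi_decay` tibble (read), invisibly for
#'   the writer.
#' @export
write_mi_curve <- function(curve, path) {
  readr::write_tsv(tibble::as_tibble(curve), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_mi_curve
#' @export
read_mi_curve <- function(path) {
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("distance", "n_pairs", "mi_raw", "mi_shuffled", "mi")
  if (!all(needed %in% names(data))) {
    abort(paste0("Curve file must have columns: ", paste(needed, collapse = ", "), "."))
  }
  new_mi_decay(data, seed = NA_integer_, n_reps = NA_integer_,
               min_pairs = NA_integer_, alphabet_size = NA_integer_,
               n_elements = NA_integer_)
}
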