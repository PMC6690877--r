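# Small corpus builders shared across the test files.

toy_corpus <- function(elements, individual = "b1", sequence = individual,
                       onset = NULL, offset = NULL, ...) {
  out <- tibble::tibble(
    individual = individual, sequence = sequence,
    element = as.character(elements)
  )
  if (!is.null(onset)) out$onset <- onset
  if (!is.null(offset)) out$offset <- offset
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# Independent plug-in implementation of the bias-corrected entropy, used
# as the direct-formula oracle against the package's estimator.
oracle_grassberger <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  (log(n) - sum(counts * digamma(counts)) / n) / log(2)
}

# Combined-grammar corpus at the structural parameters used throughout
# the simulation studies (5-state hierarchy, q = 2, Markov subsequences
# of 2-5 elements over 25 states).
combined_test_corpus <- function(n_sequences, depth = 12, seed = c(61, 62, 63)) {
  gh <- copy_hierarchical_grammar(5, q = 2, depth = depth,
                                  n_sequences = n_sequences, seed = seed[1])
  gm <- random_markov_grammar(25, seed = seed[2], length = 10, n_sequences = 5)
  sample_corpus(combined_grammar(gh, gm, c(2, 5), seed = seed[3]))
}
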