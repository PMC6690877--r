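test_that("grammar constructors validate their specifications", {
  bad <- matrix(c(0.5, 0.4, 0.5, 0.6), 2) # first column sums to 0.9
  expect_error(markov_grammar(bad, 10, 1, 1), "sum to 1")
  expect_error(random_markov_grammar(1, seed = 1), "at least 2")
  expect_error(hierarchical_grammar(diag(2), q = 1, depth = 2,
                                    n_sequences = 1, seed = 1), "q")
  g <- random_markov_grammar(4, seed = 7)
  expect_error(combined_grammar(g, g, seed = 1), "hierarchical_grammar")
})

test_that("random Markov grammars are seeded, stochastic, and concentration-sensitive", {
  g1 <- random_markov_grammar(6, seed = 3)
  g2 <- random_markov_grammar(6, seed = 3)
  expect_identical(g1$transition, g2$transition)
  expect_equal(colSums(g1$transition), rep(1, 6), tolerance = 1e-12)
  expect_true(all(g1$transition >= 0))

  # smaller concentration -> sparser columns -> lower mean column entropy
  col_entropy <- function(m) {
    mean(apply(m, 2, function(p) { p <- p[p > 0]; -sum(p * log2(p)) }))
  }
  h_small <- vapply(1:100, function(s)
    col_entropy(random_markov_grammar(8, 0.1, seed = s)$transition), numeric(1))
  h_large <- vapply(1:100, function(s)
    col_entropy(random_markov_grammar(8, 10, seed = s)$transition), numeric(1))
  expect_lt(mean(h_small), mean(h_large))
})

test_that("sample_corpus is bit-identical for identical grammar and seed", {
  gm <- random_markov_grammar(5, seed = 2, length = 30, n_sequences = 4)
  expect_identical(sample_corpus(gm), sample_corpus(gm))

  gh <- random_hierarchical_grammar(4, q = 2, depth = 5, n_sequences = 3, seed = 5)
  expect_identical(sample_corpus(gh), sample_corpus(gh))

  gc <- combined_grammar(
    copy_hierarchical_grammar(4, q = 2, depth = 4, n_sequences = 3, seed = 6),
    random_markov_grammar(8, seed = 7, length = 10, n_sequences = 8),
    c(2, 5), seed = 8
  )
  expect_identical(sample_corpus(gc), sample_corpus(gc))
})

test_that("a permutation transition matrix generates a deterministic cycle", {
  m <- matrix(c(0, 1, 1, 0), 2) # always switch state
  g <- markov_grammar(m, length = 50, n_sequences = 1, seed = 1,
                      states = c("A", "B"))
  x <- sample_corpus(g)$element
  expect_true(all(x[-1] != x[-length(x)]))
})

test_that("sampled Markov transition frequencies reproduce the matrix", {
  g <- random_markov_grammar(4, concentration = 1, seed = 9,
                             length = 1000, n_sequences = 100)
  co <- sample_corpus(g)
  enc <- midecay:::corpus_to_int(co)
  emp <- matrix(0, 4, 4)
  for (s in enc$seqs) {
    for (i in seq_len(length(s) - 1)) emp[s[i + 1], s[i]] <- emp[s[i + 1], s[i]] + 1
  }
  emp <- sweep(emp, 2, colSums(emp), "/")
  # states are relabelled alphabetically on encode; sXX order matches
  expect_lt(max(abs(emp - g$transition)), 0.02)
})

test_that("long-run Markov label frequencies converge to the stationary distribution", {
  g <- random_markov_grammar(5, concentration = 1, seed = 4,
                             length = 10000, n_sequences = 100)
  co <- sample_corpus(g)
  emp <- as.numeric(table(factor(co$element, levels = g$states))) / nrow(co)
  pi0 <- midecay:::stationary_distribution(g$transition)
  expect_lt(0.5 * sum(abs(emp - pi0)), 0.01)
})

test_that("hierarchical sampling yields q^depth elements per sequence", {
  g0 <- random_hierarchical_grammar(3, q = 2, depth = 0, n_sequences = 2, seed = 1)
  expect_equal(as.vector(table(sample_corpus(g0)$sequence)), c(1, 1))

  g2 <- random_hierarchical_grammar(3, q = 3, depth = 2, n_sequences = 2, seed = 1)
  expect_true(all(table(sample_corpus(g2)$sequence) == 9))

  g12 <- random_hierarchical_grammar(5, q = 2, depth = 12, n_sequences = 2, seed = 1)
  expect_true(all(table(sample_corpus(g12)$sequence) == 4096))
})

test_that("copy-model replacement matrices have a degenerate subdominant spectrum", {
  g <- copy_hierarchical_grammar(5, q = 2, depth = 3, n_sequences = 1,
                                 seed = 1, alpha = 0.7)
  ev <- sort(abs(eigen(g$replacement, only.values = TRUE)$values), decreasing = TRUE)
  expect_equal(ev, c(1, rep(0.7, 4)), tolerance = 1e-12)
})

test_that("combined sampling substitutes fixed subsequences for end states", {
  gh <- copy_hierarchical_grammar(5, q = 2, depth = 6, n_sequences = 4, seed = 2)
  gm <- random_markov_grammar(25, seed = 3, length = 10, n_sequences = 5)
  co <- sample_corpus(combined_grammar(gh, gm, c(2, 5), seed = 4))
  lens <- table(co$sequence)
  expect_true(all(lens >= 2 * 64 & lens <= 5 * 64))
  expect_true(all(co$element %in% gm$states))
  # each word is one substituted subsequence of 2-5 elements
  expect_true(all(table(co$word) %in% 2:5))
  # every occurrence of a given subsequence id has identical content:
  # words map deterministically to end states, so at most 5 distinct
  # word-content strings exist
  word_str <- tapply(co$element, co$word, paste, collapse = "")
  expect_lte(length(unique(word_str)), 5)

  # degenerate subsequence length [1,1]: output is a relabelled
  # hierarchical sequence of exactly q^depth elements
  co1 <- sample_corpus(combined_grammar(gh, gm, c(1, 1), seed = 4))
  expect_true(all(table(co1$sequence) == 64))
})

test_that("grammar specifications round-trip through JSON", {
  path <- file.path(tempdir(), "g.json")
  gm <- random_markov_grammar(4, seed = 11, length = 20, n_sequences = 3)
  write_grammar(gm, path)
  back <- read_grammar(path)
  expect_equal(back$transition, gm$transition, tolerance = 1e-12)
  expect_identical(sample_corpus(back), sample_corpus(gm))

  gc <- combined_grammar(
    copy_hierarchical_grammar(3, q = 2, depth = 3, n_sequences = 2, seed = 12),
    gm, c(2, 4), seed = 13
  )
  write_grammar(gc, path)
  expect_identical(sample_corpus(read_grammar(path)), sample_corpus(gc))
})
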