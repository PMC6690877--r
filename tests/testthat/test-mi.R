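test_that("Grassberger entropy matches the direct formula and analytic limits", {
  # single category: entropy -> 0 as N grows, ~ 1/(2N ln 2) at N = 1000
  expect_equal(grassberger_entropy(1000), (log(1000) - digamma(1000)) / log(2),
               tolerance = 1e-12)
  expect_lt(grassberger_entropy(1000), 1e-3)

  # uniform 2- and 4-category counts: within 0.002 bits of 1 and 2 bits
  expect_equal(grassberger_entropy(c(A = 500, B = 500)), 1, tolerance = 0.002)
  expect_equal(grassberger_entropy(rep(1000, 4)), 2, tolerance = 0.002)

  # agrees with an independently coded oracle on arbitrary counts
  withr::with_seed(1, {
    for (i in 1:5) {
      counts <- rpois(10, 50) + 1
      expect_equal(grassberger_entropy(counts), oracle_grassberger(counts),
                   tolerance = 1e-12)
    }
  })
  expect_error(grassberger_entropy(numeric()), "positive count")
  expect_error(grassberger_entropy(c(0, 0)), "positive count")
})

test_that("Grassberger converges to the plug-in entropy for large samples", {
  counts <- rep(1e5, 10)
  expect_lt(abs(grassberger_entropy(counts) - log2(10)), 1e-3)
})

test_that("pairs_at_distance enumerates within-sequence pairs only", {
  co <- toy_corpus(c("a", "b", "c", "d", "e"))
  p <- pairs_at_distance(co, 2)
  expect_equal(p$n_pairs, 3)
  expect_equal(unname(p$joint_counts["a", "c"]), 1)
  expect_equal(unname(p$joint_counts["b", "d"]), 1)
  expect_equal(unname(p$joint_counts["c", "e"]), 1)
  expect_equal(sum(p$joint_counts), 3)

  # distance 3 pairs the first and fourth element
  p3 <- pairs_at_distance(toy_corpus(c("A", "B", "C", "D")), 3)
  expect_equal(p3$n_pairs, 1)
  expect_equal(unname(p3$joint_counts["A", "D"]), 1)

  # pairs never cross sequence boundaries
  two <- toy_corpus(rep(c("a", "b"), 2), sequence = rep(c("s1", "s2"), each = 2))
  expect_equal(pairs_at_distance(two, 1)$n_pairs, 2)
  expect_equal(pairs_at_distance(two, 3)$n_pairs, 0)

  # marginals of the joint equal the per-side counts
  withr::with_seed(2, {
    co <- toy_corpus(sample(letters[1:4], 200, replace = TRUE))
    p <- pairs_at_distance(co, 5)
    expect_equal(rowSums(p$joint_counts), p$x_counts)
    expect_equal(colSums(p$joint_counts), p$y_counts)
    expect_equal(sum(p$x_counts), p$n_pairs)
  })

  expect_error(pairs_at_distance(co, 0), "positive integer")
})

test_that("mutual information is exact for coupled pairs, near zero for independent ones", {
  coupled <- toy_corpus(rep(c("a", "a", "b", "b"), 250)) # d=2: always (a,a)/(b,b)
  p <- pairs_at_distance(coupled, 2)
  expect_equal(mutual_information(p), grassberger_entropy(p$x_counts),
               tolerance = 1e-12)
  expect_equal(mutual_information(p), 1, tolerance = 0.01)

  withr::with_seed(3, {
    iid <- toy_corpus(sample(letters[1:5], 1e5, replace = TRUE))
    expect_lt(abs(mutual_information(pairs_at_distance(iid, 1))), 0.01)
  })

  expect_error(mutual_information(pairs_at_distance(toy_corpus("a"), 1)),
               "fewer than 2")
})

test_that("mutual information is symmetric in X and Y", {
  withr::with_seed(4, {
    co <- toy_corpus(sample(letters[1:3], 500, replace = TRUE))
  })
  p <- pairs_at_distance(co, 2)
  swapped <- structure(
    list(distance = p$distance, x_counts = p$y_counts, y_counts = p$x_counts,
         joint_counts = t(p$joint_counts), n_pairs = p$n_pairs),
    class = "pair_sample"
  )
  expect_equal(mutual_information(p), mutual_information(swapped),
               tolerance = 1e-12)
})

test_that("lag-1 MI of a symmetric two-state chain matches the closed form", {
  flip <- 0.1
  fx <- make_fixtures(1)
  p <- pairs_at_distance(fx$markov2, 1)
  target <- 1 - (-(1 - flip) * log2(1 - flip) - flip * log2(flip))
  expect_equal(mutual_information(p), target, tolerance = 0.02)
})

test_that("corrected MI decays with the squared subdominant eigenvalue of the chain", {
  flip <- 0.1
  m2 <- matrix(c(1 - flip, flip, flip, 1 - flip), 2)
  g <- markov_grammar(m2, length = 10000, n_sequences = 100, seed = 5,
                      states = c("A", "B"))
  cu <- mi_decay_curve(sample_corpus(g), max_distance = 10, seed = 1)
  # log2 MI falls by 2 log2(1 - 2p) per unit distance
  slope <- coef(lm(log2(mi) ~ distance, data = cu[3:8, ]))[[2]]
  expect_equal(slope, 2 * log2(1 - 2 * flip), tolerance = 0.05 * abs(2 * log2(0.8)))
})

test_that("shuffled baseline is seeded and undefined without pairs", {
  fx <- make_fixtures(1)
  co <- dplyr::slice_head(dplyr::group_by(fx$markov2, sequence), n = 50)
  b1 <- shuffled_baseline(co, 2, n_reps = 3, seed = 9)
  b2 <- shuffled_baseline(co, 2, n_reps = 3, seed = 9)
  expect_identical(b1, b2)
  expect_false(identical(b1, shuffled_baseline(co, 2, n_reps = 3, seed = 10)))

  singles <- toy_corpus(c("a", "b"), sequence = c("s1", "s2"))
  expect_error(shuffled_baseline(singles, 1, seed = 1), "fewer than 2 pairs")
})

test_that("corrected MI is ~1 bit at all lags for a periodic sequence and ~0 for i.i.d.", {
  fx <- make_fixtures(1)
  cup <- mi_decay_curve(fx$periodic, max_distance = 20, seed = 2)
  expect_true(all(abs(cup$mi - 1) < 0.01))

  cui <- mi_decay_curve(fx$iid, max_distance = 100, seed = 3)
  expect_equal(nrow(cui), 100)
  expect_true(all(abs(cui$mi) < 0.01))
})

test_that("mi = mi_raw - mi_shuffled and low-support distances are dropped", {
  fx <- make_fixtures(1)
  cu <- mi_decay_curve(fx$markov2, max_distance = 10, seed = 4, n_reps = 2)
  expect_equal(cu$mi, cu$mi_raw - cu$mi_shuffled, tolerance = 1e-12)

  short <- toy_corpus(rep(letters[1:4], 10)) # 40 elements
  cu2 <- mi_decay_curve(short, max_distance = 30, seed = 1, min_pairs = 30)
  expect_equal(max(cu2$distance), 10) # d = 10 leaves exactly 30 pairs
  cu3 <- mi_decay_curve(short, max_distance = 30, seed = 1, min_pairs = 5)
  expect_equal(max(cu3$distance), 30)
})

test_that("MI decay curves round-trip through TSV", {
  fx <- make_fixtures(1)
  cu <- mi_decay_curve(fx$periodic, max_distance = 5, seed = 1)
  path <- file.path(tempdir(), "curve.tsv")
  write_mi_curve(cu, path)
  back <- read_mi_curve(path)
  expect_equal(as.data.frame(back), as.data.frame(cu), tolerance = 1e-9,
               ignore_attr = TRUE)
})
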