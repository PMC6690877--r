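make_curve <- function(x, mi) tibble::tibble(distance = x, mi = mi)

test_that("eval_decay evaluates each family as written", {
  expect_equal(eval_decay(decay_model("exponential", c(a = 1, b = 0, c = 0)),
                          c(1, 10, 50)), rep(1, 3))
  expect_equal(eval_decay(decay_model("power_law", c(a = 2, b = -1, c = 0.3)), 1),
               2.3)
  comp <- decay_model("composite", c(a = 0, b = 1, c = 2, d = -1, f = 0.3))
  pow <- decay_model("power_law", c(a = 2, b = -1, c = 0.3))
  x <- c(1, 3, 17, 90)
  expect_equal(eval_decay(comp, x), eval_decay(pow, x))
  expect_error(eval_decay(pow, c(1, -2)), "positive")
  expect_error(decay_model("composite", c(a = 1, b = 1, c = 1)), "must be named")
})

test_that("noiseless curves recover their generating parameters", {
  x <- 1:100
  true_e <- c(a = 1, b = 0.25, c = 0.01)
  fe <- fit_decay(make_curve(x, 1 * exp(-0.25 * x) + 0.01), "exponential")
  expect_equal(unlist(fe$model$params), true_e, tolerance = 0.01)

  fp <- fit_decay(make_curve(x, 1 * x^-1 + 0.01), "power_law")
  expect_equal(unlist(fp$model$params), c(a = 1, b = -1, c = 0.01),
               tolerance = 0.01)
  expect_gt(fp$r2, 0.999)

  y_comp <- 0.5 * exp(-0.3 * x) + 0.2 * x^-0.8 + 0.01
  fc <- fit_decay(make_curve(x, y_comp), "composite")
  expect_equal(unlist(fc$model$params),
               c(a = 0.5, b = 0.3, c = 0.2, d = -0.8, f = 0.01),
               tolerance = 0.01)
  expect_gt(fc$r2, 0.999)
  fe2 <- fit_decay(make_curve(x, y_comp), "exponential")
  expect_lt(fe2$r2, fc$r2)
})

test_that("the composite never fits worse than its nested families", {
  x <- 1:100
  withr::with_seed(9, {
    y <- (exp(-0.15 * x) + 0.02) * exp(rnorm(100, 0, 0.05))
  })
  cmp <- fit_decay_models(make_curve(x, y))
  tab <- tibble::as_tibble(cmp)
  expect_lte(tab$rss[tab$family == "composite"],
             min(tab$rss[tab$family != "composite"]) + 1e-8)
})

test_that("fits are deterministic and exclude non-positive MI points", {
  x <- 1:60
  y <- exp(-0.1 * x) + 0.01
  y[c(10, 40)] <- -1e-5
  f1 <- fit_decay(make_curve(x, y), "exponential")
  f2 <- fit_decay(make_curve(x, y), "exponential")
  expect_identical(unlist(f1$model$params), unlist(f2$model$params))
  expect_equal(f1$n, 58)
  expect_equal(f1$n_excluded, 2)

  expect_error(fit_decay(make_curve(1:4, rep(1, 4)), "exponential"), "at least")
  expect_error(fit_decay(make_curve(1:10, rep(-1, 10)), "power_law"), "at least")
})

test_that("AICc comparison yields Akaike weights with the expected structure", {
  x <- 1:50
  fake_fit <- function(family, rss, k) {
    n <- length(x)
    structure(
      list(model = decay_model(family, setNames(rep(0.5, k),
                                                midecay:::decay_param_names(family))),
           family = family, rss = rss, r2 = 0.9,
           aicc = n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1),
           n = n, k = k, weighting = "log1p",
           points = tibble::tibble(distance = x, mi = 1, weight = 1),
           n_excluded = 0),
      class = "mi_decay_fit"
    )
  }
  # identical RSS and parameter count: each model equally probable
  cmp <- compare_models(list(fake_fit("exponential", 1, 3),
                             fake_fit("power_law", 1, 3),
                             fake_fit("power_law", 1, 3)))
  expect_equal(cmp$rel_prob, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(cmp$rel_prob), 1, tolerance = 1e-12)
  expect_equal(cmp$delta_aicc[cmp$best], 0)

  # a 2-unit AICc gap corresponds to a weight ratio of e
  rss_hi <- 1 * exp(2 / length(x)) # raises AICc by exactly 2
  cmp2 <- compare_models(list(fake_fit("exponential", 1, 3),
                              fake_fit("power_law", rss_hi, 3)))
  expect_equal(cmp2$rel_prob[1] / cmp2$rel_prob[2], exp(1), tolerance = 1e-9)

  # mismatched point sets are not comparable
  short <- fake_fit("exponential", 1, 3)
  short$points <- short$points[1:40, ]
  short$n <- 40
  expect_error(compare_models(list(fake_fit("power_law", 1, 3), short)),
               "identical point sets")
})

test_that("AICc is undefined when points barely exceed parameters", {
  expect_error(midecay:::aicc_ls(1, 4, 3), "undefined")
})

test_that("exponential data with 1% noise selects the exponential model", {
  x <- 1:100
  withr::with_seed(10, {
    y <- (exp(-0.1 * x) + 0.01) * exp(rnorm(100, 0, 0.01))
  })
  expect_equal(best_family(fit_decay_models(make_curve(x, y))), "exponential")
})

test_that("model selection is invariant under uniform rescaling of MI", {
  fx <- make_fixtures(1)
  cu <- mi_decay_curve(fx$markov2, max_distance = 30, seed = 1)
  cmp1 <- fit_decay_models(cu)
  doubled <- dplyr::mutate(tibble::as_tibble(cu), mi = 2 * mi)
  cmp2 <- fit_decay_models(doubled)
  expect_identical(best_family(cmp1), best_family(cmp2))
})

test_that("fit_range_scan restricts, reports, and isolates failures", {
  x <- 1:100
  y <- exp(-0.2 * x) + 0.05 * x^-0.5 + 0.001
  scan <- fit_range_scan(make_curve(x, y), c(5, 40, 100))
  # the 5-point range cannot support a 5-parameter fit; others are fine
  bad <- dplyr::filter(scan, max_distance == 5)
  expect_true(all(!is.na(bad$error)))
  ok <- dplyr::filter(scan, max_distance > 5)
  expect_true(all(is.na(ok$error)))
  expect_equal(nrow(ok), 6)

  # a full-range scan equals the direct comparison
  full <- fit_range_scan(make_curve(x, y), 100)
  direct <- fit_decay_models(make_curve(x, y))
  expect_equal(full$aicc, direct$aicc, tolerance = 1e-9)
  expect_equal(full$rel_prob, direct$rel_prob, tolerance = 1e-9)
})

test_that("decompose_fit splits the curve into complementary components", {
  x <- 1:50
  p <- c(a = 0.4, b = 0.2, c = 0.3, d = -0.7, f = 0.005)
  y <- 0.4 * exp(-0.2 * x) + 0.3 * x^-0.7 + 0.005
  fit <- fit_decay(make_curve(x, y), "composite")
  dec <- decompose_fit(fit, make_curve(x, y))
  expect_equal(nrow(dec), 50)
  # for an exactly fitted curve the residual curves equal the
  # complementary component plus the offset
  expect_equal(dec$mi_minus_exponential, 0.3 * x^-0.7 + 0.005, tolerance = 1e-4)
  expect_equal(dec$mi_minus_power_law, 0.4 * exp(-0.2 * x) + 0.005,
               tolerance = 1e-4)

  fe <- fit_decay(make_curve(x, y), "exponential")
  expect_error(decompose_fit(fe, make_curve(x, y)), "composite")
})

test_that("tidy and glance summarise fits and comparisons", {
  x <- 1:60
  y <- exp(-0.1 * x) + 0.01
  fit <- fit_decay(make_curve(x, y), "exponential")
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "c"))
  gl <- glance(fit)
  expect_equal(gl$family, "exponential")
  expect_equal(gl$n, 60)

  cmp <- fit_decay_models(make_curve(x, y), families = c("exponential", "power_law"))
  expect_equal(nrow(tidy(cmp)), 2)
  expect_equal(glance(cmp)$best, "exponential")
})
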