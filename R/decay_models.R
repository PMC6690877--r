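#' Decay model families for MI curves
#'
#' Three parametric families describe how mutual information decays with
#' sequential distance `x`:
#'
#' * exponential: `a * exp(-x * b) + c` — the signature of Markovian
#'   (finite-state, short-memory) sequential dynamics;
#' * power law: `a * x^b + c` (with `b <= 0`) — the signature of
#'   hierarchical, scale-free organisation;
#' * composite: `a * exp(-x * b) + c * x^d + f` — a linear combination of
#'   both, capturing sequences governed by the two processes at different
#'   scales.
#'
#' The exponential and power-law families have 3 parameters; the composite
#' has 5.
#'
#' @param family One of `"exponential"`, `"power_law"`, `"composite"`.
#' @param params Named numeric vector of parameters: `a, b, c` for the
#'   3-parameter families, `a, b, c, d, f` for the composite.
#' @return An object of class `decay_model`.
#' @examples
#' m <- decay_model("composite", c(a = 1, b = 0.5, c = 0.1, d = -0.5, f = 0))
#' eval_decay(m, c(1, 10, 100))
#' @export
decay_model <- function(family = c("exponential", "power_law", "composite"),
                        params) {
  family <- match.arg(family)
  wanted <- decay_param_names(family)
  if (!all(wanted %in% names(params))) {
    abort(paste0("`params` for the ", family, " family must be named ",
                 paste(wanted, collapse = ", "), "."))
  }
  structure(
    list(family = family, params = as.list(params[wanted])),
    class = "decay_model"
  )
}

decay_param_names <- function(family) {
  switch(family,
    exponential = c("a", "b", "c"),
    power_law = c("a", "b", "c"),
    composite = c("a", "b", "c", "d", "f")
  )
}

#' Evaluate a decay model at given distances
#'
#' @param model A [decay_model()] or an `mi_decay_fit`.
#' @param x Positive numeric distances.
#' @return Model values at `x`.
#' @export
eval_decay <- function(model, x) {
  if (inherits(model, "mi_decay_fit")) model <- model$model
  if (!inherits(model, "decay_model")) {
    abort("`model` must be a decay_model or mi_decay_fit.")
  }
  if (any(x <= 0)) abort("`x` must be positive.")
  p <- model$params
  switch(model$family,
    exponential = p$a * exp(-x * p$b) + p$c,
    power_law = p$a * x^p$b + p$c,
    composite = p$a * exp(-x * p$b) + p$c * x^p$d + p$f
  )
}

# Parameter bounds keep each component a genuine decay: amplitudes and
# offsets non-negative, exponential rates >= 0, power exponents <= 0.
decay_bounds <- function(family) {
  switch(family,
    exponential = list(lower = c(a = 0, b = 0, c = 0),
                       upper = c(a = Inf, b = Inf, c = Inf)),
    power_law = list(lower = c(a = 0, b = -Inf, c = 0),
                     upper = c(a = Inf, b = 0, c = Inf)),
    composite = list(lower = c(a = 0, b = 0, c = 0, d = -Inf, f = 0),
                     upper = c(a = Inf, b = Inf, c = Inf, d = 0, f = Inf))
  )
}

# Fixed multi-start initialisation grid (8 starts per family), scaled by
# the data: amplitude anchors at the first positive MI value, offsets at
# the smallest.
decay_inits <- function(family, y) {
  y1 <- max(y[1], 1e-6)
  ylo <- max(min(y), 1e-8)
  rates <- c(0.02, 0.1, 0.5, 1.5)
  exps <- c(-0.2, -0.6, -1.2, -2.5)
  offs <- c(ylo / 2, 1e-6)
  switch(family,
    exponential = purrr::map2(
      rep(rates, times = 2), rep(offs, each = 4),
      function(b, c) c(a = y1, b = b, c = c)
    ),
    power_law = purrr::map2(
      rep(exps, times = 2), rep(offs, each = 4),
      function(b, c) c(a = y1, b = b, c = c)
    ),
    composite = purrr::pmap(
      expand.grid(b = c(0.1, 0.8), d = c(-0.4, -1.5), split = c(0.3, 0.7)),
      function(b, d, split) {
        c(a = split * y1, b = b, c = (1 - split) * y1, d = d, f = ylo / 2)
      }
    )
  )
}

# Points usable for log-space fitting: positive MI only.
fit_points <- function(curve, weighting) {
  data <- tibble::as_tibble(curve)
  if (!all(c("distance", "mi") %in% names(data))) {
    abort("`curve` must have `distance` and `mi` columns.")
  }
  keep <- is.finite(data$mi) & data$mi > 0
  x <- data$distance[keep]
  y <- data$mi[keep]
  w <- switch(weighting,
    log1p = log(x + 1),
    log = log(x)
  )
  # Literal log weighting annihilates the d = 1 point; drop it rather than
  # carry a zero-weight observation.
  pos <- w > 0
  list(x = x[pos], y = y[pos], w = w[pos] / mean(w[pos]),
       n_excluded = sum(!keep) + sum(!pos))
}

#' Fit a decay model to an MI curve in log space
#'
#' Fits one model family to the positive corrected-MI values of a curve by
#' nonlinear least squares on the log-scale residuals
#' \deqn{r_i = w_i (\ln \mathrm{MI}_i - \ln f(x_i)),}
#' where the weights emphasise fit quality on a logarithmic distance axis
#' (distances are sampled linearly, so unweighted residuals would be
#' dominated by the long tail). The default weighting is
#' `w_i = log(x_i + 1)` normalised to mean 1, which keeps the `d = 1`
#' point in the fit; `weighting = "log"` uses the literal `log(x_i)`
#' (discarding `d = 1`, whose weight is zero). Optimisation runs
#' Levenberg-Marquardt with box bounds from a fixed grid of 8 starting
#' points; the best weighted residual sum of squares wins, with ties
#' broken by start order, so the fit is deterministic.
#'
#' @param curve An `mi_decay` tibble (or any data frame with `distance`
#'   and `mi` columns).
#' @param family Model family, see [decay_model()].
#' @param weighting `"log1p"` (default) or `"log"`.
#' @return An object of class `mi_decay_fit`: a list with the fitted
#'   [decay_model()], weighted `rss` in log space, `r2` on log-MI, `aicc`,
#'   point count `n`, parameter count `k`, the fitted points, and the
#'   number of excluded (non-positive MI or zero-weight) points.
#' @export
fit_decay <- function(curve, family = c("exponential", "power_law", "composite"),
                      weighting = c("log1p", "log")) {
  family <- match.arg(family)
  weighting <- match.arg(weighting)
  pts <- fit_points(curve, weighting)
  k <- length(decay_param_names(family))
  if (length(pts$x) < k + 2) {
    abort(paste0("Need at least ", k + 2, " positive-MI points to fit the ",
                 family, " model; have ", length(pts$x), "."))
  }
  log_y <- log(pts$y)
  resid_fn <- function(par) {
    f <- eval_decay(decay_model(family, setNames(par, decay_param_names(family))),
                    pts$x)
    pts$w * (log_y - log(pmax(f, 1e-300)))
  }
  bounds <- decay_bounds(family)
  best <- NULL
  for (start in decay_inits(family, pts$y)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = resid_fn,
        lower = bounds$lower, upper = bounds$upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(par = setNames(coef(fit), decay_param_names(family)), rss = rss)
    }
  }
  if (is.null(best)) abort(paste0("All starts failed for the ", family, " model."))
  n <- length(pts$x)
  wmean <- sum(pts$w^2 * log_y) / sum(pts$w^2)
  tss <- sum((pts$w * (log_y - wmean))^2)
  r2 <- if (tss > 0) 1 - best$rss / tss else NA_real_
  structure(
    list(
      model = decay_model(family, best$par),
      family = family,
      rss = best$rss,
      r2 = r2,
      aicc = aicc_ls(best$rss, n, length(best$par)),
      n = n,
      k = length(best$par),
      weighting = weighting,
      points = tibble::tibble(distance = pts$x, mi = pts$y, weight = pts$w),
      n_excluded = pts$n_excluded
    ),
    class = "mi_decay_fit"
  )
}

# Small-sample corrected AIC for least squares with k estimated parameters.
# A perfect (zero-residual) fit is floored at the smallest normalised
# double so AICc stays finite and comparable.
aicc_ls <- function(rss, n, k) {
  if (n <= k + 1) abort("AICc undefined: need n > k + 1 points.")
  rss <- max(rss, .Machine$double.xmin)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare fitted decay models by AICc
#'
#' Computes AICc differences and Akaike weights (relative probabilities)
#' \deqn{w_i = \exp(-\Delta_i / 2) / \sum_j \exp(-\Delta_j / 2)}
#' across a set of fits of the same curve. All fits must use the same
#' points, otherwise AICc values are not comparable.
#'
#' @param fits A named list of `mi_decay_fit` objects (names are ignored;
#'   families label the output), or the result of [fit_decay_models()].
#' @return A tibble of class `mi_model_comparison` with one row per
#'   family: `family`, `k`, `n`, `rss`, `r2`, `aicc`, `delta_aicc`,
#'   `rel_prob` and logical `best`; attribute `fits` keeps the fit
#'   objects.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "mi_decay_fit")) fits <- list(fits)
  if (!all(vapply(fits, inherits, logical(1), "mi_decay_fit"))) {
    abort("`fits` must be a list of mi_decay_fit objects.")
  }
  ns <- vapply(fits, function(f) f$n, numeric(1))
  xs <- lapply(fits, function(f) f$points$distance)
  if (length(unique(ns)) != 1 ||
      !all(vapply(xs, function(x) identical(x, xs[[1]]), logical(1)))) {
    abort("All fits must be computed on identical point sets.")
  }
  tab <- tibble::tibble(
    family = vapply(fits, function(f) f$family, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    n = ns,
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    r2 = vapply(fits, function(f) f$r2, numeric(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1))
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  w <- exp(-tab$delta_aicc / 2)
  tab$rel_prob <- w / sum(w)
  tab$best <- tab$delta_aicc == 0
  if (sum(tab$best) > 1) { # exact ties: first listed wins
    tab$best[which(tab$best)[-1]] <- FALSE
  }
  structure(
    tab,
    fits = setNames(fits, tab$family),
    class = c("mi_model_comparison", class(tibble::tibble()))
  )
}

#' Fit all decay families to a curve and compare them
#'
#' Convenience wrapper: fits each requested family with [fit_decay()] and
#' compares them with [compare_models()].
#'
#' @inheritParams fit_decay
#' @param families Character vector of families to fit.
#' @return An `mi_model_comparison` tibble.
#' @examples
#' g <- random_markov_grammar(6, seed = 3, length = 120, n_sequences = 60)
#' curve <- mi_decay_curve(sample_corpus(g), max_distance = 30, seed = 1)
#' fit_decay_models(curve)
#' @export
fit_decay_models <- function(curve,
                             families = c("exponential", "power_law", "composite"),
                             weighting = c("log1p", "log")) {
  weighting <- match.arg(weighting)
  fits <- lapply(families, function(f) fit_decay(curve, f, weighting))
  compare_models(fits)
}

#' Best family of a model comparison
#'
#' @param comparison An `mi_model_comparison`.
#' @return The best-fitting family name (single string).
#' @export
best_family <- function(comparison) {
  if (!inherits(comparison, "mi_model_comparison")) {
    abort("`comparison` must be an mi_model_comparison.")
  }
  comparison$family[comparison$best][1]
}

#' Repeat model fitting and comparison over nested distance ranges
#'
#' Restricts the curve to `distance <= max_distance` for each requested
#' range, refits all families, and reports the comparison per range. This
#' probes how stable the model selection is to the analysed distance
#' range. Ranges with too few usable points are reported with an `error`
#' message; other ranges are unaffected.
#'
#' @inheritParams fit_decay_models
#' @param max_distances Integer vector of maximum distances to scan.
#' @return A tibble with one row per (range, family): `max_distance` plus
#'   the [compare_models()] columns, and an `error` column that is `NA`
#'   for successful ranges.
#' @export
fit_range_scan <- function(curve,
                           max_distances,
                           families = c("exponential", "power_law", "composite"),
                           weighting = c("log1p", "log")) {
  weighting <- match.arg(weighting)
  data <- tibble::as_tibble(curve)
  purrr::map_dfr(max_distances, function(md) {
    sub <- dplyr::filter(data, .data$distance <= md)
    res <- tryCatch(
      fit_decay_models(sub, families = families, weighting = weighting),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      tibble::tibble(max_distance = as.integer(md), family = NA_character_,
                     k = NA_real_, n = NA_real_, rss = NA_real_, r2 = NA_real_,
                     aicc = NA_real_, delta_aicc = NA_real_, rel_prob = NA_real_,
                     best = NA, error = res)
    } else {
      dplyr::mutate(tibble::as_tibble(res), max_distance = as.integer(md),
                    error = NA_character_, .before = 1)
    }
  })
}

#' Split an MI curve into its fitted components
#'
#' For a composite fit `a * exp(-x b) + c * x^d + f`, subtracting the
#' exponential component from the observed MI exposes the power-law
#' portion of the decay, and vice versa.
#'
#' @param fit A composite-family `mi_decay_fit`.
#' @param curve The curve the fit was computed on (or any data frame with
#'   `distance` and `mi`).
#' @return A tibble with columns `distance`, `mi`,
#'   `mi_minus_exponential` (`mi - a e^{-xb}`) and `mi_minus_power_law`
#'   (`mi - c x^d`), aligned one-to-one with the curve's distances.
#' @export
decompose_fit <- function(fit, curve) {
  if (!inherits(fit, "mi_decay_fit") || fit$family != "composite") {
    abort("`fit` must be a composite-family mi_decay_fit.")
  }
  data <- tibble::as_tibble(curve)
  p <- fit$model$params
  tibble::tibble(
    distance = data$distance,
    mi = data$mi,
    mi_minus_exponential = data$mi - p$a * exp(-data$distance * p$b),
    mi_minus_power_law = data$mi - p$c * data$distance^p$d
  )
}

#' Serialize a model comparison (and its fits) to JSON
#'
#' @param comparison An `mi_model_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  fits <- attr(comparison, "fits")
  payload <- list(
    table = tibble::as_tibble(comparison),
    best = best_family(comparison),
    fits = lapply(fits, function(f) {
      list(family = f$family, params = f$model$params, rss = f$rss, r2 = f$r2,
           aicc = f$aicc, n = f$n, k = f$k, weighting = f$weighting,
           n_excluded = f$n_excluded)
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
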