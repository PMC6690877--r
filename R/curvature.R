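#' Curvature profile of a fitted decay in log-log space
#'
#' Computes the curvature
#' \deqn{\kappa = |y''| / (1 + y'^2)^{3/2}}
#' of the fitted decay, where `y` is the base-10 log of the model value
#' taken as a function of the base-10 log of distance. Derivatives are
#' analytic (chain rule through the model function), evaluated on a dense
#' uniform grid in log distance. The first local minimum of the profile
#' marks the "knee" of the exponential portion of the decay, and the
#' following local maximum marks the distance at which the power-law
#' component begins to dominate. A pure power law is a straight line in
#' log-log space, has zero curvature everywhere, and yields no extrema.
#'
#' @param object A composite-family `mi_decay_fit` (the distance range is
#'   taken from the fitted points) or a composite [decay_model()]
#'   (requires `from`/`to`).
#' @param from,to Positive ends of the distance range; defaults to the
#'   fitted range for fits.
#' @param n_grid Grid size, default `1e4`.
#' @return An object of class `mi_curvature`: a list with `grid` (tibble
#'   with `distance`, `log10_distance`, `y`, `kappa`), `min_location` and
#'   `max_location` in element-distance units (`NA` when no interior
#'   extremum exists).
#' @export
curvature_profile <- function(object, from = NULL, to = NULL, n_grid = 1e4) {
  if (inherits(object, "mi_decay_fit")) {
    model <- object$model
    from <- from %||% min(object$points$distance)
    to <- to %||% max(object$points$distance)
  } else if (inherits(object, "decay_model")) {
    model <- object
    if (is.null(from) || is.null(to)) {
      abort("`from` and `to` are required when profiling a bare decay_model.")
    }
  } else {
    abort("`object` must be an mi_decay_fit or decay_model.")
  }
  if (model$family != "composite") {
    abort("Curvature analysis applies to composite-family models.")
  }
  p <- model$params
  if (p$b < 0 || p$d > 0) {
    abort("Curvature analysis requires decaying components (b >= 0, d <= 0).")
  }
  if (from <= 0 || to <= from) abort("Need 0 < from < to.")

  t <- seq(log10(from), log10(to), length.out = n_grid)
  x <- 10^t
  # g(x) and its derivatives; y = log10 g as a function of t = log10 x.
  g <- p$a * exp(-p$b * x) + p$c * x^p$d + p$f
  g1 <- -p$a * p$b * exp(-p$b * x) + p$c * p$d * x^(p$d - 1)
  g2 <- p$a * p$b^2 * exp(-p$b * x) + p$c * p$d * (p$d - 1) * x^(p$d - 2)
  u <- x * g1 / g                     # dy/dt (log factors cancel in the 1st derivative)
  y2 <- log(10) * (u + x^2 * g2 / g - u^2) # d2y/dt2, t = log10 x
  kappa <- abs(y2) / (1 + u^2)^(3 / 2)

  ext <- kappa_extrema(x, kappa)
  min_loc <- ext$min_location
  max_loc <- ext$max_location
  structure(
    list(
      grid = tibble::tibble(
        distance = x, log10_distance = t,
        y = log10(pmax(g, .Machine$double.xmin)), kappa = kappa
      ),
      min_location = min_loc,
      max_location = max_loc
    ),
    class = "mi_curvature"
  )
}

# Knee detection on a sampled curvature profile. A composite decay's
# curvature typically shows two humps -- the exponential elbow and the
# exponential-to-power-law transition -- separated by a dip where the
# log-log decay is locally straightest. The knee is the deepest local
# minimum between the two dominant curvature maxima (or before the single
# dominant maximum when only one hump lies in range); the transition is
# the rightmost of those maxima. Maxima below a small fraction of the
# global curvature scale (or below an absolute floor, for profiles that
# are numerically flat, e.g. a pure power law) are treated as numerical
# ripple, not structure. NA when no such extremum exists.
kappa_extrema <- function(x, kappa, rel_prominence = 0.01, abs_floor = 1e-8) {
  n <- length(kappa)
  interior <- 2:(n - 1)
  is_min <- kappa[interior] < kappa[interior - 1] &
    kappa[interior] < kappa[interior + 1]
  is_max <- kappa[interior] > kappa[interior - 1] &
    kappa[interior] > kappa[interior + 1]
  min_idx <- interior[is_min]
  max_idx <- interior[is_max]
  kmax <- if (length(max_idx) > 0) max(kappa[max_idx]) else 0
  # Prominence of a local maximum: its height above the higher of the two
  # valley floors separating it from the nearest taller point (or the
  # range boundary). Numerical ripple has negligible prominence.
  prominence <- vapply(max_idx, function(i) {
    higher_left <- which(kappa[seq_len(i - 1)] > kappa[i])
    lo <- if (length(higher_left) > 0) max(higher_left) + 1L else 1L
    higher_right <- which(kappa[(i + 1):n] > kappa[i])
    hi <- if (length(higher_right) > 0) i + min(higher_right) - 1L else n
    left_base <- min(kappa[lo:i])
    right_base <- min(kappa[i:hi])
    kappa[i] - max(left_base, right_base)
  }, numeric(1))
  keep <- prominence >= max(rel_prominence * kmax, abs_floor)
  max_idx <- max_idx[keep]
  none <- list(min_location = NA_real_, max_location = NA_real_)
  if (length(max_idx) == 0 || length(min_idx) == 0) {
    return(none)
  }
  if (length(max_idx) >= 2) {
    top2 <- max_idx[order(kappa[max_idx], decreasing = TRUE)[1:2]]
    left <- min(top2)
    right <- max(top2)
  } else {
    left <- 1L
    right <- max_idx
  }
  between <- min_idx[min_idx > left & min_idx < right]
  if (length(between) == 0) {
    return(none)
  }
  knee <- between[which.min(kappa[between])]
  list(min_location = x[knee], max_location = x[right])
}

#' @export
print.mi_curvature <- function(x, ...) {
  cat("Curvature profile of composite decay (log-log space)\n")
  cat(sprintf("  grid: %d points over distances %.3g..%.3g\n",
              nrow(x$grid), min(x$grid$distance), max(x$grid$distance)))
  if (is.na(x$min_location)) {
    cat("  no curvature minimum (knee) located\n")
  } else {
    cat(sprintf("  knee (curvature minimum): %.3g elements\n", x$min_location))
    if (!is.na(x$max_location)) {
      cat(sprintf("  following maximum:        %.3g elements\n", x$max_location))
    }
  }
  invisible(x)
}
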