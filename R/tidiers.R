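#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted decay model
#'
#' @param x An `mi_decay_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`.
#' @export
tidy.mi_decay_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$model$params),
    estimate = unlist(x$model$params, use.names = FALSE)
  )
}

#' One-row summary of a fitted decay model
#'
#' @param x An `mi_decay_fit`.
#' @param ... Unused.
#' @return A tibble with `family`, `n`, `k`, `rss`, `r2`, `aicc` and
#'   `n_excluded`.
#' @export
glance.mi_decay_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, n = x$n, k = x$k, rss = x$rss, r2 = x$r2,
    aicc = x$aicc, n_excluded = x$n_excluded
  )
}

#' Tidy a model comparison
#'
#' @param x An `mi_model_comparison`.
#' @param ... Unused.
#' @return The comparison table as a plain tibble.
#' @export
tidy.mi_model_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a model comparison
#'
#' @param x An `mi_model_comparison`.
#' @param ... Unused.
#' @return A tibble with `best`, `rel_prob_best`, `delta_aicc_second`
#'   (AICc gap to the runner-up) and `n`.
#' @export
glance.mi_model_comparison <- function(x, ...) {
  deltas <- sort(x$delta_aicc)
  tibble::tibble(
    best = best_family(x),
    rel_prob_best = max(x$rel_prob),
    delta_aicc_second = if (length(deltas) > 1) deltas[2] else NA_real_,
    n = x$n[1]
  )
}

#' Tidy a curvature profile
#'
#' @param x An `mi_curvature`.
#' @param ... Unused.
#' @return The dense grid tibble (`distance`, `log10_distance`, `y`,
#'   `kappa`).
#' @export
tidy.mi_curvature <- function(x, ...) {
  x$grid
}

#' One-row summary of a curvature profile
#'
#' @param x An `mi_curvature`.
#' @param ... Unused.
#' @return A tibble with `knee` (curvature minimum, in element
#'   distances) and `transition` (the following maximum).
#' @export
glance.mi_curvature <- function(x, ...) {
  tibble::tibble(knee = x$min_location, transition = x$max_location)
}

#' @export
print.mi_decay_fit <- function(x, ...) {
  cat(sprintf("Decay fit: %s family (%d parameters, %d points)\n",
              x$family, x$k, x$n))
  pars <- paste(sprintf("%s = %.4g", names(x$model$params),
                        unlist(x$model$params)), collapse = ", ")
  cat("  ", pars, "\n", sep = "")
  cat(sprintf("  weighted log-RSS = %.4g, r2 = %.4f, AICc = %.2f\n",
              x$rss, x$r2, x$aicc))
  if (x$n_excluded > 0) {
    cat(sprintf("  (%d non-positive MI points excluded from the log-space fit)\n",
                x$n_excluded))
  }
  invisible(x)
}
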