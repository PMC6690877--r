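#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an MI decay curve
#'
#' Corrected MI against sequential distance on log-log axes; non-positive
#' corrected values cannot be drawn on a log axis and are omitted.
#'
#' @param object An `mi_decay` tibble.
#' @param show_raw Also draw the raw and shuffled-baseline estimates.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mi_decay <- function(object, show_raw = FALSE, ...) {
  data <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(
    dplyr::filter(data, .data$mi > 0),
    ggplot2::aes(x = .data$distance, y = .data$mi)
  ) +
    ggplot2::geom_point(colour = "grey25", size = 1.4) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "sequential distance (elements)",
      y = "corrected mutual information (bits)"
    ) +
    ggplot2::theme_minimal()
  if (show_raw) {
    long <- data |>
      dplyr::select("distance", raw = "mi_raw", shuffled = "mi_shuffled") |>
      tidyr::pivot_longer(-"distance", names_to = "estimate", values_to = "value") |>
      dplyr::filter(.data$value > 0)
    p <- p + ggplot2::geom_point(
      data = long,
      ggplot2::aes(y = .data$value, colour = .data$estimate),
      size = 1, alpha = 0.6
    )
  }
  p
}

#' Plot a decay fit over its data
#'
#' Shows the fitted model as a line over the fitted MI points on log-log
#' axes; for composite fits the exponential and power-law components are
#' overlaid as dashed and dotted lines.
#'
#' @param object An `mi_decay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mi_decay_fit <- function(object, ...) {
  pts <- object$points
  xg <- exp(seq(log(min(pts$distance)), log(max(pts$distance)),
                length.out = 400))
  layers <- tibble::tibble(distance = xg, value = eval_decay(object, xg),
                           component = "fit")
  if (object$family == "composite") {
    p <- object$model$params
    layers <- dplyr::bind_rows(
      layers,
      tibble::tibble(distance = xg, value = p$a * exp(-p$b * xg) + p$f,
                     component = "exponential + offset"),
      tibble::tibble(distance = xg, value = p$c * xg^p$d + p$f,
                     component = "power law + offset")
    )
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mi), colour = "grey25",
                        size = 1.4) +
    ggplot2::geom_line(
      data = dplyr::filter(layers, .data$value > 0),
      ggplot2::aes(y = .data$value, linetype = .data$component),
      colour = "steelblue"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_linetype_manual(
      values = c(fit = "solid", `exponential + offset` = "dashed",
                 `power law + offset` = "dotted")
    ) +
    ggplot2::labs(
      x = "sequential distance (elements)",
      y = "corrected mutual information (bits)",
      linetype = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot all fitted families of a model comparison
#'
#' @param object An `mi_model_comparison`.
#' @param ... Unused.
#' @return A ggplot with one fitted line per family over the shared
#'   points.
#' @export
autoplot.mi_model_comparison <- function(object, ...) {
  fits <- attr(object, "fits")
  pts <- fits[[1]]$points
  xg <- exp(seq(log(min(pts$distance)), log(max(pts$distance)),
                length.out = 400))
  lines <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(distance = xg, value = eval_decay(f, xg),
                   family = f$family)
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mi), colour = "grey25",
                        size = 1.4) +
    ggplot2::geom_line(
      data = dplyr::filter(lines, .data$value > 0),
      ggplot2::aes(y = .data$value, colour = .data$family)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "sequential distance (elements)",
      y = "corrected mutual information (bits)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a curvature profile
#'
#' Curvature of the fitted composite decay in log-log space, with the
#' knee (curvature minimum) and the following maximum marked.
#'
#' @param object An `mi_curvature`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mi_curvature <- function(object, ...) {
  p <- ggplot2::ggplot(object$grid,
                       ggplot2::aes(x = .data$distance, y = .data$kappa)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "sequential distance (elements)",
                  y = expression(kappa)) +
    ggplot2::theme_minimal()
  if (!is.na(object$min_location)) {
    p <- p + ggplot2::geom_vline(xintercept = object$min_location,
                                 linetype = "dashed", colour = "firebrick")
  }
  if (!is.na(object$max_location)) {
    p <- p + ggplot2::geom_vline(xintercept = object$max_location,
                                 linetype = "dotted", colour = "steelblue")
  }
  p
}
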