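# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted clustering
#'
#' Scatter of the first two features colored by hard cluster assignment,
#' with cluster centers overlaid as crosses. One-dimensional fits are drawn
#' as a histogram with center rules.
#'
#' @param object A `wbfc_fit` or `owbfc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wbfc_fit
#' @export
autoplot.wbfc_fit <- function(object, ...) {
  aug <- augment(object)
  feat <- names(aug)[!startsWith(names(aug), ".")]
  cent <- tidy(object)
  if (length(feat) >= 2L) {
    ggplot2::ggplot(aug, ggplot2::aes(.data[[feat[1L]]], .data[[feat[2L]]])) +
      ggplot2::geom_point(ggplot2::aes(color = .data$.cluster), alpha = 0.6) +
      ggplot2::geom_point(
        data = cent,
        ggplot2::aes(.data[[feat[1L]]], .data[[feat[2L]]]),
        shape = 4, size = 4, stroke = 1.5
      ) +
      ggplot2::labs(color = "cluster") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(aug, ggplot2::aes(.data[[feat[1L]]])) +
      ggplot2::geom_histogram(ggplot2::aes(fill = .data$.cluster),
                              bins = 40, position = "identity", alpha = 0.6) +
      ggplot2::geom_vline(data = cent,
                          ggplot2::aes(xintercept = .data[[feat[1L]]]),
                          linetype = 2) +
      ggplot2::labs(fill = "cluster") +
      ggplot2::theme_minimal()
  }
}

#' Plot a phantom image
#'
#' @param object An `owbfc_phantom` from [make_phantom()].
#' @param what `"image"` (intensities) or `"labels"` (regions).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot owbfc_phantom
#' @export
autoplot.owbfc_phantom <- function(object, what = c("image", "labels"), ...) {
  what <- match.arg(what)
  px <- object$pixels
  if (what == "image") {
    ggplot2::ggplot(px, ggplot2::aes(.data$col, .data$row,
                                     fill = .data$intensity)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   limits = c(0, 1)) +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::theme_void()
  } else {
    ggplot2::ggplot(px, ggplot2::aes(.data$col, .data$row,
                                     fill = factor(.data$.region))) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() +
      ggplot2::labs(fill = "region") +
      ggplot2::theme_void()
  }
}

#' Plot the objective trace of a fit
#'
#' Best-so-far joint objective J against sampler sweep (non-increasing by
#' construction).
#'
#' @param fit A `wbfc_fit` or `owbfc_fit`.
#' @return A ggplot object.
#' @export
plot_trace <- function(fit) {
  ggplot2::ggplot(fit$trace, ggplot2::aes(.data$sweep, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sweep", y = "best joint objective J") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
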