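#' Plot a weight map
#'
#' Raster display of one display position's slope map (or the mean over
#' displays), blue for positive (overweighting) and red for negative weight.
#'
#' @param object A `wm_weight_maps` object.
#' @param display Display position 1-6, or `"mean"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wm_weight_maps
#' @export
autoplot.wm_weight_maps <- function(object, display = "mean", ...) {
  d <- tidy(object)
  if (identical(display, "mean")) {
    d <- d |>
      dplyr::group_by(.data$x, .data$y) |>
      dplyr::summarise(beta = mean(.data$beta), .groups = "drop")
    ttl <- "decision-weight map (mean over displays)"
  } else {
    d <- d[d$display == display, ]
    ttl <- sprintf("decision-weight map, display %s", display)
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$beta)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "black",
                                  high = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", fill = "weight",
                  title = ttl) +
    ggplot2::theme_minimal()
}

#' Plot a group pixel test
#'
#' t-map raster with the FDR-significant pixels outlined.
#'
#' @param object A `wm_group_test` object.
#' @param display Display index (1 for collapsed tests).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wm_group_test
#' @export
autoplot.wm_group_test <- function(object, display = 1, ...) {
  d <- tidy(object)
  d <- d[d$display == display, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$t)) +
    ggplot2::geom_point(data = d[d$significant, ], size = 0.2,
                        color = "white", alpha = 0.6) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "black",
                                  high = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", fill = "t",
                  title = sprintf("group map (BH-FDR %.2g)", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot angular tuning profiles
#'
#' Group-mean segment weight as a function of absolute angular distance from
#' the memorized location, per display position.
#'
#' @param object A `wm_tuning` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wm_tuning
#' @export
autoplot.wm_tuning <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$abs_distance, .data$mean_weight)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~display, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "absolute angular distance from WM sample (deg)",
                  y = "mean decision weight") +
    ggplot2::theme_minimal()
}

#' Plot psychometric weighting functions
#'
#' Proportion of blue judgements per excess-count level and display position.
#'
#' @param wf A [weighting_function()] tibble.
#' @return A ggplot object.
#' @export
plot_weighting_function <- function(wf) {
  d <- wf |>
    dplyr::group_by(.data$display, .data$level) |>
    dplyr::summarise(p_blue = stats::weighted.mean(.data$p_blue, .data$n),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$level, .data$p_blue)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, color = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~display, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "excess blue - red dots (relative to stream mean)",
                  y = "P(judged blue)") +
    ggplot2::theme_minimal()
}
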