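# ggplot2 visualizations for the result types.

#' Plot an image matrix
#'
#' @param img image matrix in [0, 1].
#' @return a ggplot raster plot (origin top-left, like the matrix).
#' @export
plot_image <- function(img) {
  check_image(img)
  d <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  d$value <- as.vector(t(unclass(img)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}

#' @exportS3Method
autoplot.mse_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$order, y = .data$mse,
                                       colour = .data$image_id)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "moment order", y = "reconstruction MSE",
                  colour = "image") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.posterior_accuracy <- function(object, ...) {
  x <- seq(0.001, 0.999, length.out = 400)
  d <- tibble(accuracy = x,
              density = stats::dbeta(x, object$shape_a, object$shape_b))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$accuracy, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_area(data = dplyr::filter(d, .data$accuracy >= object$lower,
                                            .data$accuracy <= object$upper),
                       alpha = 0.3) +
    ggplot2::geom_vline(xintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "accuracy", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.mass_study <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$model, y = .data$mean,
                               ymin = .data$mean - .data$se,
                               ymax = .data$mean + .data$se,
                               colour = .data$metric)) +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "model", y = "metric (mean ± SE)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
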