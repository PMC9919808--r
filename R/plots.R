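#' Plot methods
#'
#' `autoplot()` methods for the package's objects, built on ggplot2:
#' \itemize{
#'   \item `accel_stream` — the three axis traces over time with activity
#'     segments shaded.
#'   \item `har_confusion` — a heatmap of counts with the diagonal
#'     highlighted.
#'   \item `har_cv` — per-algorithm mean fold score with +/- 1 SD bars.
#'   \item `har_metrics` — per-class precision/recall/F1 as grouped bars.
#' }
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return a `ggplot`.
#' @name har-autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname har-autoplot
#' @export
autoplot.accel_stream <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), c("x", "y", "z"),
                            names_to = "axis", values_to = "acceleration_g")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t,
                                        y = .data$acceleration_g,
                                        colour = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "acceleration (g)") +
    ggplot2::theme_minimal()
  if ("label" %in% names(object)) {
    runs <- rle(as.character(object$label))
    ends <- cumsum(runs$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    seg <- tibble(xmin = object$t[starts], xmax = object$t[ends],
                  activity = runs$values)
    p <- p +
      ggplot2::geom_rect(data = seg, inherit.aes = FALSE,
                         ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                      ymin = -Inf, ymax = Inf,
                                      fill = .data$activity),
                         alpha = 0.12) +
      ggplot2::labs(fill = "activity")
  }
  p
}

#' @rdname har-autoplot
#' @export
autoplot.har_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' @rdname har-autoplot
#' @export
autoplot.har_cv <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$algorithm, .data$mean_score),
    y = .data$mean_score)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_score - .data$std_score,
      ymax = .data$mean_score + .data$std_score)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("mean %d-fold accuracy (+/- 1 SD)",
                                        object$k)) +
    ggplot2::theme_minimal()
}

#' @rdname har-autoplot
#' @export
autoplot.har_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class,
                            c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$activity, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
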