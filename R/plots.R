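#' Plot a confusion matrix
#'
#' Tile plot with counts, true classes on the y axis (top to bottom in
#' canonical order) and predictions on the x axis.
#'
#' @param object A `plum_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plum_confusion <- function(object, ...) {
  df <- tidy.plum_confusion(object)
  df$true <- factor(df$true, levels = rev(defect_classes()))
  df$predicted <- factor(df$predicted, levels = defect_classes())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Loss and training accuracy per epoch, with the SWA snapshot count shown
#' in the subtitle.
#'
#' @param object A `plum_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plum_fit <- function(object, ...) {
  h <- object$history
  df <- tibble::tibble(
    epoch = rep(h$epoch, 2),
    value = c(h$loss, h$train_accuracy),
    quantity = rep(c("loss", "train accuracy"), each = nrow(h)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = "epoch", y = NULL,
      subtitle = sprintf("%d SWA snapshot(s) averaged",
                         object$swa$n_models)) +
    ggplot2::theme_minimal()
}

#' Plot per-class metrics
#'
#' @param object A `plum_metrics`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plum_metrics <- function(object, ...) {
  df <- object$per_class
  long <- tibble::tibble(
    class = rep(df$class, 3),
    value = c(df$recall, df$precision, df$f1),
    metric = rep(c("recall", "precision", "F1"), each = nrow(df)))
  long$class <- factor(long$class, levels = defect_classes())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL
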