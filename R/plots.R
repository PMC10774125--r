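# ggplot2 displays for the pipeline's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cumulative performance trace
#'
#' Cumulative accuracy (and mean angular error for eight-target traces)
#' against trial number, with the gray 90% chance envelope and a red
#' vertical line at the last non-significant trial.
#'
#' @param object a [cumulative_trace()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot fus_trace
#' @export
autoplot.fus_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  last_ns <- attr(object, "last_nonsignificant")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 100 * .data$acc_low,
                                      ymax = 100 * .data$acc_high),
                         fill = "gray80") +
    ggplot2::geom_line(ggplot2::aes(y = 100 * .data$accuracy),
                       color = "#2c7fb8", linewidth = 0.8) +
    ggplot2::labs(x = "Trial number", y = "Cumulative accuracy (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
  if (!is.null(last_ns) && last_ns > 0) {
    p <- p + ggplot2::geom_vline(xintercept = last_ns, color = "red",
                                 linetype = "solid")
  }
  p
}

#' Plot a confusion matrix
#'
#' @param object a [confusion_matrix()] result.
#' @param ... unused.
#' @return A ggplot (tile map of row-normalized percentages).
#' @method autoplot fus_confusion
#' @export
autoplot.fus_confusion <- function(object, ...) {
  df <- tidy(object)
  df$cued <- factor(df$cued, rev(rownames(object)))
  df$predicted <- factor(df$predicted, colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$cued,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data$percent)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 limits = c(0, 100), na.value = "gray90") +
    ggplot2::labs(x = "Predicted class", y = "Cued class",
                  fill = "% of row") +
    ggplot2::theme_minimal()
}

#' Plot a searchlight map
#'
#' Score map with the top-decile overlay voxels outlined.
#'
#' @param object a [searchlight_map()] result.
#' @param mask optional logical overlay mask (default: the top-decile
#'   mask).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot fus_searchlight
#' @export
autoplot.fus_searchlight <- function(object, mask = NULL, ...) {
  if (is.null(mask)) mask <- top_decile_mask(object)
  H <- nrow(object$score); W <- ncol(object$score)
  g <- expand.grid(y = seq_len(H), x = seq_len(W))
  g$score <- as.vector(object$score)
  g$top <- as.vector(mask)
  lab <- if (object$metric == "accuracy") "CV accuracy"
  else "Mean angular error (deg)"
  ggplot2::ggplot(g, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$score)) +
    ggplot2::geom_point(data = g[g$top, ], color = "red", size = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "gray95") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = lab) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
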