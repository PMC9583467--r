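# ggplot2 diagnostics for training metrics and template inspection.

#' @importFrom rlang .data
NULL

#' Plot training curves
#'
#' Development-set MLL (and training loss) per epoch, one panel per task
#' phase.
#'
#' @param object an `ss_metrics` tibble (from [train_task()] or
#'   `run$metrics`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ss_metrics <- function(object, ...) {
  df <- as.data.frame(object)
  df$task <- factor(df$task, levels = unique(df$task))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$dev_mll,
                                   colour = .data$task)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "dev MLL", colour = "task") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat-map of one template slice
#'
#' Red for positive and blue for negative entries, the way shared-parameter
#' slices are usually inspected.
#'
#' @param template an `sps_template`.
#' @param slice 1-based slice index.
#' @return a ggplot object.
#' @export
plot_template_slice <- function(template, slice = 1) {
  M <- template$values[slice, , ]
  df <- expand.grid(row = seq_len(nrow(M)), col = seq_len(ncol(M)))
  df$value <- as.vector(M)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "value",
                  title = sprintf("template slice %d", slice)) +
    ggplot2::theme_minimal()
}
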