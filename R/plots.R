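#' Spike raster plot
#'
#' @param raster a raster tibble (`time_ms`, `neuron`, `pop`).
#' @param t_start,t_stop optional time window, ms.
#' @return A ggplot object: time on x, neuron index on y, one panel per
#'   population.
#' @export
plot_raster <- function(raster, t_start = NULL, t_stop = NULL) {
  df <- raster
  if (!is.null(t_start)) df <- dplyr::filter(df, .data$time_ms >= t_start)
  if (!is.null(t_stop)) df <- dplyr::filter(df, .data$time_ms < t_stop)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms / 1000, .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$pop), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Heatmap of a projection's weights
#'
#' @param net a network object.
#' @param projection projection name, e.g. `"cx_cx"`.
#' @return A ggplot heatmap, sources on y, targets on x.
#' @export
plot_weights <- function(net, projection = "cx_cx") {
  W <- get_weights(net, projection)
  df <- tidyr::expand_grid(src = seq_len(nrow(W)), tgt = seq_len(ncol(W)))
  df$w <- as.vector(W)[(df$tgt - 1L) * nrow(W) + df$src]
  ggplot2::ggplot(df, ggplot2::aes(.data$tgt, .data$src, fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "w (nS)") +
    ggplot2::labs(x = "target", y = "source", title = projection) +
    ggplot2::theme_minimal()
}

#' Post/pre weight ratio by block category
#'
#' @param stats a [weight_block_stats()] tibble.
#' @return A ggplot bar chart of the post/pre ratio per category, with a
#'   reference line at 1 (no change).
#' @export
plot_block_stats <- function(stats) {
  stats$category <- factor(stats$category,
                           c("same_instance", "same_class", "cross_class"))
  ggplot2::ggplot(stats,
                  ggplot2::aes(.data$category, .data$ratio,
                               fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "post/pre weight ratio") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Overview plot of a protocol report
#'
#' Shows the offline-phase (sleep or awake-control) cortical raster, the
#' canonical at-a-glance view of the slow-oscillation regime.
#'
#' @param object a [run_full_protocol()] report.
#' @param window_s how many seconds of the offline phase to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.somnet_report <- function(object, window_s = 20, ...) {
  log <- offline_log(object)
  plot_raster(log$raster, t_start = log$t_start,
              t_stop = min(log$t_start + window_s * 1000, log$t_stop))
}

#' @rdname plot_weights
#' @param object a network object (autoplot method).
#' @param ... unused.
#' @export
autoplot.somnet_network <- function(object, projection = "cx_cx", ...) {
  plot_weights(object, projection)
}
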