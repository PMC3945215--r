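# ggplot2 views of the main result types.

#' @exportS3Method ggplot2::autoplot
#' @describeIn smooth_and_normalize Replication-timing curve per
#'   chromosome with the unsmoothed mean ratio in grey; pass a peak
#'   table via `peaks =` to mark called peaks.
#' @param object The object to plot.
#' @param peaks Optional [call_peaks()] table.
autoplot.timing_profile <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$start / 1000)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_ratio /
                                       attr(object, "baseline")),
                        colour = "grey70", size = 0.3, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$normalized),
                       colour = "steelblue", na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "normalized S/G1 ratio") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = .data$coord / 1000),
                                 linetype = "dashed", colour = "grey40",
                                 linewidth = 0.3)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
#' @describeIn metaprofile Mean nucleosome density around the anchors.
#' @param object The object to plot.
#' @param ... Unused.
autoplot.meta_profile <- function(object, ...) {
  d <- tibble(offset = object$offsets, density = object$column_means)
  ggplot2::ggplot(d, ggplot2::aes(.data$offset, .data$density)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "offset from anchor (bp)",
                  y = "mean nucleosome density") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
#' @describeIn enrichment_ratio Heat map of per-position, per-base
#'   enrichment (averaged matrices only show one panel).
#' @param object The object to plot.
#' @param ... Unused.
autoplot.enrichment_matrix <- function(object, ...) {
  d <- as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$base,
                                       fill = .data$log2_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", na.value = "grey85") +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  fill = "log2 enrichment") +
    ggplot2::theme_minimal()
  if ("replicate" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(~replicate, ncol = 1)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
#' @describeIn split_bimodal Histogram of motif scores with the fitted
#'   class threshold.
#' @param object The object to plot.
autoplot.ars_class_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$score)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::labs(x = "best motif score (bits)", y = "ARS count") +
    ggplot2::theme_minimal()
  if (object$split) {
    p <- p + ggplot2::geom_vline(xintercept = object$threshold,
                                 colour = "red", linetype = "dashed")
  }
  p
}

#' Average base composition around motif hits, as a line plot
#'
#' @param flank_freq A [flank_base_frequencies()] tibble.
#' @return A ggplot object.
#' @export
plot_flank_frequencies <- function(flank_freq) {
  ggplot2::ggplot(flank_freq,
                  ggplot2::aes(.data$offset, .data$freq,
                               colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from motif start (bp)", y = "base frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
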