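#' Plot cumulative doublet rank curves
#'
#' @param curves Tibble from [doublet_rank_curve()], optionally with a
#'   grouping column (e.g. `dataset`).
#' @param colour Name of an optional grouping column.
#' @return A ggplot object.
#' @export
plot_doublet_rank_curve <- function(curves, colour = NULL) {
  aes <- if (!is.null(colour))
    ggplot2::aes(.data$cutoff, .data$fraction,
                 colour = .data[[colour]], group = .data[[colour]])
  else ggplot2::aes(.data$cutoff, .data$fraction, group = 1)
  ggplot2::ggplot(curves, aes) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "intensity rank cutoff",
                  y = "cumulative fraction of doublet-containing CSMs") +
    ggplot2::theme_minimal()
}

#' Plot per-category sequence coverage distributions
#'
#' @param coverage Long tibble with columns `category`, `coverage` and an
#'   optional `condition` for side-by-side comparison.
#' @return A ggplot object (boxplots).
#' @export
plot_coverage <- function(coverage) {
  aes <- if ("condition" %in% names(coverage))
    ggplot2::aes(.data$category, .data$coverage, fill = .data$condition)
  else ggplot2::aes(.data$category, .data$coverage)
  ggplot2::ggplot(coverage, aes) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "sequence coverage") +
    ggplot2::theme_minimal()
}

#' Score distributions with FDR cutoffs
#'
#' Histograms of target-target and target-decoy scores with dashed lines
#' at the group score thresholds.
#'
#' @param object An `xl_fdr` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot xl_fdr
#' @export
autoplot.xl_fdr <- function(object, ...) {
  d <- dplyr::filter(object$csms, .data$td_class != "DD")
  thr <- object$groups
  ggplot2::ggplot(d, ggplot2::aes(.data$score, fill = .data$td_class)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    ggplot2::geom_vline(data = thr,
                        ggplot2::aes(xintercept = .data$threshold_score),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "CSM score", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}
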