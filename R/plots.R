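#' @importFrom ggplot2 ggplot aes geom_point geom_abline geom_boxplot
#'   geom_histogram geom_vline geom_hline scale_x_log10 scale_y_log10
#'   labs autoplot facet_wrap
NULL

#' @export
ggplot2::autoplot

#' PCA score plot of samples
#'
#' @param object a [run_pca()] result.
#' @param colour_by optional vector (one value per sample) used as the
#'   colour aesthetic, e.g. condition labels.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tn_pca
#' @export
autoplot.tn_pca <- function(object, colour_by = NULL, ...) {
  d <- object$scores
  pcs <- setdiff(names(d), "sample")[1:2]
  if (!is.null(colour_by)) d$group <- colour_by
  p <- ggplot(d, aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]])) +
    labs(x = sprintf("%s (%.1f%%)", pcs[1],
                     100 * object$explained_variance[1]),
         y = sprintf("%s (%.1f%%)", pcs[2],
                     100 * object$explained_variance[2]))
  if (is.null(colour_by)) {
    p + geom_point(size = 3)
  } else {
    p + geom_point(aes(colour = .data$group), size = 3)
  }
}

#' Mean-abundance scatter of predation vs no-predation counts
#'
#' Log-log scatter of mean normalized counts, top-quantile enriched
#' rows highlighted, with the identity diagonal.
#'
#' @param table enrichment tibble from [compute_log2fc()] /
#'   [select_top()].
#' @param pseudocount offset used on both axes for display.
#' @return a ggplot.
#' @export
plot_enrichment <- function(table, pseudocount = 1) {
  if (!"top_flag" %in% names(table)) table$top_flag <- FALSE
  ggplot(table, aes(x = .data$mean_no_predation + pseudocount,
                    y = .data$mean_predation + pseudocount,
                    colour = .data$top_flag)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, colour = "darkgreen") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "mean normalized count, no predation",
         y = "mean normalized count, predation",
         colour = "top quantile")
}

#' Simulated depletion across the survival grid
#'
#' Boxplots of the simulated fraction of lost rows per grid survival
#' value, with the observed value as a horizontal line.
#'
#' @param simulated per-simulation [depletion_stats()] tibble with a
#'   `survival` column.
#' @param observed_loss optional observed fraction of rows lost.
#' @return a ggplot.
#' @export
plot_depletion <- function(simulated, observed_loss = NULL) {
  p <- ggplot(simulated, aes(x = factor(.data$survival),
                             y = .data$fraction_rows_lost)) +
    geom_boxplot() +
    labs(x = "survival fraction", y = "fraction of input rows lost")
  if (!is.null(observed_loss)) {
    p <- p + geom_hline(yintercept = observed_loss, colour = "red",
                        linetype = "dashed")
  }
  p
}

#' Cell-length distribution with filament threshold
#'
#' @param table cell table with `length_um` (and optional `condition`).
#' @param threshold optional filament threshold (um), drawn as a
#'   vertical line.
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_cell_lengths <- function(table, threshold = NULL, bins = 60) {
  p <- ggplot(table, aes(x = .data$length_um)) +
    geom_histogram(bins = bins) +
    labs(x = "pole-to-pole length (µm)", y = "cells")
  if ("condition" %in% names(table) && !all(is.na(table$condition))) {
    p <- p + facet_wrap(~condition, ncol = 1)
  }
  if (!is.null(threshold)) {
    p <- p + geom_vline(xintercept = threshold, colour = "red")
  }
  p
}
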