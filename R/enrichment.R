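#' Per-row log2 fold change between predation and no-predation samples
#'
#' Computes, for every row of a normalized count matrix, the group means
#' and SDs (sample SD, n - 1 denominator) over predation and
#' no-predation replicate columns and the log2 ratio of means with a
#' pseudocount:
#' `log2fc = log2((mean_pred + pseudocount) / (mean_no + pseudocount))`.
#' Ranking is by the log2 fold change of replicate means (not the mean
#' of per-replicate ratios), descending, with boundary ties broken by
#' row order.
#'
#' @param matrix a normalized `tn_counts` matrix (error otherwise).
#' @param predation_cols,control_cols column names of the two groups.
#' @param pseudocount added to both means, in normalized-count units
#'   (default 1); keeps bottlenecked zero rows finite while preserving
#'   large-fold-change ordering.
#' @return an enrichment tibble: `row_id`, `mean_no_predation`,
#'   `mean_predation`, `sd_no`, `sd_pred`, `log2fc`, `rank`.
#' @export
compute_log2fc <- function(matrix, predation_cols, control_cols,
                           pseudocount = 1) {
  if (!is_normalized(matrix)) {
    abort("count matrix must be normalized before computing fold changes")
  }
  if (length(predation_cols) == 0 || length(control_cols) == 0) {
    abort("both sample groups must be non-empty")
  }
  miss <- setdiff(c(predation_cols, control_cols), sample_cols(matrix))
  if (length(miss) > 0) {
    abort(sprintf("unknown sample column(s): %s", paste(miss, collapse = ", ")))
  }
  if (pseudocount < 0) abort("`pseudocount` must be >= 0")
  pred <- as.matrix(matrix[predation_cols])
  ctrl <- as.matrix(matrix[control_cols])
  row_sd <- function(m) {
    if (ncol(m) < 2) return(rep(NA_real_, nrow(m)))
    apply(m, 1L, sd)
  }
  out <- tibble(
    row_id = matrix$row_id,
    mean_no_predation = rowMeans(ctrl),
    mean_predation = rowMeans(pred),
    sd_no = row_sd(ctrl),
    sd_pred = row_sd(pred))
  out$log2fc <- log2((out$mean_predation + pseudocount) /
                       (out$mean_no_predation + pseudocount))
  out$rank <- rank(-out$log2fc, ties.method = "first")
  out
}

#' Flag the most-enriched quantile of rows
#'
#' Marks exactly `ceiling(quantile * n)` rows with the highest log2
#' fold change (the "top 1 percent most-enriched windows" convention),
#' ties at the boundary broken by row order.
#'
#' @param table an enrichment tibble from [compute_log2fc()].
#' @param quantile proportion of rows to flag, in (0, 1].
#' @return the table with a logical `top_flag` column.
#' @export
select_top <- function(table, quantile = 0.01) {
  if (nrow(table) == 0) abort("enrichment table is empty")
  if (!is.numeric(quantile) || quantile <= 0 || quantile > 1) {
    abort("`quantile` must be in (0, 1].",
          class = "predscreen_invalid_parameter")
  }
  k <- ceiling(quantile * nrow(table))
  mutate(table, top_flag = .data$rank <= k)
}

#' Per-row replicate summaries
#'
#' Plain mean +/- SD aggregation across replicate columns for
#' reporting; with a single replicate the SD is reported as missing.
#'
#' @param matrix a `tn_counts` matrix.
#' @param groups named list mapping group label to column names.
#' @return tibble with `row_id`, `group`, `n`, `mean`, `sd`.
#' @export
summarize_replicates <- function(matrix, groups) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  purrr::map_dfr(names(groups), function(g) {
    m <- as.matrix(matrix[groups[[g]]])
    tibble(row_id = matrix$row_id, group = g, n = ncol(m),
           mean = rowMeans(m),
           sd = if (ncol(m) < 2) NA_real_ else apply(m, 1L, sd))
  })
}

#' Principal component summary of sample structure
#'
#' PCA of samples in row space: each row (window/feature) is centered
#' across samples, optionally after a log2(x + 1) transform, and
#' samples are projected on orthonormal components, mirroring the way
#' replicate clustering is assessed in pooled screens.
#'
#' @param matrix a `tn_counts` matrix with >= 2 samples.
#' @param log_transform apply log2(x + 1) first (default TRUE).
#' @param n_components number of components to retain; must not exceed
#'   the number of samples.
#' @return a `tn_pca` object with `scores` (tibble: `sample`, `PC1`,
#'   ...) and `explained_variance` (non-increasing fractions summing to
#'   <= 1). Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
run_pca <- function(matrix, log_transform = TRUE, n_components = 2) {
  cols <- sample_cols(matrix)
  if (length(cols) < 2) abort("PCA needs at least 2 samples")
  if (n_components > length(cols)) {
    abort("fewer samples than requested components")
  }
  x <- t(as.matrix(matrix[cols]))
  if (log_transform) x <- log2(x + 1)
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x[, seq_len(k), drop = FALSE])
  scores <- bind_cols(tibble(sample = cols), scores)
  structure(list(scores = scores,
                 explained_variance = ev[seq_len(k)],
                 n_components = k),
            class = "tn_pca")
}

#' @export
print.tn_pca <- function(x, ...) {
  cat(sprintf("<tn_pca> %d samples, %d components (%s%% variance)\n",
              nrow(x$scores), x$n_components,
              paste(round(100 * x$explained_variance, 1), collapse = "/")))
  print(x$scores)
  invisible(x)
}
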