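#' Count matrix constructor
#'
#' A count matrix is a tibble with a `row_id` column (window or feature
#' identifiers) and one numeric column per sample, carrying two
#' attributes: `normalized` (logical) and `excluded`, a tibble of rows
#' removed by filtering with the reason for each.
#'
#' @param x data frame with `row_id` plus numeric sample columns.
#' @param normalized whether columns are on a common (CPM) scale.
#' @param excluded tibble (`row_id`, `reason`) of filtered-out rows.
#' @return a `tn_counts` tibble.
#' @export
as_count_matrix <- function(x, normalized = FALSE, excluded = NULL) {
  stopifnot("row_id" %in% names(x))
  vals <- as.matrix(x[setdiff(names(x), "row_id")])
  if (any(vals < 0)) abort("count matrix values must be non-negative")
  out <- as_tibble(x)
  attr(out, "normalized") <- normalized
  attr(out, "excluded") <- excluded %||%
    tibble(row_id = character(), reason = character())
  class(out) <- c("tn_counts", class(tibble()))
  out
}

#' @rdname as_count_matrix
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' @rdname as_count_matrix
#' @export
excluded_rows <- function(x) {
  attr(x, "excluded") %||% tibble(row_id = character(), reason = character())
}

sample_cols <- function(matrix) setdiff(names(matrix), "row_id")

#' Tile a genome into fixed-length windows
#'
#' Non-overlapping windows anchored at position 1; the final window is
#' truncated at the genome end (no wrap-around for circular genomes).
#'
#' @param genome_length chromosome length in bp.
#' @param window_length window size in bp (default 200).
#' @return tibble with `window` (index), `start`, `end` (1-based
#'   inclusive), and `row_id` of the form `"<index>:<start>-<end>"`.
#' @export
tile_windows <- function(genome_length, window_length = 200) {
  check_positive(genome_length, "genome_length")
  if (window_length < 1) abort("`window_length` must be >= 1.",
                               class = "predscreen_invalid_parameter")
  n <- ceiling(genome_length / window_length)
  start <- (seq_len(n) - 1L) * window_length + 1
  end <- pmin(seq_len(n) * window_length, genome_length)
  tibble(window = seq_len(n), start = start, end = end,
         row_id = sprintf("%d:%d-%d", seq_len(n), start, end))
}

#' Count insertions per window
#'
#' @param profile insertion profile tibble (`position`, `count`).
#' @param windows a [tile_windows()] table.
#' @return the windows table with a `count` column; total counts are
#'   conserved.
#' @export
count_windows <- function(profile, windows) {
  if (nrow(profile) > 0 &&
      max(profile$position) > max(windows$end)) {
    abort("profile positions extend beyond the tiled genome")
  }
  idx <- findInterval(profile$position, windows$start)
  counts <- rep(0, nrow(windows))
  if (nrow(profile) > 0) {
    agg <- tapply(profile$count, idx, sum)
    counts[as.integer(names(agg))] <- agg
  }
  mutate(windows, count = counts)
}

#' Count insertions per annotated feature
#'
#' Insertions falling within `[start, end]` of each feature are summed
#' per feature. An insertion inside several overlapping (e.g. nested)
#' features is counted once for every feature it hits, so totals over
#' feature rows can exceed the profile total when annotations overlap.
#' Insertions outside every feature are reported under synthetic
#' `intergenic:<start>-<end>` rows, one per annotation gap, so that
#' for non-overlapping annotations total counts are conserved.
#'
#' @param profile insertion profile tibble (`position`, `count`).
#' @param features data frame with `locus_tag`, `start`, `end`.
#' @param genome_length chromosome length (for the trailing gap);
#'   default: max of feature ends and profile positions.
#' @return tibble with `row_id`, `start`, `end`, `type`
#'   ("cds"/"intergenic"), `count`.
#' @export
count_features <- function(profile, features, genome_length = NULL) {
  stopifnot(all(c("locus_tag", "start", "end") %in% names(features)))
  genome_length <- genome_length %||%
    max(features$end, profile$position, 1)
  feat_ir <- IRanges::IRanges(start = features$start, end = features$end)
  gaps_ir <- IRanges::gaps(IRanges::reduce(feat_ir), start = 1L,
                           end = as.integer(genome_length))
  pos_ir <- IRanges::IRanges(profile$position, profile$position)

  tally <- function(ir) {
    hits <- IRanges::findOverlaps(pos_ir, ir)
    counts <- rep(0, length(ir))
    if (length(hits) > 0) {
      agg <- tapply(profile$count[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits), sum)
      counts[as.integer(names(agg))] <- agg
    }
    counts
  }
  bind_rows(
    tibble(row_id = features$locus_tag, start = features$start,
           end = features$end, type = "cds", count = tally(feat_ir)),
    tibble(row_id = sprintf("intergenic:%d-%d", IRanges::start(gaps_ir),
                            IRanges::end(gaps_ir)),
           start = IRanges::start(gaps_ir), end = IRanges::end(gaps_ir),
           type = "intergenic", count = tally(gaps_ir))
  ) |> arrange(.data$start, .data$type)
}

#' Assemble a count matrix from several samples
#'
#' @param profiles named list of insertion profile tibbles; names become
#'   sample (column) ids.
#' @param windows a [tile_windows()] table (window-based counting), or
#' @param features a feature table (feature-based counting, see
#'   [count_features()]).
#' @param genome_length passed to [count_features()].
#' @return a raw [as_count_matrix()] matrix.
#' @export
count_matrix <- function(profiles, windows = NULL, features = NULL,
                         genome_length = NULL) {
  stopifnot(is.list(profiles), !is.null(names(profiles)),
            xor(is.null(windows), is.null(features)))
  per_sample <- purrr::map(profiles, function(p) {
    if (!is.null(windows)) {
      count_windows(p, windows)[, c("row_id", "count")]
    } else {
      count_features(p, features, genome_length)[, c("row_id", "count")]
    }
  })
  out <- per_sample[[1]]["row_id"]
  for (s in names(per_sample)) out[[s]] <- per_sample[[s]]$count
  as_count_matrix(out, normalized = FALSE)
}

#' Scale samples to equal column totals (CPM)
#'
#' Each sample column is scaled so that its total equals `scale`
#' (counts-per-million by default), making per-row values comparable
#' across samples. Within-column ratios are preserved and the operation
#' is idempotent.
#'
#' @param matrix a `tn_counts` matrix.
#' @param scale common column total after scaling.
#' @return the normalized matrix with the `normalized` flag set.
#' @export
normalize_counts <- function(matrix, scale = 1e6) {
  cols <- sample_cols(matrix)
  if (length(cols) == 0 || nrow(matrix) == 0) abort("empty count matrix")
  totals <- vapply(matrix[cols], sum, numeric(1))
  if (any(totals == 0)) {
    abort(sprintf("sample(s) with zero total counts: %s",
                  paste(cols[totals == 0], collapse = ", ")))
  }
  out <- matrix
  for (s in cols) out[[s]] <- out[[s]] * scale / totals[[s]]
  as_count_matrix(out, normalized = TRUE, excluded = excluded_rows(matrix))
}

#' Exclude low-coverage rows relative to the starting population
#'
#' Rows (windows or features) whose mean count across the starting
#' population (input) samples is below `fraction` of the median of
#' those means are moved to the matrix's excluded set. The median is
#' taken over rows with a nonzero input mean, so never-inserted regions
#' cannot drag it to zero; such all-zero rows are themselves excluded
#' for any `fraction > 0`.
#'
#' @param matrix a `tn_counts` matrix.
#' @param input_samples column names of the starting-population samples.
#' @param fraction threshold as a fraction of the median input mean
#'   (default 0.05).
#' @return the filtered matrix; removed rows are recorded in
#'   [excluded_rows()]. Raising `fraction` never un-excludes a row.
#' @export
filter_low_coverage <- function(matrix, input_samples, fraction = 0.05) {
  if (nrow(matrix) == 0) abort("empty count matrix")
  check_proportion(fraction, "fraction")
  if (!all(input_samples %in% sample_cols(matrix))) {
    abort("`input_samples` must be columns of the matrix")
  }
  means <- rowMeans(as.matrix(matrix[input_samples]))
  med <- median(means[means > 0])
  thr <- fraction * med
  drop <- means < thr
  excl <- bind_rows(
    excluded_rows(matrix),
    tibble(row_id = matrix$row_id[drop],
           reason = sprintf("mean input count %.4g below %.4g (%.3g x median %.4g)",
                            means[drop], thr, fraction, med)))
  as_count_matrix(matrix[!drop, , drop = FALSE],
                  normalized = is_normalized(matrix), excluded = excl)
}
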