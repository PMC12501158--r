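#' Scan a CDS for homopolymer repeats
#'
#' Finds all maximal single-nucleotide runs of length >= `min_run` on
#' the coding strand, in coordinate order -- the substrate of
#' slipped-strand mispairing and hence of phase variation.
#'
#' @param cds coding-strand nucleotide string (A/C/G/T only; other
#'   characters raise an error listing the offending positions).
#' @param min_run minimum run length (default 8, the canonical 8-mer
#'   criterion).
#' @param base optional filter: report only runs of this nucleotide
#'   (e.g. `"A"` for polyadenine tracts).
#' @return tibble with `base`, `start_in_cds` (1-based), `run_length`.
#' @export
scan_repeats <- function(cds, min_run = 8L, base = NULL) {
  if (length(cds) != 1L || !is.character(cds) || nchar(cds) == 0L) {
    abort("`cds` must be a single non-empty string")
  }
  chars <- strsplit(cds, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% BASES)
  if (length(bad) > 0) {
    abort(sprintf("non-ACGT character(s) at position(s): %s",
                  paste(utils::head(bad, 10L), collapse = ", ")),
          class = "predscreen_invalid_sequence")
  }
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_run
  if (!is.null(base)) keep <- keep & r$values %in% base
  tibble(base = r$values[keep],
         start_in_cds = as.integer(ends[keep] - r$lengths[keep] + 1L),
         run_length = as.integer(r$lengths[keep]))
}

#' Call a repeat-length change in one ortholog
#'
#' Locates a reference homopolymer run inside an ortholog CDS via its
#' exact 12 bp flanking anchor sequences (each must occur exactly once,
#' in order; otherwise the call is `alignable = FALSE` and the ortholog
#' is excluded from denominators). The run length is measured between
#' the anchors; a length change not divisible by 3 shifts the reading
#' frame. The ortholog is then scanned from its start codon for the
#' first in-frame stop: a stop before `stop_cutoff` of the reference
#' protein length is a premature stop, and
#' `inactivating = frameshifted & premature_stop`.
#'
#' @param ortholog_cds ortholog coding-strand sequence.
#' @param repeat_locus one row of a [scan_repeats()] table for the
#'   reference.
#' @param reference_cds reference coding-strand sequence.
#' @param anchor flanking anchor length in bp (default 12).
#' @param stop_cutoff premature-stop cutoff as fraction of reference
#'   protein length (default 0.9).
#' @return one-row tibble: `alignable`, `length_delta`, `frameshifted`,
#'   `premature_stop`, `stop_position_fraction`, `inactivating`.
#' @export
compare_ortholog <- function(ortholog_cds, repeat_locus, reference_cds,
                             anchor = 12L, stop_cutoff = 0.9) {
  rstart <- repeat_locus$start_in_cds
  rlen <- repeat_locus$run_length
  rend <- rstart + rlen - 1L
  unalignable <- tibble(alignable = FALSE, length_delta = NA_integer_,
                        frameshifted = NA, premature_stop = NA,
                        stop_position_fraction = NA_real_,
                        inactivating = NA)
  if (rstart <= anchor || rend + anchor > nchar(reference_cds)) {
    return(unalignable)
  }
  left <- substr(reference_cds, rstart - anchor, rstart - 1L)
  right <- substr(reference_cds, rend + 1L, rend + anchor)
  find_once <- function(pattern) {
    m <- gregexpr(pattern, ortholog_cds, fixed = TRUE)[[1]]
    if (length(m) != 1L || m[1L] == -1L) NA_integer_ else as.integer(m[1L])
  }
  lpos <- find_once(left)
  rpos <- find_once(right)
  if (is.na(lpos) || is.na(rpos)) return(unalignable)
  run_start <- lpos + anchor
  run_len <- rpos - run_start
  if (run_len < 0) return(unalignable)
  if (run_len > 0) {
    region <- substr(ortholog_cds, run_start, rpos - 1L)
    if (gsub(repeat_locus$base, "", region, fixed = TRUE) != "") {
      return(unalignable)
    }
  }
  delta <- run_len - rlen
  frameshifted <- (delta %% 3L) != 0L
  ref_stop <- nchar(reference_cds) %/% 3L
  stop_idx <- first_stop_index(ortholog_cds)
  stop_frac <- if (is.na(stop_idx)) NA_real_ else stop_idx / ref_stop
  premature <- !is.na(stop_frac) && stop_frac < stop_cutoff
  tibble(alignable = TRUE, length_delta = as.integer(delta),
         frameshifted = frameshifted, premature_stop = premature,
         stop_position_fraction = stop_frac,
         inactivating = frameshifted && premature)
}

#' Fraction of orthologs inactivated by repeat frameshifts, per gene
#'
#' For each reference gene carrying at least one homopolymer run
#' >= `min_run` (genes without one are excluded from the output), every
#' ortholog is tested at every run with [compare_ortholog()]. An
#' ortholog is alignable when all runs anchor uniquely, and
#' inactivating when any run shows a frameshifting length change with a
#' premature stop. The reported fraction is
#' `n_inactivating / n_alignable`; with zero alignable orthologs the
#' fraction is missing.
#'
#' @param orthologs tibble (`locus_tag`, `strain_id`, `cds`) of
#'   ortholog sequences, as from [generate_pangenome()].
#' @param references named character vector of reference CDS sequences
#'   (names are locus tags), e.g. from [cds_seq()].
#' @param min_run minimum homopolymer run length (default 8).
#' @param anchor,stop_cutoff passed to [compare_ortholog()].
#' @return tibble: `locus_tag`, `n_orthologs`, `n_unalignable`,
#'   `n_frameshifted`, `n_inactivating`, `fraction`.
#' @export
gene_frameshift_fraction <- function(orthologs, references, min_run = 8L,
                                     anchor = 12L, stop_cutoff = 0.9) {
  stopifnot(all(c("locus_tag", "strain_id", "cds") %in% names(orthologs)))
  tags <- intersect(names(references), unique(orthologs$locus_tag))
  purrr::map_dfr(tags, function(tag) {
    ref <- references[[tag]]
    runs <- scan_repeats(ref, min_run = min_run)
    if (nrow(runs) == 0) return(NULL)
    orth <- orthologs[orthologs$locus_tag == tag, , drop = FALSE]
    calls <- purrr::map_dfr(seq_len(nrow(orth)), function(k) {
      per_run <- purrr::map_dfr(seq_len(nrow(runs)), function(ri) {
        compare_ortholog(orth$cds[k], runs[ri, ], ref,
                         anchor = anchor, stop_cutoff = stop_cutoff)
      })
      tibble(alignable = all(per_run$alignable),
             frameshifted = all(per_run$alignable) &&
               any(per_run$frameshifted),
             inactivating = all(per_run$alignable) &&
               any(per_run$inactivating))
    })
    n_align <- sum(calls$alignable)
    tibble(locus_tag = tag,
           n_orthologs = nrow(orth),
           n_unalignable = nrow(orth) - n_align,
           n_frameshifted = sum(calls$frameshifted),
           n_inactivating = sum(calls$inactivating),
           fraction = if (n_align > 0) sum(calls$inactivating) / n_align
                      else NA_real_)
  })
}

#' Rank genes by frameshifted-ortholog fraction
#'
#' Descending sort by inactivated fraction, ties broken by locus tag;
#' the top `ceiling(top_quantile * n)` genes are flagged (the
#' "top 5 percent of frameshifts among repeat-bearing genes" rule).
#'
#' @param summaries a [gene_frameshift_fraction()] table.
#' @param top_quantile proportion of genes to flag (default 0.05).
#' @return the table sorted, with `rank` and `top_flag` columns.
#' @export
rank_by_fraction <- function(summaries, top_quantile = 0.05) {
  check_proportion(top_quantile, "top_quantile")
  out <- arrange(summaries, desc(.data$fraction), .data$locus_tag)
  out$rank <- seq_len(nrow(out))
  out$top_flag <- out$rank <= ceiling(top_quantile * nrow(out))
  out
}
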