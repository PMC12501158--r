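# Replace every homopolymer run of length > max_run in `chars` by
# substituting the base that would extend the run; `protect` marks
# positions that must not be touched.
break_runs_chars <- function(chars, max_run, protect = NULL) {
  r <- rle(chars)
  if (!any(r$lengths > max_run)) return(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$lengths > max_run)) {
    pos <- seq(starts[i] + max_run, ends[i], by = max_run + 1L)
    for (p in pos) {
      if (!is.null(protect) && protect[p]) next
      chars[p] <- setdiff(BASES, r$values[i])[1L]
    }
  }
  chars
}

# Random intergenic sequence without homopolymer runs > 5, so that runs
# can never reach 8 across a segment boundary.
random_intergenic <- function(n) {
  if (n <= 0) return("")
  paste(break_runs_chars(random_bases(n), max_run = 5L), collapse = "")
}

# Random CDS of n_codons codons (ATG ... TAA) with no internal stop codon
# and no homopolymer run >= 8 anywhere in the coding sequence.
random_cds_codons <- function(n_codons) {
  stopifnot(n_codons >= 3L)
  cods <- c("ATG", sample(SENSE_CODONS, n_codons - 2L, replace = TRUE), "TAA")
  for (iter in seq_len(200L)) {
    chars <- strsplit(paste(cods, collapse = ""), "", fixed = TRUE)[[1]]
    r <- rle(chars)
    bad <- which(r$lengths >= 8L)
    if (length(bad) == 0L) break
    end_pos <- cumsum(r$lengths)[bad[1L]]
    cod_idx <- (end_pos - 1L) %/% 3L + 1L
    cod_idx <- min(max(cod_idx, 2L), n_codons - 1L)
    cods[cod_idx] <- sample(SENSE_CODONS, 1L)
  }
  cods
}

# Overwrite codons j..j+4 with an in-frame poly-A 9-mer followed by a
# context in which a -1 slippage deletion immediately creates a TAA stop:
# ref  ... AAA AAA AAA CTA ACT ...
# -1 A ... AAA AAA AAC TAA ...   (premature stop right after the run)
plant_repeat <- function(cods, j) {
  if (substr(cods[j - 1L], 3L, 3L) == "A") cods[j - 1L] <- "GGT"
  cods[j:(j + 4L)] <- c("AAA", "AAA", "AAA", "CTA", "ACT")
  cods
}

#' Generate a synthetic annotated bacterial genome
#'
#' Builds a random single-chromosome genome of alternating intergenic
#' spacers and protein-coding sequences whose length distributions have
#' (approximately) the requested medians, mimicking the summary
#' statistics of a typical *Bacillus subtilis*-like chromosome. A chosen
#' fraction of CDSs carries an in-frame homopolymer (poly-A) run of
#' length 9, placed so that a -1 slippage deletion shifts the reading
#' frame into an immediate premature stop codon -- the substrate for
#' phase-variation scanning. Random sequence is generated free of
#' accidental runs >= 8 nt so planted repeat genes are exact ground
#' truth.
#'
#' @param n_genes number of CDS features (>= 1).
#' @param median_cds_len target median CDS length in bp (rounded to
#'   codons).
#' @param median_intergenic_len target median intergenic spacer in bp.
#' @param repeat_gene_fraction fraction of CDSs that receive a planted
#'   homopolymer run.
#' @param essential_fraction fraction of genes flagged essential
#'   (insertion-free zones for library generation).
#' @param cds_sdlog,intergenic_sdlog log-scale SDs of the log-normal
#'   length distributions.
#' @param seed integer seed; identical seeds give bit-identical genomes.
#'
#' @return An object of class `synthetic_genome`: a list with `length`
#'   (bp), `sequence` (chromosome string), and `features`, a tibble with
#'   columns `locus_tag`, `start`, `end` (1-based inclusive), `strand`,
#'   `essential`, `has_repeat`, sorted by `start`.
#' @export
generate_genome <- function(n_genes,
                            median_cds_len = 744,
                            median_intergenic_len = 115,
                            repeat_gene_fraction = 0.05,
                            essential_fraction = 0.06,
                            cds_sdlog = 0.7,
                            intergenic_sdlog = 0.9,
                            seed = 1L) {
  check_positive(n_genes, "n_genes")
  check_positive(median_cds_len, "median_cds_len")
  check_positive(median_intergenic_len, "median_intergenic_len")
  check_proportion(repeat_gene_fraction, "repeat_gene_fraction")
  check_proportion(essential_fraction, "essential_fraction")

  withr::with_seed(as.integer(seed), {
    n_cod <- pmax(10L, as.integer(round(
      rlnorm(n_genes, log(median_cds_len), cds_sdlog) / 3)))
    gap_len <- as.integer(round(
      rlnorm(n_genes, log(median_intergenic_len), intergenic_sdlog)))
    n_repeat <- round(repeat_gene_fraction * n_genes)
    repeat_genes <- sort(sample.int(n_genes, n_repeat))
    n_cod[repeat_genes] <- pmax(n_cod[repeat_genes], 15L)
    essential <- runif(n_genes) < essential_fraction
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)

    segments <- character(2L * n_genes)
    start <- end <- integer(n_genes)
    pos <- 0L
    for (i in seq_len(n_genes)) {
      spacer <- random_intergenic(gap_len[i])
      cods <- random_cds_codons(n_cod[i])
      if (i %in% repeat_genes) {
        j_max <- min(floor(0.55 * n_cod[i]), n_cod[i] - 5L)
        j <- if (j_max <= 6L) 6L else sample(6:j_max, 1L)
        cods <- plant_repeat(cods, j)
      }
      cds <- paste(cods, collapse = "")
      if (strand[i] == "-") cds_genomic <- revcomp(cds) else cds_genomic <- cds
      segments[2L * i - 1L] <- spacer
      segments[2L * i] <- cds_genomic
      start[i] <- pos + gap_len[i] + 1L
      end[i] <- start[i] + 3L * n_cod[i] - 1L
      pos <- end[i]
    }

    features <- tibble(
      locus_tag = sprintf("g%04d", seq_len(n_genes)),
      start = start, end = end, strand = strand,
      essential = essential,
      has_repeat = seq_len(n_genes) %in% repeat_genes
    )
    structure(
      list(length = pos, sequence = paste(segments, collapse = ""),
           features = features),
      class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> %s bp, %d CDS (%d essential, %d repeat-bearing)\n",
    format(x$length, big.mark = ","), nrow(x$features),
    sum(x$features$essential), sum(x$features$has_repeat)))
  invisible(x)
}

#' Extract coding-strand CDS sequences from a synthetic genome
#'
#' @param genome a `synthetic_genome`.
#' @param locus_tags loci to extract; default all.
#' @return named character vector of coding-strand sequences.
#' @export
cds_seq <- function(genome, locus_tags = NULL) {
  feats <- genome$features
  if (!is.null(locus_tags)) {
    feats <- feats[match(locus_tags, feats$locus_tag), , drop = FALSE]
    if (anyNA(feats$start)) abort("unknown locus_tag")
  }
  seqs <- substring(genome$sequence, feats$start, feats$end)
  seqs[feats$strand == "-"] <- revcomp(seqs[feats$strand == "-"])
  setNames(seqs, feats$locus_tag)
}

#' Summarise CDS and intergenic length distributions of an annotation
#'
#' Computes the genome summary statistics used to motivate a window
#' size: median CDS length and median intergenic gap, with 5th/95th
#' percentiles. Works on any feature table with 1-based inclusive
#' `start`/`end` columns sorted or unsorted.
#'
#' @param features data frame with `start` and `end` columns (one row
#'   per CDS).
#' @param genome_length chromosome length in bp (for the trailing gap);
#'   default: last feature end.
#' @return tibble with one row per statistic class (`cds`,
#'   `intergenic`) and columns `n`, `median`, `p5`, `p95`.
#' @export
annotation_summary <- function(features, genome_length = NULL) {
  stopifnot(all(c("start", "end") %in% names(features)))
  features <- arrange(features, .data$start)
  genome_length <- genome_length %||% max(features$end)
  cds_len <- features$end - features$start + 1
  gap <- pmax(0, features$start - dplyr::lag(features$end, default = 0) - 1)
  tail_gap <- genome_length - max(features$end)
  if (tail_gap > 0) gap <- c(gap, tail_gap)
  summarise_len <- function(x, what) {
    tibble(class = what, n = length(x), median = median(x),
           p5 = unname(quantile(x, 0.05)), p95 = unname(quantile(x, 0.95)))
  }
  bind_rows(summarise_len(cds_len, "cds"), summarise_len(gap, "intergenic"))
}
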