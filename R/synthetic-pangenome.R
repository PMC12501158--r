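apply_substitutions <- function(seq, rate, protect_start, protect_end) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  protect <- rep(FALSE, length(chars))
  for (i in seq_along(protect_start)) {
    protect[protect_start[i]:protect_end[i]] <- TRUE
  }
  idx <- which(runif(length(chars)) < rate & !protect)
  for (i in idx) chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  paste(chars, collapse = "")
}

apply_indel <- function(seq, pos, delta, base) {
  n <- nchar(seq)
  if (delta == -1L) {
    paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + 1L, n))
  } else {
    paste0(substr(seq, 1L, pos - 1L), base, substr(seq, pos, n))
  }
}

#' Generate a synthetic pangenome with planted repeat-slippage indels
#'
#' For every CDS of the reference genome, emits one ortholog per strain.
#' With probability `frameshift_rate` an ortholog of a repeat-bearing
#' gene (a gene containing at least one homopolymer run >= 8 nt; genes
#' without such runs are never frameshifted) receives a single +1/-1 bp
#' slippage indel inside a randomly chosen run -- the mutational
#' signature of slipped-strand mispairing. Point substitutions are added
#' independently per base outside repeat runs. Ground truth for each
#' planted indel, including whether the shifted frame hits a premature
#' stop codon (determined by direct in-frame stop scanning of the
#' mutated sequence), is recorded for recovery testing.
#'
#' @param genome a [generate_genome()] result (the reference).
#' @param n_strains number of strains (orthologs per gene).
#' @param frameshift_rate per-gene, per-strain probability of a planted
#'   slippage indel (only effective in repeat-bearing genes).
#' @param substitution_rate per-base substitution probability outside
#'   repeat runs.
#' @param min_run minimum homopolymer run length eligible for slippage.
#' @param stop_cutoff premature-stop cutoff as a fraction of the
#'   reference protein length, used when recording truth.
#' @param seed integer seed.
#' @return list with `orthologs`, a tibble (`locus_tag`, `strain_id`,
#'   `cds`), and `truth`, a tibble of planted calls (`locus_tag`,
#'   `strain_id`, `run_start`, `base`, `delta`, `frameshifted`,
#'   `premature_stop`, `inactivating`).
#' @export
generate_pangenome <- function(genome, n_strains, frameshift_rate = 0.05,
                               substitution_rate = 0, min_run = 8L,
                               stop_cutoff = 0.9, seed = 1L) {
  check_proportion(frameshift_rate, "frameshift_rate")
  check_proportion(substitution_rate, "substitution_rate")
  check_positive(n_strains, "n_strains")
  refs <- cds_seq(genome)
  strains <- sprintf("s%03d", seq_len(n_strains))
  withr::with_seed(as.integer(seed), {
    per_gene <- purrr::map(names(refs), function(tag) {
      ref <- refs[[tag]]
      runs <- scan_repeats(ref, min_run = min_run)
      ref_stop <- nchar(ref) %/% 3L
      seqs <- character(n_strains)
      truth <- vector("list", n_strains)
      for (k in seq_len(n_strains)) {
        s <- apply_substitutions(ref, substitution_rate,
                                 runs$start_in_cds,
                                 runs$start_in_cds + runs$run_length - 1L)
        if (nrow(runs) > 0 && runif(1) < frameshift_rate) {
          ri <- if (nrow(runs) == 1L) 1L else sample.int(nrow(runs), 1L)
          delta <- sample(c(-1L, 1L), 1L)
          s <- apply_indel(s, runs$start_in_cds[ri], delta, runs$base[ri])
          stop_idx <- first_stop_index(s)
          premature <- !is.na(stop_idx) && stop_idx / ref_stop < stop_cutoff
          truth[[k]] <- tibble(
            locus_tag = tag, strain_id = strains[k],
            run_start = runs$start_in_cds[ri], base = runs$base[ri],
            delta = delta, frameshifted = TRUE,
            premature_stop = premature,
            inactivating = premature)
        }
        seqs[k] <- s
      }
      list(orthologs = tibble(locus_tag = tag, strain_id = strains,
                              cds = seqs),
           truth = bind_rows(truth))
    })
    list(orthologs = bind_rows(purrr::map(per_gene, "orthologs")),
         truth = bind_rows(purrr::map(per_gene, "truth")))
  })
}

#' Generate a bimodal cell-length table
#'
#' Mixture of two zero-truncated normal components: ordinary single
#' cells and filaments, with the component labels recorded as ground
#' truth for downstream filament classification.
#'
#' @param n number of cells.
#' @param single_mean,single_sd single-cell length distribution (um).
#' @param filament_fraction proportion of cells in the filament
#'   component.
#' @param filament_mean,filament_sd filament length distribution (um).
#' @param condition optional condition label stored per row.
#' @param seed integer seed.
#' @return tibble with `length_um`, `component` ("single"/"filament"),
#'   `condition`.
#' @export
generate_cell_lengths <- function(n, single_mean = 4.96, single_sd = 1.2,
                                  filament_fraction = 0.1,
                                  filament_mean = 20, filament_sd = 8,
                                  condition = NA_character_, seed = 1L) {
  check_positive(n, "n")
  check_positive(single_mean, "single_mean")
  check_positive(filament_mean, "filament_mean")
  check_proportion(filament_fraction, "filament_fraction")
  rtrunc_norm <- function(m, mean, sd) {
    if (m == 0L) return(numeric(0))
    x <- rnorm(m, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
    x
  }
  withr::with_seed(as.integer(seed), {
    fil <- runif(n) < filament_fraction
    len <- numeric(n)
    len[!fil] <- rtrunc_norm(sum(!fil), single_mean, single_sd)
    len[fil] <- rtrunc_norm(sum(fil), filament_mean, filament_sd)
    tibble(length_um = len,
           component = ifelse(fil, "filament", "single"),
           condition = condition)
  })
}

#' Generate two-channel competition event counts
#'
#' Emulates flow-cytometry readout of a mutant/wild-type competition:
#' mutant-channel events are binomial in the true mutant frequency,
#' the remainder are wild type.
#'
#' @param true_frequency true mutant frequency in the population.
#' @param n_events total events recorded.
#' @param seed integer seed.
#' @return one-row tibble with `mutant_events`, `wildtype_events`.
#' @export
generate_competition <- function(true_frequency, n_events, seed = 1L) {
  check_proportion(true_frequency, "true_frequency")
  check_positive(n_events, "n_events")
  withr::with_seed(as.integer(seed), {
    m <- rbinom(1L, n_events, true_frequency)
    tibble(mutant_events = m, wildtype_events = as.integer(n_events) - m)
  })
}
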