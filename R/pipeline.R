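write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the all-synthetic demonstration pipeline
#'
#' Generates a synthetic genome, transposon library, and predation
#' screens, then runs every analysis stage end to end: window
#' quantification with normalization and low-coverage filtering,
#' top-quantile enrichment with PCA, bottleneck bracketing of the
#' consumed-cell fraction, pangenome phase-variation scanning, and
#' phenotype statistics (filamentation, competition). All outputs are
#' written as plain-text files (wig, FASTA, TSV) under `out_dir`,
#' together with a JSON manifest of parameters, per-stage seeds, and
#' output checksums. Every stage receives a seed derived
#' deterministically from `seed` and the stage name, so reruns with
#' identical arguments are bit-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed.
#' @param n_genes,n_sites,population_size,recovery_depth,
#'   survival_fraction,resistance_advantage,n_resistant,n_replicates
#'   screen-scale parameters (defaults are demo-sized so the pipeline
#'   completes in seconds).
#' @return invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_demo <- function(out_dir, seed = 1L,
                     n_genes = 120, n_sites = 2000,
                     population_size = 2e5, recovery_depth = 2e5,
                     survival_fraction = 1e-3,
                     resistance_advantage = 100,
                     n_resistant = 20, n_replicates = 3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  params <- list(seed = seed, n_genes = n_genes, n_sites = n_sites,
                 population_size = population_size,
                 recovery_depth = recovery_depth,
                 survival_fraction = survival_fraction,
                 resistance_advantage = resistance_advantage,
                 n_resistant = n_resistant, n_replicates = n_replicates)
  seeds <- purrr::map(
    setNames(nm = c("genome", "library", "screen", "pangenome",
                    "cells", "competition")),
    function(st) derive_seed(seed, st))

  # -- synthetic inputs ---------------------------------------------------
  genome <- generate_genome(n_genes, repeat_gene_fraction = 0.1,
                            seed = seeds$genome)
  seqinr::write.fasta(strsplit(genome$sequence, "")[[1]], "chr",
                      path("genome.fna"))
  write_tsv_file(genome$features, path("features.tsv"))
  lib <- generate_library(genome, n_sites, abundance_sigma = 1,
                          depth = population_size, seed = seeds$library)
  write_wig(lib$profile, path("input.wig"), chrom = "chr")

  truth <- screen_truth(survival_fraction,
                        resistant_sites = sort(sample_resistant(
                          lib$profile$position, n_resistant,
                          seeds$screen)),
                        resistance_advantage = resistance_advantage,
                        seed = seeds$screen)
  screens <- simulate_screen(lib$profile, truth, recovery_depth,
                             n_replicates)
  for (r in seq_len(n_replicates)) {
    write_wig(filter(screens, .data$replicate == r)[c("position", "count")],
              path(sprintf("predation_rep%d.wig", r)), chrom = "chr")
  }

  # -- quantification -----------------------------------------------------
  windows <- tile_windows(genome$length, 200)
  profiles <- c(list(input = lib$profile),
                setNames(
                  purrr::map(seq_len(n_replicates), function(r) {
                    filter(screens, .data$replicate == r)[
                      c("position", "count")]
                  }),
                  sprintf("pred_rep%d", n_replicates |> seq_len())))
  mat <- count_matrix(profiles, windows = windows)
  norm <- normalize_counts(mat)
  filt <- filter_low_coverage(norm, input_samples = "input",
                              fraction = 0.05)
  write_tsv_file(filt, path("window_counts_normalized.tsv"))

  # -- enrichment ---------------------------------------------------------
  enr <- compute_log2fc(filt,
                        predation_cols = sprintf("pred_rep%d",
                                                 seq_len(n_replicates)),
                        control_cols = "input") |>
    select_top(0.01)
  write_tsv_file(enr, path("enrichment.tsv"))
  pca <- run_pca(filt)

  # -- bottleneck ---------------------------------------------------------
  cfg <- bottleneck_config(population_size = population_size,
                           recovery_depth = recovery_depth,
                           n_sim = 10, seed = derive_seed(seed, "bneck"))
  sims <- depletion_stats(simulate_expected_counts(lib$profile, cfg),
                          lib$profile)
  obs <- depletion_stats(screens, lib$profile)
  fit <- estimate_survival_range(obs, sims)
  write_tsv_file(sims, path("depletion_simulated.tsv"))
  writeLines(consumed_fraction_report(fit), path("bottleneck_report.txt"))

  # -- phase variation ----------------------------------------------------
  pan <- generate_pangenome(genome, n_strains = 40, frameshift_rate = 0.1,
                            seed = seeds$pangenome)
  fs <- gene_frameshift_fraction(pan$orthologs, cds_seq(genome)) |>
    rank_by_fraction(0.05)
  write_tsv_file(fs, path("phase_variation.tsv"))

  # -- phenotypes ---------------------------------------------------------
  cells <- bind_rows(
    generate_cell_lengths(1500, filament_fraction = 0.02,
                          condition = "no_predation", seed = seeds$cells),
    generate_cell_lengths(1500, filament_fraction = 0.25,
                          condition = "high_predation",
                          seed = seeds$cells + 1L))
  thr <- filament_threshold(cells$length_um)
  vols <- volume_fractions(cells, thr$threshold)
  write_tsv_file(vols, path("filamentation.tsv"))
  comp <- purrr::map_dfr(1:6, function(r) {
    generate_competition(0.3, 10000, seed = seeds$competition + r)
  }) |> estimate_frequency()
  comp_tests <- bind_rows(
    mutate(test_frequency(comp$frequency, mu = 0.1), test = "frequency"),
    mutate(test_log_ratio(comp$frequency, initial = 0.1),
           test = "log_ratio"))
  write_tsv_file(comp_tests, path("competition_tests.tsv"))

  # -- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    params = params, seeds = seeds,
    truth = list(resistant_sites = truth$resistant_sites,
                 survival_fraction = survival_fraction),
    results = list(
      n_windows = nrow(filt),
      n_excluded = nrow(excluded_rows(filt)),
      pca_variance = pca$explained_variance,
      bottleneck = consumed_fraction_report(fit),
      filament_threshold_um = thr$threshold),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

sample_resistant <- function(positions, n, seed) {
  withr::with_seed(seed, sample(positions, n))
}
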