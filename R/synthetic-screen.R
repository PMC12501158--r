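#' Ground truth for a simulated predation screen
#'
#' Records the survival regime of a simulated bottleneck: the per-cell
#' survival probability, the set of insertion sites whose mutants are
#' genuinely predation-resistant, and the multiplicative survival
#' advantage those mutants enjoy (capped so no probability exceeds 1).
#'
#' @param survival_fraction per-cell probability of surviving predation,
#'   in (0, 1].
#' @param resistant_sites integer vector of insertion positions carrying
#'   resistance.
#' @param resistance_advantage multiplier (>= 1) on the survival
#'   probability of resistant cells.
#' @param seed integer seed controlling the stochastic screen.
#' @return a `screen_truth` list.
#' @export
screen_truth <- function(survival_fraction, resistant_sites = integer(),
                         resistance_advantage = 1, seed = 1L) {
  check_positive(survival_fraction, "survival_fraction")
  if (survival_fraction > 1) {
    abort("`survival_fraction` must be <= 1.",
          class = "predscreen_invalid_parameter")
  }
  if (resistance_advantage < 1) {
    abort("`resistance_advantage` must be >= 1.",
          class = "predscreen_invalid_parameter")
  }
  structure(list(survival_fraction = survival_fraction,
                 resistant_sites = as.integer(resistant_sites),
                 resistance_advantage = resistance_advantage,
                 seed = as.integer(seed)),
            class = "screen_truth")
}

#' Generate a transposon mutant library over a synthetic genome
#'
#' Draws insertion sites uniformly without replacement from all
#' non-essential genome positions and assigns each mutant lineage a
#' log-normal abundance (heavy-tailed, as in real transposon pools).
#' Abundances are converted to integer read counts summing exactly to
#' `depth` by largest-remainder rounding, so the same table serves as
#' the cell-count input of [simulate_screen()] when `depth` is set to
#' the population size.
#'
#' @param genome a [generate_genome()] result.
#' @param n_sites number of insertion sites (mutant lineages).
#' @param abundance_sigma log-scale SD of lineage abundances; 0 gives a
#'   perfectly even library.
#' @param depth total read (or cell) count the library is scaled to.
#' @param seed integer seed.
#' @return list with `profile`, a tibble (`position`, `count`) sorted by
#'   position, and `abundances`, the latent relative abundances.
#' @export
generate_library <- function(genome, n_sites, abundance_sigma = 1,
                             depth = 1e6, seed = 1L) {
  check_positive(n_sites, "n_sites")
  check_positive(depth, "depth")
  if (abundance_sigma < 0) abort("`abundance_sigma` must be >= 0.",
                                 class = "predscreen_invalid_parameter")
  ess <- filter(genome$features, .data$essential)
  open <- rep(TRUE, genome$length)
  if (nrow(ess) > 0) {
    for (i in seq_len(nrow(ess))) open[ess$start[i]:ess$end[i]] <- FALSE
  }
  avail <- which(open)
  if (n_sites > length(avail)) {
    abort(sprintf(
      "n_sites (%d) exceeds the %d non-essential positions available.",
      n_sites, length(avail)), class = "predscreen_invalid_parameter")
  }
  withr::with_seed(as.integer(seed), {
    pos <- sort(sample(avail, n_sites))
    ab <- rlnorm(n_sites, meanlog = 0, sdlog = abundance_sigma)
    counts <- largest_remainder(ab, depth)
    list(profile = tibble(position = pos, count = counts),
         abundances = tibble(position = pos, abundance = ab))
  })
}

#' Simulate a predation screen over a mutant library
#'
#' Models the predation bottleneck and recovery/sequencing of a pooled
#' screen: each cell of each lineage survives independently with the
#' truth's survival probability (resistant lineages get the capped
#' advantage), surviving cells are drawn binomially per site, and the
#' surviving population is resampled multinomially to `recovery_depth`
#' reads -- recovery growth and sequencing treated as unbiased
#' proportional amplification. Replicates in which no cell survives are
#' kept with all-zero counts and flagged `empty` rather than erroring.
#'
#' @param library an insertion profile tibble (`position`, `count`) in
#'   which counts are interpreted as cell numbers.
#' @param truth a [screen_truth()].
#' @param recovery_depth total sequencing reads per replicate.
#' @param n_replicates number of independent replicate screens.
#' @return tibble with columns `replicate`, `position`, `count`,
#'   `empty`; per non-empty replicate the counts sum to
#'   `recovery_depth`.
#' @export
simulate_screen <- function(library, truth, recovery_depth = 1e6,
                            n_replicates = 3) {
  stopifnot(inherits(truth, "screen_truth"))
  if (nrow(library) == 0) abort("`library` is empty.")
  p <- rep(truth$survival_fraction, nrow(library))
  res <- library$position %in% truth$resistant_sites
  p[res] <- pmin(1, truth$survival_fraction * truth$resistance_advantage)
  withr::with_seed(truth$seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      surv <- rbinom(nrow(library), library$count, p)
      if (sum(surv) == 0) {
        tibble(replicate = r, position = library$position,
               count = 0L, empty = TRUE)
      } else {
        reads <- as.integer(rmultinom(1L, recovery_depth, surv)[, 1L])
        tibble(replicate = r, position = library$position,
               count = reads, empty = FALSE)
      }
    })
  })
}
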