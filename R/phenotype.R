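#' Filament classification threshold by fixed-point iteration
#'
#' A cell is called filamentous when longer than twice the mean
#' single-cell length -- but the mean single-cell length itself depends
#' on which cells are called single. The circularity is resolved by
#' fixed-point iteration: starting from `t0 = 2 * median(lengths)`,
#' repeatedly set `t <- 2 * mean(lengths[lengths <= t])` until the
#' threshold moves by less than `tol`. The mean may instead be supplied
#' directly via `mean_single` (e.g. to reproduce a published value), in
#' which case the threshold is simply `2 * mean_single`.
#'
#' @param lengths numeric vector of pole-to-pole cell lengths (um);
#'   at least 2 cells unless `mean_single` is given.
#' @param mean_single optional known mean single-cell length (um).
#' @param tol convergence tolerance in um (default 1e-6).
#' @param max_iter iteration cap; non-convergence errors with the
#'   iteration trace attached.
#' @return one-row tibble: `mean_single`, `threshold`, `iterations`.
#'   The threshold scales linearly with the data (scale invariance).
#' @export
filament_threshold <- function(lengths = NULL, mean_single = NULL,
                               tol = 1e-6, max_iter = 100L) {
  if (!is.null(mean_single)) {
    check_positive(mean_single, "mean_single")
    return(tibble(mean_single = mean_single,
                  threshold = 2 * mean_single, iterations = 0L))
  }
  if (length(lengths) < 2) abort("need at least 2 cell lengths")
  if (any(lengths <= 0)) abort("cell lengths must be positive")
  t_cur <- 2 * median(lengths)
  trace <- t_cur
  for (i in seq_len(max_iter)) {
    t_new <- 2 * mean(lengths[lengths <= t_cur])
    trace <- c(trace, t_new)
    if (abs(t_new - t_cur) < tol) {
      return(tibble(mean_single = t_new / 2, threshold = t_new,
                    iterations = i))
    }
    t_cur <- t_new
  }
  abort(sprintf(
    "filament threshold did not converge in %d iterations; trace: %s",
    max_iter, paste(signif(trace, 6), collapse = " -> ")),
    class = "predscreen_no_convergence")
}

#' Filamentous volume and count fractions per condition
#'
#' Cell volume is taken proportional to length (constant-width rod
#' model), so the filamentous volume fraction is the summed length of
#' cells above the threshold over the summed length of all cells.
#'
#' @param table cell table with `length_um` and (optionally)
#'   `condition` columns.
#' @param threshold filament threshold in um (> 0), e.g. from
#'   [filament_threshold()].
#' @return tibble per condition: `n_cells`, `percent_count_filamentous`,
#'   `percent_volume_filamentous`.
#' @export
volume_fractions <- function(table, threshold) {
  check_positive(threshold, "threshold")
  stopifnot("length_um" %in% names(table))
  if (!"condition" %in% names(table)) table$condition <- NA_character_
  table |>
    group_by(.data$condition) |>
    summarise(
      n_cells = dplyr::n(),
      percent_count_filamentous =
        100 * mean(.data$length_um > threshold),
      percent_volume_filamentous =
        100 * sum(.data$length_um[.data$length_um > threshold]) /
          sum(.data$length_um),
      .groups = "drop")
}

#' Wilcoxon rank-sum (Mann-Whitney) test with both statistic conventions
#'
#' Wraps the two-sample rank-sum test (exact for small tie-free
#' samples, tie-corrected normal approximation otherwise) and reports
#' both statistic conventions, since published W values differ between
#' software: `U` (the Mann-Whitney statistic of the first group, as
#' returned by R) and `W_ranksum = U + n1 (n1 + 1) / 2` (the sum of
#' ranks of the first group).
#'
#' @param lengths_a,lengths_b the two samples (first group is the one
#'   the statistics refer to).
#' @param alternative passed to [stats::wilcox.test()].
#' @return one-row tibble: `n_a`, `n_b`, `U`, `W_ranksum`, `p_value`,
#'   `method`.
#' @export
ranksum <- function(lengths_a, lengths_b, alternative = "two.sided") {
  if (length(lengths_a) == 0 || length(lengths_b) == 0) {
    abort("both groups must be non-empty")
  }
  ht <- suppressWarnings(
    wilcox.test(lengths_a, lengths_b, alternative = alternative))
  # all-tied groups give a degenerate normal approximation (sd 0)
  if (is.nan(ht$p.value)) ht$p.value <- 1
  n1 <- length(lengths_a)
  tibble(n_a = n1, n_b = length(lengths_b),
         U = unname(ht$statistic),
         W_ranksum = unname(ht$statistic) + n1 * (n1 + 1) / 2,
         p_value = ht$p.value,
         method = ht$method)
}

#' Mutant frequency from two-channel event counts
#'
#' @param record data frame with `mutant_events` and `wildtype_events`
#'   columns (one row per replicate); zero-event totals error, a
#'   zero-count single channel warns and yields frequency 0 or 1.
#' @return the record with a `frequency` column
#'   (`mutant / (mutant + wildtype)`).
#' @export
estimate_frequency <- function(record) {
  stopifnot(all(c("mutant_events", "wildtype_events") %in% names(record)))
  tot <- record$mutant_events + record$wildtype_events
  if (any(tot <= 0)) abort("each replicate needs at least one event")
  if (any(record$mutant_events == 0 | record$wildtype_events == 0)) {
    warn("replicate(s) with an empty channel: frequency is exactly 0 or 1")
  }
  mutate(record, frequency = .data$mutant_events / tot)
}

t_one_sample <- function(x, mu) {
  if (length(x) < 2) abort("tests need >= 2 replicates")
  if (sd(x) == 0) {
    t_val <- if (mean(x) == mu) 0 else sign(mean(x) - mu) * Inf
    return(tibble(estimate = mean(x), mu = mu, t = t_val,
                  df = length(x) - 1, p_value = NA_real_))
  }
  ht <- t.test(x, mu = mu)
  tibble(estimate = unname(ht$estimate), mu = mu,
         t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' One-sample tests on competition frequencies
#'
#' `test_frequency` tests whether end-of-competition mutant frequencies
#' deviate from the starting frequency (`mu`, default 0.1 for a 10
#' percent inoculum); `test_log_ratio` tests the log-transformed
#' frequency relative to the start (`log(freq / initial)`) against 0.
#' Zero variance across replicates reports a missing p-value.
#'
#' @param frequencies numeric vector of per-replicate mutant
#'   frequencies (see [estimate_frequency()]).
#' @param mu,initial null value / starting frequency.
#' @return one-row tibble: `estimate`, `mu`, `t`, `df`, `p_value`.
#' @export
test_frequency <- function(frequencies, mu = 0.1) {
  t_one_sample(frequencies, mu)
}

#' @rdname test_frequency
#' @export
test_log_ratio <- function(frequencies, initial = 0.1) {
  if (any(frequencies <= 0)) {
    abort("log-ratio test requires strictly positive frequencies")
  }
  t_one_sample(log(frequencies / initial), 0)
}

#' Per-locus spontaneous-mutant percentages
#'
#' @param mutation_table data frame with `locus`,
#'   `n_isolates_with_mutation`, `n_total_isolates`.
#' @return the table with a `percent` column, rounded to the nearest
#'   integer.
#' @export
tally_loci <- function(mutation_table) {
  stopifnot(all(c("locus", "n_isolates_with_mutation", "n_total_isolates")
                %in% names(mutation_table)))
  if (any(mutation_table$n_total_isolates <= 0)) {
    abort("`n_total_isolates` must be positive")
  }
  if (any(mutation_table$n_isolates_with_mutation >
          mutation_table$n_total_isolates)) {
    abort("mutated isolates cannot exceed total isolates")
  }
  mutate(mutation_table,
         percent = round(100 * .data$n_isolates_with_mutation /
                           .data$n_total_isolates))
}
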