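#' Bottleneck simulation configuration
#'
#' @param survival_grid candidate survival fractions, each in (0, 1];
#'   default decade steps `10^-(1:5)`, matching the decade-width
#'   brackets the depletion comparison reports.
#' @param population_size number of cells entering predation.
#' @param recovery_depth sequencing reads per simulated sample.
#' @param n_sim simulations per grid point (>= 1).
#' @param seed integer seed.
#' @return a `bottleneck_config` list.
#' @export
bottleneck_config <- function(survival_grid = 10^-(1:5),
                              population_size = 1e6,
                              recovery_depth = 1e6,
                              n_sim = 10, seed = 1L) {
  if (any(survival_grid <= 0 | survival_grid > 1)) {
    abort("`survival_grid` values must be in (0, 1].",
          class = "predscreen_invalid_parameter")
  }
  check_positive(population_size, "population_size")
  check_positive(recovery_depth, "recovery_depth")
  if (n_sim < 1) abort("`n_sim` must be >= 1.",
                       class = "predscreen_invalid_parameter")
  structure(list(survival_grid = sort(unique(survival_grid),
                                      decreasing = TRUE),
                 population_size = population_size,
                 recovery_depth = recovery_depth,
                 n_sim = as.integer(n_sim), seed = as.integer(seed)),
            class = "bottleneck_config")
}

# One bottleneck + recovery pass: binomial survival per lineage,
# multinomial resampling of survivors to sequencing depth.
sim_bottleneck_once <- function(cells, survival, depth) {
  surv <- rbinom(length(cells), cells, survival)
  if (sum(surv) == 0) return(integer(length(cells)))
  as.integer(rmultinom(1L, depth, surv)[, 1L])
}

allocate_cells <- function(input_profile, population_size) {
  if (nrow(input_profile) == 0) abort("`input_profile` is empty")
  if (population_size < nrow(input_profile)) {
    warn(paste("population_size is smaller than the number of rows;",
               "most lineages start with < 1 expected cell"))
  }
  largest_remainder(input_profile$count, population_size)
}

#' Simulate expected read counts under candidate survival fractions
#'
#' Allocates `population_size` cells to lineages proportional to the
#' empirical input counts, applies an independent binomial survival
#' bottleneck at every grid survival value, and resamples survivors
#' multinomially to `recovery_depth` reads (recovery growth and
#' sequencing as unbiased proportional amplification); one simulated
#' sample per (grid value, simulation index).
#'
#' @param input_profile starting-population profile tibble (`position`,
#'   `count`).
#' @param config a [bottleneck_config()].
#' @return long tibble: `survival`, `sim`, `position`, `count`.
#' @export
simulate_expected_counts <- function(input_profile, config) {
  stopifnot(inherits(config, "bottleneck_config"))
  cells <- allocate_cells(input_profile, config$population_size)
  withr::with_seed(config$seed, {
    purrr::map_dfr(config$survival_grid, function(s) {
      purrr::map_dfr(seq_len(config$n_sim), function(i) {
        tibble(survival = s, sim = i, position = input_profile$position,
               count = sim_bottleneck_once(cells, s, config$recovery_depth))
      })
    })
  })
}

depletion_one <- function(out_counts, in_counts) {
  present <- in_counts > 0
  lost <- mean(out_counts[present] == 0)
  both <- present & out_counts > 0
  rc <- NA_real_
  if (sum(both) >= 3) {
    ri <- rank(in_counts[both])
    ro <- rank(out_counts[both])
    if (sd(ri) == 0 && sd(ro) == 0) {
      rc <- 1  # both flat: trivially concordant
    } else if (sd(ri) > 0 && sd(ro) > 0) {
      rc <- cor(ri, ro)
    }
  }
  tibble(fraction_rows_lost = lost, rank_correlation_to_input = rc)
}

#' Mutant depletion statistics relative to the starting population
#'
#' For each sample (or simulated sample) computes the fraction of input
#' rows that dropped to zero counts and the Spearman rank correlation
#' of the surviving rows with the input -- both monotone readouts of
#' bottleneck severity.
#'
#' @param x either a wide `tn_counts` matrix, or a long tibble with a
#'   `count` column plus grouping columns (any of `survival`, `sim`,
#'   `replicate`, `sample`) as produced by [simulate_expected_counts()]
#'   or [simulate_screen()].
#' @param input_profile tibble with `count` (and `position`/`row_id`)
#'   for the starting population; the row universe must match.
#' @return tibble of per-sample summaries with `fraction_rows_lost` and
#'   `rank_correlation_to_input`.
#' @export
depletion_stats <- function(x, input_profile) {
  in_counts <- input_profile$count
  if (inherits(x, "tn_counts")) {
    if (nrow(x) != length(in_counts)) {
      abort("matrix rows and input profile do not match")
    }
    return(purrr::map_dfr(sample_cols(x), function(s) {
      bind_cols(tibble(sample = s), depletion_one(x[[s]], in_counts))
    }))
  }
  by <- intersect(c("survival", "sim", "replicate", "sample"), names(x))
  if (length(by) == 0) {
    if (nrow(x) != length(in_counts)) {
      abort("counts and input profile do not match")
    }
    return(depletion_one(x$count, in_counts))
  }
  x |>
    group_by(across(all_of(by))) |>
    group_modify(function(d, key) {
      if (nrow(d) != length(in_counts)) {
        abort("counts and input profile do not match")
      }
      depletion_one(d$count, in_counts)
    }) |>
    ungroup()
}

#' Bracket the survival fraction from depletion of mutants
#'
#' Compares the observed fraction of lost rows with the simulated
#' depletion distribution at every grid survival value. If the observed
#' value falls inside a grid point's central 50 percent simulated
#' interval, the bracket is that point's flanking grid values;
#' otherwise it is the two adjacent grid survivals whose median losses
#' straddle the observation. Observations outside the simulated range
#' return an open bound at the nearest grid edge, flagged. Non-monotone
#' median depletion across the grid errors (diagnostic of an
#' inadequate configuration).
#'
#' @param observed numeric vector of observed `fraction_rows_lost`
#'   values (e.g. one per replicate) or a [depletion_stats()] tibble;
#'   replicates are averaged.
#' @param simulated per-simulation depletion summaries over the grid
#'   (tibble with `survival` and `fraction_rows_lost`), e.g.
#'   `depletion_stats(simulate_expected_counts(...), input)`.
#' @return a `bottleneck_fit` with elements `survival_lower`,
#'   `survival_upper` (NA when open), `open`, `observed_loss`, and
#'   `grid_summary`. `print()` reports the consumed-cell bracket;
#'   see [consumed_fraction_report()].
#' @export
estimate_survival_range <- function(observed, simulated) {
  if (is.data.frame(observed)) observed <- observed$fraction_rows_lost
  obs <- mean(observed)
  gs <- simulated |>
    group_by(.data$survival) |>
    summarise(q25 = quantile(.data$fraction_rows_lost, 0.25),
              median = median(.data$fraction_rows_lost),
              q75 = quantile(.data$fraction_rows_lost, 0.75),
              .groups = "drop") |>
    arrange(desc(.data$survival))
  if (nrow(gs) < 2) abort("the ensemble must cover at least 2 grid points")
  if (any(diff(gs$median) < -1e-9)) {
    abort(paste("simulated depletion is not monotone across the survival",
                "grid; increase n_sim or widen the grid"),
          class = "predscreen_nonmonotone")
  }
  grid <- gs$survival
  k <- length(grid)
  lower <- upper <- NA_real_
  open <- FALSE
  inside <- which(obs >= gs$q25 & obs <= gs$q75)
  if (length(inside) > 0) {
    i <- inside[which.min(abs(gs$median[inside] - obs))]
    if (i < k) lower <- grid[i + 1L] else open <- TRUE
    if (i > 1L) upper <- grid[i - 1L] else open <- TRUE
    if (i == 1L && is.na(upper)) upper <- NA_real_
  } else if (obs < gs$median[1L]) {
    lower <- grid[1L]
    open <- TRUE
  } else if (obs > gs$median[k]) {
    upper <- grid[k]
    open <- TRUE
  } else {
    i <- max(which(gs$median <= obs))
    lower <- grid[i + 1L]
    upper <- grid[i]
  }
  structure(list(survival_lower = lower, survival_upper = upper,
                 open = open, observed_loss = obs, grid_summary = gs),
            class = "bottleneck_fit")
}

fmt_consumed <- function(s) formatC((1 - s) * 100, format = "fg")

#' Consumed-cell fraction report for a bottleneck fit
#'
#' Formats the survival bracket as the fraction of cells consumed, in
#' decade-bracket style (e.g. survival between 1e-3 and 1e-2 reads
#' "between 99 and 99.9% of cells are consumed").
#'
#' @param fit a [estimate_survival_range()] result.
#' @return character scalar.
#' @export
consumed_fraction_report <- function(fit) {
  lo <- fit$survival_lower
  hi <- fit$survival_upper
  if (is.na(lo) && is.na(hi)) return("consumed fraction indeterminate")
  if (is.na(hi)) {
    sprintf("less than %s%% of cells are consumed (open bracket)",
            fmt_consumed(lo))
  } else if (is.na(lo)) {
    sprintf("more than %s%% of cells are consumed (open bracket)",
            fmt_consumed(hi))
  } else {
    sprintf("between %s and %s%% of cells are consumed",
            fmt_consumed(hi), fmt_consumed(lo))
  }
}

#' @export
print.bottleneck_fit <- function(x, ...) {
  cat("<bottleneck_fit>\n")
  cat(sprintf("  observed fraction of rows lost: %.4f\n", x$observed_loss))
  cat(sprintf("  survival bracket: [%s, %s]%s\n",
              format(x$survival_lower), format(x$survival_upper),
              if (x$open) " (open)" else ""))
  cat(" ", consumed_fraction_report(x), "\n")
  invisible(x)
}

#' Jackpot-event risk under a neutral bottleneck
#'
#' Monte-Carlo probability, for every lineage, that its log2 fold
#' change versus the input (CPM-scaled, with the enrichment module's
#' pseudocount) exceeds a threshold purely through chance survival
#' under a neutral bottleneck -- the false-positive enrichment risk
#' that motivates restricting calls to the top quantile.
#'
#' @param input_profile starting-population profile tibble.
#' @param config a [bottleneck_config()].
#' @param log2fc_threshold finite threshold on log2 fold change.
#' @param pseudocount pseudocount in CPM units (default 1, matching
#'   [compute_log2fc()]).
#' @return tibble `survival`, `position`, `risk` (per-row probability,
#'   averaged over the ensemble).
#' @export
jackpot_risk <- function(input_profile, config, log2fc_threshold,
                         pseudocount = 1) {
  stopifnot(inherits(config, "bottleneck_config"),
            is.finite(log2fc_threshold))
  cells <- allocate_cells(input_profile, config$population_size)
  cpm_in <- input_profile$count / sum(input_profile$count) * 1e6
  withr::with_seed(derive_seed(config$seed, "jackpot"), {
    purrr::map_dfr(config$survival_grid, function(s) {
      exceed <- numeric(nrow(input_profile))
      for (i in seq_len(config$n_sim)) {
        out <- sim_bottleneck_once(cells, s, config$recovery_depth)
        cpm_out <- if (sum(out) > 0) out / sum(out) * 1e6 else out * 0
        lfc <- log2((cpm_out + pseudocount) / (cpm_in + pseudocount))
        exceed <- exceed + (lfc > log2fc_threshold)
      }
      tibble(survival = s, position = input_profile$position,
             risk = exceed / config$n_sim)
    })
  })
}
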