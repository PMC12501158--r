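uniform_profile <- function(n_rows = 1000, cells_per_row = 100) {
  tibble::tibble(position = seq_len(n_rows),
                 count = rep(cells_per_row, n_rows))
}

test_that("depletion statistics behave at the extremes", {
  inp <- uniform_profile(200, 10)
  same <- dplyr::mutate(inp, sample = "s")
  d <- depletion_stats(same, inp)
  expect_equal(d$fraction_rows_lost, 0)
  expect_equal(d$rank_correlation_to_input, 1)

  withr::with_seed(9, {
    lognorm <- tibble::tibble(position = 1:1000,
                              count = round(rlnorm(1000, 5, 1)))
    perm <- tibble::tibble(position = 1:1000,
                           count = sample(lognorm$count), sample = "p")
  })
  dp <- depletion_stats(perm, lognorm)
  expect_lt(abs(dp$rank_correlation_to_input), 0.1)
})

test_that("full survival loses nothing; vanishing survival loses all", {
  inp <- uniform_profile(500, 100)
  cfg1 <- bottleneck_config(survival_grid = 1, population_size = 5e4,
                            recovery_depth = 1e6, n_sim = 3, seed = 1)
  d1 <- depletion_stats(simulate_expected_counts(inp, cfg1), inp)
  expect_true(all(d1$fraction_rows_lost < 0.01))

  cfg0 <- bottleneck_config(survival_grid = 1e-6, population_size = 5e4,
                            recovery_depth = 1e6, n_sim = 3, seed = 1)
  d0 <- depletion_stats(simulate_expected_counts(inp, cfg0), inp)
  expect_true(all(d0$fraction_rows_lost > 0.95))
})

test_that("simulated depletion matches the Poisson-limit closed form", {
  inp <- uniform_profile(10000, 100)
  cfg <- bottleneck_config(survival_grid = 1e-3, population_size = 1e6,
                           recovery_depth = 1e6, n_sim = 20, seed = 42)
  d <- depletion_stats(simulate_expected_counts(inp, cfg), inp)
  expected <- (1 - 1e-3)^100  # ~ exp(-0.1) in the Poisson limit
  mc_se <- sd(d$fraction_rows_lost) / sqrt(nrow(d))
  expect_lt(abs(mean(d$fraction_rows_lost) - expected), 3 * mc_se + 1e-4)
})

test_that("depletion increases monotonically as survival decreases", {
  inp <- uniform_profile(2000, 100)
  cfg <- bottleneck_config(survival_grid = 10^-(1:4),
                           population_size = 2e5, recovery_depth = 2e5,
                           n_sim = 8, seed = 5)
  d <- depletion_stats(simulate_expected_counts(inp, cfg), inp)
  med <- d |>
    dplyr::group_by(survival) |>
    dplyr::summarise(m = median(fraction_rows_lost)) |>
    dplyr::arrange(dplyr::desc(survival))
  expect_true(all(diff(med$m) > 0))
})

test_that("the survival bracket recovers a mid-grid truth", {
  g <- generate_genome(150, repeat_gene_fraction = 0, seed = 31)
  lib <- generate_library(g, 4000, abundance_sigma = 1, depth = 5e5,
                          seed = 31)
  truth <- screen_truth(1e-3, seed = 32)
  obs <- depletion_stats(
    simulate_screen(lib$profile, truth, 5e5, 3), lib$profile)
  cfg <- bottleneck_config(population_size = 5e5, recovery_depth = 5e5,
                           n_sim = 10, seed = 33)
  sims <- depletion_stats(simulate_expected_counts(lib$profile, cfg),
                          lib$profile)
  fit <- estimate_survival_range(obs, sims)
  expect_s3_class(fit, "bottleneck_fit")
  expect_true(fit$survival_lower <= 1e-3)
  expect_true(fit$survival_upper >= 1e-3)
})

test_that("out-of-grid observations return open brackets", {
  sims <- tidyr::expand_grid(survival = 10^-(1:3), sim = 1:8) |>
    dplyr::mutate(fraction_rows_lost =
                    0.2 + 0.3 * (-log10(survival) - 1) + 0.001 * sim)
  fit_low <- estimate_survival_range(0, sims)
  expect_true(fit_low$open)
  expect_equal(fit_low$survival_lower, 1e-1)
  fit_high <- estimate_survival_range(1, sims)
  expect_true(fit_high$open)
  expect_equal(fit_high$survival_upper, 1e-3)
})

test_that("non-monotone simulated depletion is rejected", {
  bad <- tibble::tibble(survival = rep(10^-(1:3), each = 4),
                        fraction_rows_lost = rep(c(0.9, 0.2, 0.5), each = 4))
  expect_error(estimate_survival_range(0.4, bad),
               class = "predscreen_nonmonotone")
})

test_that("consumed-fraction reports use decade-bracket phrasing", {
  fit <- structure(list(survival_lower = 1e-3, survival_upper = 1e-2,
                        open = FALSE, observed_loss = 0.8,
                        grid_summary = NULL),
                   class = "bottleneck_fit")
  expect_equal(consumed_fraction_report(fit),
               "between 99 and 99.9% of cells are consumed")
  td <- tidy(fit)
  expect_equal(td$consumed_lower_pct, 99)
  expect_equal(td$consumed_upper_pct, 99.9)
})

test_that("jackpot risk is monotone in threshold and in bottleneck severity", {
  inp <- uniform_profile(1000, 100)
  cfg <- bottleneck_config(survival_grid = c(1e-1, 1e-3),
                           population_size = 1e5, recovery_depth = 1e5,
                           n_sim = 10, seed = 7)
  r1 <- jackpot_risk(inp, cfg, log2fc_threshold = 1)
  r2 <- jackpot_risk(inp, cfg, log2fc_threshold = 2)
  expect_true(all(r2$risk <= r1$risk))

  mean_by_s <- r1 |>
    dplyr::group_by(survival) |>
    dplyr::summarise(m = mean(risk))
  expect_gt(mean_by_s$m[mean_by_s$survival == 1e-3],
            mean_by_s$m[mean_by_s$survival == 1e-1])

  cfg_deep <- bottleneck_config(survival_grid = 1, population_size = 1e5,
                                recovery_depth = 1e6, n_sim = 5, seed = 8)
  r0 <- jackpot_risk(inp, cfg_deep, log2fc_threshold = 0.5)
  expect_lt(mean(r0$risk), 0.01)
})

test_that("neutral screens exceed a log2FC cutoff at the jackpot rate", {
  inp <- uniform_profile(2000, 100)
  cfg <- bottleneck_config(survival_grid = 1e-2, population_size = 2e5,
                           recovery_depth = 2e5, n_sim = 30, seed = 9)
  risk <- jackpot_risk(inp, cfg, log2fc_threshold = 1)
  truth <- screen_truth(1e-2, resistance_advantage = 1, seed = 10)
  scr <- simulate_screen(inp, truth, 2e5, n_replicates = 30)
  cpm_in <- inp$count / sum(inp$count) * 1e6
  exceed <- scr |>
    dplyr::group_by(replicate) |>
    dplyr::summarise(f = mean(log2((count / sum(count) * 1e6 + 1) /
                                     (cpm_in + 1)) > 1))
  expect_lt(abs(mean(exceed$f) - mean(risk$risk)), 0.05)
})
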