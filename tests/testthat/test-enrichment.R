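norm_matrix <- function(df) as_count_matrix(df, normalized = TRUE)

test_that("log2 fold change follows the pseudocount formula", {
  m <- norm_matrix(tibble::tibble(row_id = c("a", "b"),
                                  c1 = c(2, 5), c2 = c(2, 5),
                                  p1 = c(8, 5), p2 = c(8, 5)))
  e <- compute_log2fc(m, c("p1", "p2"), c("c1", "c2"), pseudocount = 0)
  expect_equal(e$log2fc, c(2, 0))
  expect_equal(e$mean_predation, c(8, 5))
  expect_equal(e$sd_pred, c(0, 0))
  expect_equal(e$rank, c(1L, 2L))
})

test_that("swapping groups negates the fold change", {
  withr::with_seed(8, {
    m <- norm_matrix(tibble::tibble(
      row_id = sprintf("r%02d", 1:50),
      c1 = runif(50, 0, 100), c2 = runif(50, 0, 100),
      p1 = runif(50, 0, 100), p2 = runif(50, 0, 100)))
  })
  fwd <- compute_log2fc(m, c("p1", "p2"), c("c1", "c2"), 1)
  rev <- compute_log2fc(m, c("c1", "c2"), c("p1", "p2"), 1)
  expect_equal(fwd$log2fc, -rev$log2fc)
})

test_that("fold changes demand a normalized matrix and valid groups", {
  raw <- as_count_matrix(tibble::tibble(row_id = "a", x = 1, y = 2))
  expect_error(compute_log2fc(raw, "x", "y"), "normalized")
  m <- norm_matrix(tibble::tibble(row_id = "a", x = 1, y = 2))
  expect_error(compute_log2fc(m, character(0), "y"), "non-empty")
  expect_error(compute_log2fc(m, "nope", "y"), "unknown")
})

test_that("top-quantile selection flags exactly ceil(q*n) rows", {
  tb <- tibble::tibble(row_id = sprintf("r%03d", 1:300),
                       log2fc = rev(seq_len(300)) / 10,
                       rank = seq_len(300))
  expect_equal(sum(select_top(tb, 0.01)$top_flag), 3L)
  expect_equal(sum(select_top(tb, 1)$top_flag), 300L)
  expect_true(all(select_top(tb, 0.01)$top_flag[1:3]))
  expect_error(select_top(tb, 0), class = "predscreen_invalid_parameter")
  expect_error(select_top(tb, 1.5), class = "predscreen_invalid_parameter")
})

test_that("ranks are invariant under global scaling (pseudocount 0)", {
  withr::with_seed(12, {
    vals <- matrix(runif(200, 1, 100), ncol = 4)
  })
  m1 <- norm_matrix(tibble::tibble(row_id = sprintf("r%02d", 1:50),
                                   c1 = vals[, 1], c2 = vals[, 2],
                                   p1 = vals[, 3], p2 = vals[, 4]))
  m2 <- norm_matrix(tibble::tibble(row_id = sprintf("r%02d", 1:50),
                                   c1 = 7 * vals[, 1], c2 = 7 * vals[, 2],
                                   p1 = 7 * vals[, 3], p2 = 7 * vals[, 4]))
  r1 <- compute_log2fc(m1, c("p1", "p2"), c("c1", "c2"), 0)$rank
  r2 <- compute_log2fc(m2, c("p1", "p2"), c("c1", "c2"), 0)$rank
  expect_equal(r1, r2)
})

test_that("replicate summaries aggregate mean and SD correctly", {
  m <- as_count_matrix(tibble::tibble(row_id = "r", a = 1, b = 2, c = 3,
                                      solo = 9))
  s <- summarize_replicates(m, list(grp = c("a", "b", "c"),
                                    single = "solo"))
  expect_equal(s$mean, c(2, 9))
  expect_equal(s$sd, c(1, NA_real_))
  withr::with_seed(2, x <- matrix(rnorm(30), nrow = 3))
  m2 <- as_count_matrix(tibble::tibble(row_id = c("a", "b", "c"),
                                       s1 = abs(x[, 1]), s2 = abs(x[, 2]),
                                       s3 = abs(x[, 3])))
  s2 <- summarize_replicates(m2, list(g = c("s1", "s2", "s3")))
  expect_equal(s2$sd, apply(cbind(m2$s1, m2$s2, m2$s3), 1, sd))
})

test_that("PCA puts identical samples at the origin and is duplication-stable", {
  m <- norm_matrix(tibble::tibble(row_id = sprintf("r%02d", 1:20),
                                  s1 = 1:20, s2 = 1:20))
  p <- run_pca(m, log_transform = FALSE)
  expect_equal(unname(unlist(p$scores[, -1])), rep(0, 4), tolerance = 1e-10)

  withr::with_seed(4, {
    vals <- matrix(rpois(80, 50), ncol = 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  })
  base <- tibble::tibble(row_id = sprintf("r%02d", 1:20),
                         as.data.frame(vals))
  dup <- dplyr::bind_cols(base,
                          setNames(as.data.frame(vals), paste0("t", 1:4)))
  ev1 <- run_pca(norm_matrix(base))$explained_variance
  ev2 <- run_pca(norm_matrix(dup))$explained_variance
  expect_equal(ev1, ev2, tolerance = 1e-8)
  expect_true(all(diff(ev1) <= 1e-12))
  expect_lte(sum(ev1), 1 + 1e-12)
  expect_error(run_pca(norm_matrix(base), n_components = 9), "fewer samples")
})

test_that("PCA separates screens selected on orthogonal resistant sets", {
  g <- generate_genome(200, repeat_gene_fraction = 0, seed = 21)
  lib <- generate_library(g, 4000, abundance_sigma = 1, depth = 5e5,
                          seed = 21)
  sites <- withr::with_seed(22, sample(lib$profile$position, 200))
  truth_np <- screen_truth(1e-2, sites[1:100], 50, seed = 23)
  truth_nr <- screen_truth(1e-2, sites[101:200], 50, seed = 24)
  np <- simulate_screen(lib$profile, truth_np, 5e5, 3)
  nr <- simulate_screen(lib$profile, truth_nr, 5e5, 3)
  cols <- c(
    setNames(lapply(1:3, function(r) {
      dplyr::filter(np, replicate == r)[c("position", "count")]
    }), paste0("NP", 1:3)),
    setNames(lapply(1:3, function(r) {
      dplyr::filter(nr, replicate == r)[c("position", "count")]
    }), paste0("NR", 1:3)))
  tb <- tibble::tibble(row_id = as.character(lib$profile$position))
  for (s in names(cols)) tb[[s]] <- cols[[s]]$count
  p <- run_pca(normalize_counts(as_count_matrix(tb)))
  sc <- as.matrix(p$scores[, c("PC1", "PC2")])
  centroid_np <- colMeans(sc[1:3, ])
  centroid_nr <- colMeans(sc[4:6, ])
  between <- sqrt(sum((centroid_np - centroid_nr)^2))
  within <- mean(c(
    sqrt(rowSums((sc[1:3, ] - rep(centroid_np, each = 3))^2)),
    sqrt(rowSums((sc[4:6, ] - rep(centroid_nr, each = 3))^2))))
  expect_gt(between, within)
})
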