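test_that("repeat scanning finds exactly the maximal runs", {
  r <- scan_repeats(paste0("ATG", strrep("A", 8), "TAA"), 8)
  expect_equal(nrow(r), 1L)
  expect_equal(r$base, "A")
  expect_equal(r$start_in_cds, 4L)
  expect_equal(r$run_length, 8L)

  expect_equal(nrow(scan_repeats(paste0("CG", strrep("A", 7), "CG"), 8)), 0L)

  two <- scan_repeats(paste0(strrep("G", 9), "AC", strrep("T", 10)), 8)
  expect_equal(two$base, c("G", "T"))
  expect_equal(two$start_in_cds, c(1L, 12L))
  expect_equal(two$run_length, c(9L, 10L))

  expect_error(scan_repeats("ACGTN"), "position",
               class = "predscreen_invalid_sequence")
  expect_equal(nrow(scan_repeats(strrep("A", 20), 8, base = "C")), 0L)
})

test_that("scan_repeats agrees with a brute-force scanner on random input", {
  withr::with_seed(101, {
    for (i in 1:1000) {
      s <- random_runny_seq(sample(30:150, 1), bias = runif(1, 0.3, 0.8))
      got <- as.data.frame(scan_repeats(s, 8))
      want <- brute_scan_runs(s, 8)
      expect_equal(got, want, ignore_attr = TRUE)
    }
  })
})

ref_with_run <- function() {
  # ATG + filler + A9 run + CTA ACT + filler + TAA; run placed so a -1
  # slip stops at ~40% of the protein.
  filler1 <- "GGCATTGACCTGTTCGAGCATGTC"  # non-repetitive, in-frame, no stop
  filler2 <- strrep("CGT", 20)
  paste0("ATG", filler1, strrep("A", 9), "CTAACT", filler2, "TAA")
}

test_that("ortholog comparison calls deltas, frames, and stops", {
  ref <- ref_with_run()
  run <- scan_repeats(ref, 8)[1, ]
  expect_equal(run$run_length, 9L)

  same <- compare_ortholog(ref, run, ref)
  expect_true(same$alignable)
  expect_equal(same$length_delta, 0L)
  expect_false(same$frameshifted)
  expect_false(same$inactivating)
  expect_equal(same$stop_position_fraction, 1)

  # -1 slip: frameshift with immediate premature stop
  del <- paste0(substr(ref, 1, run$start_in_cds - 1),
                substr(ref, run$start_in_cds + 1, nchar(ref)))
  call_del <- compare_ortholog(del, run, ref)
  expect_equal(call_del$length_delta, -1L)
  expect_true(call_del$frameshifted)
  expect_true(call_del$premature_stop)
  expect_true(call_del$inactivating)
  # independent check by direct codon reading of the mutated sequence
  starts <- seq(1, nchar(del) - 2, 3)
  cods <- substring(del, starts, starts + 2)
  direct_stop <- which(cods %in% c("TAA", "TAG", "TGA"))[1]
  expect_equal(call_del$stop_position_fraction,
               direct_stop / (nchar(ref) %/% 3))
  expect_lt(call_del$stop_position_fraction, 0.5)

  # +3 in-frame insertion: never inactivating, whatever lies downstream
  ins3 <- paste0(substr(ref, 1, run$start_in_cds - 1), "AAA",
                 substr(ref, run$start_in_cds, nchar(ref)))
  call_ins <- compare_ortholog(ins3, run, ref)
  expect_equal(call_ins$length_delta, 3L)
  expect_false(call_ins$frameshifted)
  expect_false(call_ins$inactivating)
})

test_that("broken or ambiguous anchors yield unalignable calls", {
  ref <- ref_with_run()
  run <- scan_repeats(ref, 8)[1, ]
  # corrupt one base of the left anchor
  orth <- ref
  substr(orth, run$start_in_cds - 5, run$start_in_cds - 5) <- "T"
  expect_false(compare_ortholog(orth, run, ref)$alignable)
  # duplicated right anchor -> ambiguous
  right <- substr(ref, run$start_in_cds + 9, run$start_in_cds + 20)
  dup <- paste0(ref, right)
  expect_false(compare_ortholog(dup, run, ref)$alignable)
})

test_that("per-gene inactivated fractions match hand-built groups", {
  ref <- ref_with_run()
  run <- scan_repeats(ref, 8)[1, ]
  del <- paste0(substr(ref, 1, run$start_in_cds - 1),
                substr(ref, run$start_in_cds + 1, nchar(ref)))
  orth <- tibble::tibble(
    locus_tag = "slrC_like",
    strain_id = sprintf("s%02d", 1:39),
    cds = c(rep(ref, 38), del))
  fr <- gene_frameshift_fraction(orth, c(slrC_like = ref))
  expect_equal(fr$n_orthologs, 39L)
  expect_equal(fr$n_inactivating, 1L)
  expect_equal(round(100 * fr$fraction, 1), 2.6)

  none <- gene_frameshift_fraction(
    dplyr::mutate(orth, cds = ref), c(slrC_like = ref))
  expect_equal(none$fraction, 0)

  # genes without a qualifying run are excluded from the output
  norun <- paste0("ATG", strrep("CGT", 30), "TAA")
  out <- gene_frameshift_fraction(
    tibble::tibble(locus_tag = "flat", strain_id = "s1", cds = norun),
    c(flat = norun))
  expect_equal(nrow(out), 0L)
})

test_that("planted pangenome frameshift fractions are recovered exactly", {
  g <- generate_genome(25, repeat_gene_fraction = 0.6, seed = 41)
  pan <- generate_pangenome(g, n_strains = 30, frameshift_rate = 0.2,
                            substitution_rate = 0, seed = 42)
  got <- gene_frameshift_fraction(pan$orthologs, cds_seq(g))
  truth_by_gene <- pan$truth |>
    dplyr::group_by(locus_tag) |>
    dplyr::summarise(n_inact = sum(inactivating),
                     n_fs = sum(frameshifted))
  expect_equal(got$n_unalignable, rep(0L, nrow(got)))
  for (i in seq_len(nrow(got))) {
    tr <- truth_by_gene[truth_by_gene$locus_tag == got$locus_tag[i], ]
    n_inact <- if (nrow(tr) == 0) 0L else tr$n_inact
    n_fs <- if (nrow(tr) == 0) 0L else tr$n_fs
    expect_equal(got$n_inactivating[i], n_inact)
    expect_equal(got$n_frameshifted[i], n_fs)
    expect_equal(got$fraction[i], n_inact / got$n_orthologs[i])
  }
})

test_that("zero frameshift rate plants nothing; substitutions cause no false calls", {
  g <- generate_genome(20, repeat_gene_fraction = 0.5, seed = 43)
  pan0 <- generate_pangenome(g, 10, frameshift_rate = 0, seed = 44)
  expect_equal(nrow(pan0$truth), 0L)
  got0 <- gene_frameshift_fraction(pan0$orthologs, cds_seq(g))
  expect_true(all(got0$n_frameshifted == 0))

  pan_sub <- generate_pangenome(g, 15, frameshift_rate = 0,
                                substitution_rate = 0.01, seed = 45)
  got <- gene_frameshift_fraction(pan_sub$orthologs, cds_seq(g))
  expect_true(all(got$n_inactivating == 0))
  expect_true(all(got$n_frameshifted == 0))
})

test_that("planted fraction approaches the configured rate at scale", {
  g <- generate_genome(6, repeat_gene_fraction = 1, seed = 46)
  pan <- generate_pangenome(g, n_strains = 400, frameshift_rate = 0.155,
                            seed = 47)
  per_gene <- pan$truth |>
    dplyr::count(locus_tag) |>
    dplyr::mutate(frac = n / 400)
  expect_lt(max(abs(per_gene$frac - 0.155)), 0.06)
})

test_that("genes are ranked by fraction with deterministic tie-breaks", {
  tb <- tibble::tibble(locus_tag = c("b", "a", "c", "d"),
                       fraction = c(0.1, 0.1, 0.5, 0))
  r <- rank_by_fraction(tb, top_quantile = 0.25)
  expect_equal(r$locus_tag, c("c", "a", "b", "d"))
  expect_equal(r$top_flag, c(TRUE, FALSE, FALSE, FALSE))

  zeros <- tibble::tibble(locus_tag = letters[1:10], fraction = 0)
  rz <- rank_by_fraction(zeros, 0.2)
  expect_equal(rz$locus_tag[rz$top_flag], c("a", "b"))

  # a swrA-like gene at 15.5% outranks background genes at <= 2%
  mix <- tibble::tibble(locus_tag = c(sprintf("bg%02d", 1:19), "swrA_like"),
                        fraction = c(runif(19, 0, 0.02), 0.155))
  expect_equal(rank_by_fraction(mix, 0.05)$locus_tag[1], "swrA_like")
})
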