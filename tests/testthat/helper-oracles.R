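# Independent oracles used across tests.

# Position-by-position run scanner (deliberately not rle-based).
brute_scan_runs <- function(seq, min_run = 8L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && chars[j + 1L] == chars[i]) j <- j + 1L
    if (j - i + 1L >= min_run) {
      out[[length(out) + 1L]] <- data.frame(
        base = chars[i], start_in_cds = i, run_length = j - i + 1L,
        stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  if (length(out) == 0L) {
    data.frame(base = character(0), start_in_cds = integer(0),
               run_length = integer(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

# Exhaustive permutation distribution of the Mann-Whitney U of group a.
exact_ranksum <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2L, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(U = u_obs,
       p_less = p_le,
       p_greater = p_ge,
       p_two_sided = min(1, 2 * min(p_le, p_ge)))
}

# Random A/C/G/T sequence biased toward homopolymer runs.
random_runny_seq <- function(len, bias = 0.5) {
  chars <- character(len)
  chars[1] <- sample(c("A", "C", "G", "T"), 1L)
  for (i in 2:len) {
    chars[i] <- if (stats::runif(1) < bias) {
      chars[i - 1L]
    } else {
      sample(c("A", "C", "G", "T"), 1L)
    }
  }
  paste(chars, collapse = "")
}

# Site-level count matrix: input library plus screen replicates.
screen_site_matrix <- function(lib_profile, screens) {
  out <- tibble::tibble(row_id = as.character(lib_profile$position),
                        input = lib_profile$count)
  for (r in unique(screens$replicate)) {
    out[[paste0("rep", r)]] <-
      screens$count[screens$replicate == r]
  }
  as_count_matrix(out)
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".wig")
  writeLines(lines, f)
  f
}
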