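#' @importFrom rlang abort warn `%||%`
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats rbinom rmultinom rlnorm rnorm runif median sd quantile
#'   prcomp cor t.test wilcox.test setNames
NULL

# Allocate `total` integer units across weights, preserving proportions
# exactly in expectation and the total exactly (largest-remainder rounding).
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0)
  n <- length(weights)
  if (n == 0L || total == 0 || sum(weights) == 0) {
    return(integer(n))
  }
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  short <- as.integer(round(total - sum(base)))
  if (short > 0L) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Deterministic per-stage seed derived from a global seed; stays < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 10000L
  as.integer((as.numeric(seed) * 10007 + h) %% .Machine$integer.max)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number, got %s.",
                  name, paste(format(x), collapse = ",")),
          class = "predscreen_invalid_parameter")
  }
  invisible(x)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a proportion in [0, 1].", name),
          class = "predscreen_invalid_parameter")
  }
  invisible(x)
}

random_bases <- function(n) {
  if (n <= 0) return(character(0))
  sample(BASES, n, replace = TRUE)
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(seq, "", fixed = TRUE),
                function(ch) paste(rev(ch), collapse = ""), character(1)))
}

# Split a CDS string into codons (drops a trailing partial codon).
codons_of <- function(seq) {
  len <- nchar(seq)
  n_cod <- len %/% 3L
  if (n_cod == 0L) return(character(0))
  starts <- seq(1L, by = 3L, length.out = n_cod)
  substring(seq, starts, starts + 2L)
}

# Index (in codons, 1-based) of the first in-frame stop codon, NA if none.
first_stop_index <- function(seq) {
  cods <- codons_of(seq)
  hit <- which(cods %in% STOP_CODONS)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}
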