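#' Read a wiggle (wig) insertion-count track
#'
#' Parses a single-chromosome wig file in `fixedStep` or `variableStep`
#' format (1-based coordinates) into an insertion profile. `track`
#' header lines and comments are ignored. Malformed headers, negative
#' values, non-numeric data, and positions outside a `fixedStep` block
#' raise an error naming the offending line.
#'
#' @param path path to a wig file.
#' @return tibble with integer columns `position` and `count`, sorted by
#'   position; the chromosome name is attached as attribute `chrom`. An
#'   empty track yields a zero-row tibble.
#' @export
read_wig <- function(path) {
  lines <- readLines(path)
  parse_error <- function(i, msg) {
    abort(sprintf("wig parse error at line %d: %s", i, msg),
          class = "predscreen_parse_error")
  }
  kv <- function(fields, key, i, required = TRUE) {
    hit <- grep(paste0("^", key, "="), fields, value = TRUE)
    if (length(hit) == 0L) {
      if (required) parse_error(i, sprintf("missing %s= in step header", key))
      return(NA_character_)
    }
    sub(paste0("^", key, "="), "", hit[1L])
  }
  mode <- NULL
  chrom <- NA_character_
  fixed_pos <- NA_integer_
  fixed_step <- NA_integer_
  pos <- integer(0)
  val <- numeric(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#") || startsWith(line, "track")) next
    fields <- strsplit(line, "[ \t]+")[[1]]
    if (fields[1L] %in% c("variableStep", "fixedStep")) {
      mode <- fields[1L]
      ch <- kv(fields, "chrom", i)
      if (!is.na(chrom) && ch != chrom) {
        parse_error(i, "multiple chromosomes in one track are not supported")
      }
      chrom <- ch
      if (mode == "fixedStep") {
        fixed_pos <- suppressWarnings(as.integer(kv(fields, "start", i)))
        fixed_step <- suppressWarnings(
          as.integer(kv(fields, "step", i, required = FALSE)))
        if (is.na(fixed_step)) fixed_step <- 1L
        if (is.na(fixed_pos) || fixed_pos < 1L) {
          parse_error(i, "fixedStep start must be a positive integer")
        }
      }
      next
    }
    if (is.null(mode)) parse_error(i, "data before any step header")
    if (mode == "variableStep") {
      if (length(fields) != 2L) {
        parse_error(i, "variableStep data need 2 fields (position value)")
      }
      p <- suppressWarnings(as.integer(fields[1L]))
      v <- suppressWarnings(as.numeric(fields[2L]))
      if (is.na(p) || p < 1L) parse_error(i, "invalid position")
      if (is.na(v)) parse_error(i, "non-numeric value")
      if (v < 0) parse_error(i, "negative count")
      pos <- c(pos, p)
      val <- c(val, v)
    } else {
      v <- suppressWarnings(as.numeric(fields[1L]))
      if (is.na(v)) parse_error(i, "non-numeric value")
      if (v < 0) parse_error(i, "negative count")
      pos <- c(pos, fixed_pos)
      val <- c(val, v)
      fixed_pos <- fixed_pos + fixed_step
    }
  }
  ord <- order(pos)
  out <- tibble(position = pos[ord], count = val[ord])
  attr(out, "chrom") <- chrom
  out
}

#' Write an insertion profile as a variableStep wig track
#'
#' @param profile tibble with `position` and `count` columns.
#' @param path output path.
#' @param chrom chromosome name written in the step header.
#' @return `path`, invisibly. `read_wig(write_wig(p))` round-trips
#'   exactly for integer counts.
#' @export
write_wig <- function(profile, path, chrom = "chr") {
  stopifnot(all(c("position", "count") %in% names(profile)))
  chrom <- attr(profile, "chrom") %||% chrom
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("variableStep chrom=%s", chrom), con)
  if (nrow(profile) > 0) {
    ord <- order(profile$position)
    writeLines(paste(profile$position[ord],
                     format(profile$count[ord], scientific = FALSE,
                            trim = TRUE)), con)
  }
  invisible(path)
}
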