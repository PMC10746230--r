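# Low-level sequence helpers shared across modules. Sequences are plain
# character scalars; coordinates are 0-based half-open internally and only
# converted to 1-based at the GFF3 boundary.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (case-insensitive; `N` and IUPAC ambiguity letters
#'   are complemented to `N`).
#' @return Upper-case reverse complement.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("ACGTUNRYSWKMBDHV", "TGCAANNNNNNNNNNN", str_to_upper(seq))
  intToUtf8(rev(utf8ToInt(x)))
}

# Split a sequence into a character vector of single bases (upper-cased).
seq_chars <- function(seq) {
  strsplit(str_to_upper(seq), "", fixed = TRUE)[[1L]]
}

# Validate a DNA string; `strict` rejects anything outside ACGT and names
# the first offending 1-based position. U is always rejected (DNA pipeline).
check_dna <- function(seq, strict = TRUE, what = "sequence") {
  ch <- seq_chars(seq)
  if (strict) {
    bad <- which(!ch %in% DNA_BASES)
    if (length(bad) > 0L) {
      abort(sprintf(
        "ambiguous or non-DNA base '%s' in %s at position %d",
        ch[bad[1L]], what, bad[1L]
      ), class = "phagecode_ambiguous_base")
    }
  } else if (any(ch == "U")) {
    abort(sprintf("RNA base 'U' in %s; this is a DNA-only pipeline", what),
          class = "phagecode_ambiguous_base")
  }
  invisible(ch)
}

# Length of the union of 0-based half-open intervals, via IRanges.
interval_union_width <- function(start0, end0) {
  keep <- end0 > start0
  start0 <- start0[keep]
  end0 <- end0[keep]
  if (length(start0) == 0L) return(0L)
  ir <- IRanges::IRanges(start = start0 + 1L, end = end0)
  sum(IRanges::width(IRanges::reduce(ir)))
}

# Half-up rounding (R's round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Validate a tibble of sequences: columns seq_id (unique) and seq.
check_seq_tbl <- function(x, arg = "seqs") {
  if (!is.data.frame(x) || !all(c("seq_id", "seq") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns seq_id and seq", arg))
  }
  if (anyDuplicated(x$seq_id)) {
    abort(sprintf("duplicated seq_id in `%s`", arg))
  }
  as_tibble(x)
}

# Draw a random DNA string of length n from the current RNG stream.
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
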