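#' Genetic code tables
#'
#' Builds a genetic-code object for NCBI translation tables 11 (standard
#' bacterial), 25 (Candidate Division SR1 / Gracilibacteria: TGA encodes
#' glycine) or 4 (TGA encodes tryptophan). Codon tables come from
#' [Biostrings::getGeneticCode()]; this wrapper fixes the DNA alphabet,
#' exposes the stop-codon set explicitly, and is the single source of
#' translation rules for the ORF caller and the density profiler.
#'
#' @param code_id Integer: 11, 25 or 4.
#' @return An object of class `genetic_code`: a list with `code_id`,
#'   `table` (named character vector over the 64 DNA codons, stops as `"*"`),
#'   `stops` (character vector of stop codons) and `starts`
#'   (ATG/GTG/TTG, the prokaryotic start set used by [find_orfs()]).
#' @export
#' @examples
#' genetic_code(25)$stops     # TAA, TAG -- TGA is glycine
#' genetic_code(11)$table[["TGA"]]
genetic_code <- function(code_id) {
  if (!code_id %in% c(11L, 25L, 4L)) {
    abort("code_id must be one of 11, 25, 4", class = "phagecode_bad_code")
  }
  tab <- Biostrings::getGeneticCode(as.character(code_id))
  tab <- tab[order(names(tab))]
  structure(
    list(
      code_id = as.integer(code_id),
      table = tab,
      stops = sort(names(tab)[tab == "*"]),
      starts = c("ATG", "GTG", "TTG")
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code %d> stops: %s; TGA -> %s\n",
              x$code_id, paste(x$stops, collapse = ","),
              x$table[["TGA"]]))
  invisible(x)
}

as_genetic_code <- function(code) {
  if (inherits(code, "genetic_code")) code else genetic_code(code)
}

#' Translate a DNA string
#'
#' @param seq DNA string, length divisible by 3, bases A/C/G/T only
#'   (case-insensitive).
#' @param code A `genetic_code` object or a code id (11, 25, 4).
#' @param stop_policy `"mark"` emits stop codons as `*`; `"truncate"` ends
#'   the translation before the first stop codon.
#' @return Amino-acid string (one letter per codon under `"mark"`).
#' @export
#' @examples
#' translate_dna("ATGTGATAA", 25, "mark")   # "MG*"
#' translate_dna("ATGTGATAA", 11, "mark")   # "M**"
translate_dna <- function(seq, code, stop_policy = c("mark", "truncate")) {
  stop_policy <- match.arg(stop_policy)
  code <- as_genetic_code(code)
  ch <- check_dna(seq, strict = TRUE)
  n <- length(ch)
  if (n %% 3L != 0L) {
    abort(sprintf("sequence length %d is not divisible by 3", n),
          class = "phagecode_frame_error")
  }
  if (n == 0L) return("")
  codons <- paste0(ch[seq(1L, n, 3L)], ch[seq(2L, n, 3L)], ch[seq(3L, n, 3L)])
  aa <- unname(code$table[codons])
  if (stop_policy == "truncate") {
    first_stop <- which(aa == "*")
    if (length(first_stop) > 0L) aa <- aa[seq_len(first_stop[1L] - 1L)]
  }
  paste(aa, collapse = "")
}

# Codon start positions (0-based, forward coordinates) and codon strings for
# one frame/strand scan. For strand "-" the scan reads the reverse complement
# in frame `frame`; positions refer to the leftmost forward-strand base of
# each codon. Codons containing non-ACGT characters are returned verbatim
# (callers treat them as neither start nor stop).
frame_codons <- function(ch, frame, strand) {
  n <- length(ch)
  if (strand == "-") ch <- seq_chars(revcomp(paste(ch, collapse = "")))
  if (frame + 3L > n) return(list(pos0 = integer(0), codon = character(0)))
  starts1 <- seq.int(frame + 1L, n - 2L, by = 3L)
  codon <- paste0(ch[starts1], ch[starts1 + 1L], ch[starts1 + 2L])
  pos0 <- if (strand == "+") starts1 - 1L else n - (starts1 - 1L) - 3L
  list(pos0 = pos0, codon = codon)
}

#' Stop-codon positions in one frame
#'
#' Scans one frame of one strand and returns the 0-based codon start
#' positions (forward coordinate system, regardless of strand) of every stop
#' codon under the given code, in increasing order.
#'
#' @param seq DNA string (A/C/G/T, case-insensitive).
#' @param code A `genetic_code` object or code id.
#' @param frame 0, 1 or 2; for strand `"-"` the frame is counted on the
#'   reverse complement.
#' @param strand `"+"` or `"-"`.
#' @return Integer vector of 0-based positions, strictly increasing.
#' @export
#' @examples
#' stop_positions("AAATAAAAA", 11, frame = 0, strand = "+")  # 3
stop_positions <- function(seq, code, frame = 0L, strand = c("+", "-")) {
  strand <- match.arg(strand)
  code <- as_genetic_code(code)
  if (!frame %in% 0:2) abort("frame must be 0, 1 or 2")
  ch <- check_dna(seq, strict = TRUE)
  fc <- frame_codons(ch, as.integer(frame), strand)
  sort(fc$pos0[fc$codon %in% code$stops])
}
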