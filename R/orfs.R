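#' Six-frame ORF calling under a chosen genetic code
#'
#' Deterministic maximal-ORF caller: in each of the six frame/strand
#' combinations an ORF runs from the first start codon (ATG/GTG/TTG)
#' following the previous stop codon (or the sequence edge) to the next
#' in-frame stop codon inclusive, or to the sequence edge
#' (`has_terminal_stop = FALSE`). Codons containing non-ACGT characters are
#' never a start, never a stop, and break any ORF that would contain them.
#' This caller deliberately trades Prodigal's start-site model for exact,
#' oracle-checkable semantics; the dual-code density signal it feeds depends
#' on the stop-codon landscape, not on start precision.
#'
#' @param seqs A data frame with columns `seq_id`, `seq`, or a single DNA
#'   string.
#' @param code A `genetic_code` object or code id (11, 25, 4).
#' @param min_orf_len Minimum ORF length in nucleotides (terminal stop codon
#'   included); must be divisible by 3. Default 90.
#' @return A tibble with one row per ORF: `seq_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `frame` (0-2, counted on the
#'   reverse complement for `-`), `code_id`, `has_terminal_stop`,
#'   `n_inframe_tga` and list-column `inframe_tga` (0-based forward-strand
#'   positions of internal TGA codons, only ever non-empty when TGA is a
#'   sense codon). Sorted by `seq_id`, `start`, `strand`, `frame`.
#' @export
#' @examples
#' find_orfs("ATGAAATGATAA", 25, min_orf_len = 6)
find_orfs <- function(seqs, code, min_orf_len = 90L) {
  seqs <- as_seq_tbl(seqs)
  code <- as_genetic_code(code)
  min_orf_len <- as.integer(min_orf_len)
  if (min_orf_len %% 3L != 0L || min_orf_len < 3L) {
    abort("min_orf_len must be a positive multiple of 3")
  }
  if (nrow(seqs) == 0L) {
    return(mutate(orf_tbl_empty(), seq_id = character(0), .before = 1L))
  }
  res <- purrr::map2(seqs$seq_id, seqs$seq, function(id, s) {
    orfs_one(s, code, min_orf_len) |> mutate(seq_id = id, .before = 1L)
  })
  bind_rows(res) |>
    arrange(.data$seq_id, .data$start, .data$strand, .data$frame)
}

# Accept either a seq tibble or a bare DNA string.
as_seq_tbl <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1L) {
    seqs <- tibble(seq_id = "seq1", seq = seqs)
  }
  check_seq_tbl(seqs)
}

orfs_one <- function(seq, code, min_orf_len) {
  if (!nzchar(seq)) abort("empty input sequence", class = "phagecode_empty_input")
  ch <- check_dna(seq, strict = FALSE)
  if (length(ch) < 3L) {
    return(orf_tbl_empty())
  }
  combos <- expand.grid(frame = 0:2, strand = c("+", "-"),
                        stringsAsFactors = FALSE)
  res <- purrr::pmap(combos, function(frame, strand) {
    orfs_frame(ch, code, frame, strand, min_orf_len)
  })
  bind_rows(res)
}

orf_tbl_empty <- function() {
  tibble(
    start = integer(0), end = integer(0), strand = character(0),
    frame = integer(0), code_id = integer(0),
    has_terminal_stop = logical(0), n_inframe_tga = integer(0),
    inframe_tga = list()
  )
}

# Scan one frame/strand. Works in codon-index space, then maps back to
# forward coordinates via the per-codon position vector.
orfs_frame <- function(ch, code, frame, strand, min_orf_len) {
  fc <- frame_codons(ch, frame, strand)
  m <- length(fc$codon)
  if (m == 0L) return(orf_tbl_empty())
  valid <- !str_detect(fc$codon, "[^ACGT]")
  is_stop <- fc$codon %in% code$stops
  is_start <- fc$codon %in% code$starts & valid
  # stops and N-codons both terminate scanning; only true stops are retained
  # as part of the ORF interval.
  barrier_idx <- which(is_stop | !valid)
  barriers <- c(barrier_idx, m + 1L)
  start_idx <- which(is_start)
  if (length(start_idx) == 0L) return(orf_tbl_empty())
  nxt <- barriers[findInterval(start_idx, barriers) + 1L]
  first_start <- tapply(start_idx, nxt, min)
  s <- as.integer(first_start)
  b <- as.integer(names(first_start))
  terminal <- b <= m & is_stop[pmin(b, m)]
  e <- ifelse(terminal, b, b - 1L)
  len_nt <- (e - s + 1L) * 3L
  keep <- len_nt >= min_orf_len
  if (!any(keep)) return(orf_tbl_empty())
  s <- s[keep]; e <- e[keep]; terminal <- terminal[keep]
  pos0 <- fc$pos0
  if (strand == "+") {
    start0 <- pos0[s]
    end0 <- pos0[e] + 3L
  } else {
    start0 <- pos0[e]
    end0 <- pos0[s] + 3L
  }
  tga_idx <- which(fc$codon == "TGA" & !is_stop)
  inframe <- purrr::pmap(list(s, e, terminal), function(si, ei, term) {
    last_sense <- if (term) ei - 1L else ei
    t_in <- tga_idx[tga_idx >= si & tga_idx <= last_sense]
    # exclude the start codon itself: TGA can never be a start, so no-op,
    # kept for clarity of the invariant (internal sense codons only).
    sort(pos0[t_in])
  })
  tibble(
    start = start0, end = end0, strand = strand, frame = as.integer(frame),
    code_id = code$code_id, has_terminal_stop = terminal,
    n_inframe_tga = purrr::map_int(inframe, length),
    inframe_tga = inframe
  )
}

#' Coding density under one genetic code
#'
#' Fraction of each sequence covered by the union of all maximal ORFs from
#' both strands (see [find_orfs()]).
#'
#' @inheritParams find_orfs
#' @return A tibble: `seq_id`, `length_bp`, `density` (fraction in 0-1).
#' @export
coding_density <- function(seqs, code, min_orf_len = 90L) {
  seqs <- as_seq_tbl(seqs)
  orfs <- find_orfs(seqs, code, min_orf_len)
  dens <- purrr::map2_dbl(seqs$seq_id, nchar(seqs$seq), function(id, len) {
    o <- orfs[orfs$seq_id == id, ]
    interval_union_width(o$start, o$end) / len
  })
  tibble(seq_id = seqs$seq_id, length_bp = nchar(seqs$seq), density = dens)
}

#' Dual-code coding-density profile and genetic-code call
#'
#' Computes the coding density of each sequence under the standard bacterial
#' code 11 and the alternative code 25 (TGA = glycine), their difference in
#' percentage points, and a genetic-code call. Sequences at or below
#' `size_floor` are not evaluated (`call = "not_evaluated"`); larger
#' sequences are called `"code25"` when the density gain reaches
#' `delta_threshold` percentage points and `"code11_compatible"` otherwise.
#'
#' @inheritParams find_orfs
#' @param min_orf_len Minimum ORF length for the density estimate, nt.
#'   Default 300 (100 codons): six-frame unions of short maximal ORFs
#'   saturate on chance open reading frames regardless of the true code,
#'   so density profiling uses a conventional long-ORF floor rather than
#'   [find_orfs()]'s 90 nt gene-calling default.
#' @param size_floor Minimum sequence length (bp, exclusive) for a call;
#'   default 20000.
#' @param delta_threshold Density difference (d25 - d11) in percentage
#'   points at or above which a sequence is called alternatively coded;
#'   default 10.
#' @return A tibble of class `code_profile`: `seq_id`, `length_bp`, `d11`,
#'   `d25`, `delta`, `call`.
#' @export
profile_code <- function(seqs, min_orf_len = 300L, size_floor = 20000L,
                         delta_threshold = 10) {
  seqs <- as_seq_tbl(seqs)
  dens11 <- coding_density(seqs, genetic_code(11L), min_orf_len)
  dens25 <- coding_density(seqs, genetic_code(25L), min_orf_len)
  out <- tibble(
    seq_id = dens11$seq_id,
    length_bp = dens11$length_bp,
    d11 = dens11$density,
    d25 = dens25$density,
    delta = (dens25$density - dens11$density) * 100
  ) |>
    mutate(call = dplyr::case_when(
      .data$length_bp <= size_floor ~ "not_evaluated",
      .data$delta >= delta_threshold ~ "code25",
      TRUE ~ "code11_compatible"
    ))
  class(out) <- c("code_profile", class(out))
  attr(out, "delta_threshold") <- delta_threshold
  attr(out, "size_floor") <- size_floor
  out
}

#' Gene-terminus stop-codon analysis
#'
#' For ORFs predicted under code 25, reports the terminal stop codon and any
#' backup stop codons within `window` in-frame codons downstream, and flags
#' termini that remain viable under code 11 (terminal TAA/TAG, or a TAA/TAG
#' backup close by). An ORF is additionally flagged `code11_translatable`
#' when it also contains no in-frame TGA. Edge ORFs without a terminal stop
#' are excluded.
#'
#' @param seqs Sequence tibble (or single string) the ORFs were called on.
#' @param orfs ORF tibble from [find_orfs()] under code 25.
#' @param window Number of in-frame codons scanned downstream of the
#'   terminal stop; default 10.
#' @return A tibble: ORF coordinates, `terminal_stop`, list-column
#'   `backup_stops` (tibble with `codon`, `offset` in codons downstream of
#'   the terminal stop), `code11_viable_terminus`, `code11_translatable`.
#' @export
analyze_termini <- function(seqs, orfs, window = 10L) {
  seqs <- as_seq_tbl(seqs)
  if (nrow(orfs) > 0 && any(orfs$code_id != 25L)) {
    warn("analyze_termini expects ORFs predicted under code 25")
  }
  seq_map <- setNames(str_to_upper(seqs$seq), seqs$seq_id)
  orfs <- orfs[orfs$has_terminal_stop, , drop = FALSE]
  if (nrow(orfs) == 0L) {
    return(tibble(
      seq_id = character(0), start = integer(0), end = integer(0),
      strand = character(0), terminal_stop = character(0),
      backup_stops = list(), code11_viable_terminus = logical(0),
      code11_translatable = logical(0)
    ))
  }
  rows <- purrr::pmap(
    list(orfs$seq_id, orfs$start, orfs$end, orfs$strand, orfs$n_inframe_tga),
    function(id, start, end, strand, n_tga) {
      s <- seq_map[[id]]
      if (is.null(s)) abort(sprintf("unknown seq_id '%s' in orfs", id))
      L <- nchar(s)
      if (start < 0L || end > L) {
        abort(sprintf("ORF [%d,%d) outside sequence '%s' (length %d)",
                      start, end, id, L), class = "phagecode_coord_error")
      }
      if (strand == "+") {
        terminal <- substr(s, end - 2L, end)
        offs <- seq_len(window)
        cod_start <- end + 3L * (offs - 1L) + 1L
        ok <- cod_start + 2L <= L
        codons <- substr(rep(s, sum(ok)), cod_start[ok], cod_start[ok] + 2L)
        offs <- offs[ok]
      } else {
        terminal <- revcomp(substr(s, start + 1L, start + 3L))
        offs <- seq_len(window)
        cod_start <- start - 3L * offs + 1L
        ok <- cod_start >= 1L
        codons <- vapply(cod_start[ok],
                         function(p) revcomp(substr(s, p, p + 2L)),
                         character(1))
        offs <- offs[ok]
      }
      is_bk <- codons %in% c("TAA", "TAG", "TGA")
      backup <- tibble(codon = codons[is_bk], offset = offs[is_bk])
      viable <- terminal %in% c("TAA", "TAG") ||
        any(backup$codon %in% c("TAA", "TAG"))
      tibble(
        seq_id = id, start = start, end = end, strand = strand,
        terminal_stop = terminal, backup_stops = list(backup),
        code11_viable_terminus = viable,
        code11_translatable = viable && n_tga == 0L
      )
    }
  )
  bind_rows(rows)
}
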