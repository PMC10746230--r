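# Readers and writers for the pipeline's file formats. FASTA goes through
# Biostrings; GFF3 and TSV are written with fixed column and attribute
# ordering so that identical runs produce byte-identical files.

#' Read a FASTA file into a sequence tibble
#'
#' @param path FASTA file path.
#' @return A tibble with `seq_id` (first whitespace-delimited token of the
#'   header) and `seq` (upper-case).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read FASTA file '%s'", path),
          class = "phagecode_io_error")
  }
  x <- Biostrings::readDNAStringSet(path)
  tibble(
    seq_id = sub("\\s.*$", "", names(x)),
    seq = unname(as.character(x))
  )
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with `seq_id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- check_seq_tbl(seqs)
  x <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$seq_id))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  gsub("=", "%3D", x, fixed = TRUE)
}

gff3_line <- function(seqid, source, type, start0, end0, score, strand,
                      phase, attrs) {
  paste(seqid, source, type, start0 + 1L, end0, score, strand, phase,
        attrs, sep = "\t")
}

#' Write ORFs as GFF3
#'
#' One `CDS` feature per ORF (1-based inclusive coordinates) with
#' attributes `code_id`, `inframe_tga` (count) and `terminal_stop`.
#'
#' @param orfs ORF tibble from [find_orfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orfs_gff3 <- function(orfs, path) {
  lines <- "##gff-version 3"
  if (nrow(orfs) > 0L) {
    attrs <- sprintf(
      "ID=orf%05d;code_id=%d;inframe_tga=%d;terminal_stop=%s",
      seq_len(nrow(orfs)), orfs$code_id, orfs$n_inframe_tga,
      ifelse(orfs$has_terminal_stop, "true", "false")
    )
    lines <- c(lines, gff3_line(gff3_escape(orfs$seq_id), "phagecode", "CDS",
                                orfs$start, orfs$end, ".", orfs$strand, "0",
                                attrs))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write CRISPR arrays as GFF3
#'
#' Each array becomes a `repeat_region` feature with child `direct_repeat`
#' and `binding_site` (spacer) features, mirroring the repeat/spacer
#' decomposition.
#'
#' @param arrays Array tibble from [detect_arrays()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arrays_gff3 <- function(arrays, path) {
  lines <- "##gff-version 3"
  if (nrow(arrays) > 0L) {
    for (i in seq_len(nrow(arrays))) {
      a <- arrays[i, ]
      aid <- sprintf("%s.array%d", a$seq_id, a$array_index)
      lines <- c(lines, gff3_line(
        gff3_escape(a$seq_id), "phagecode", "repeat_region", a$start, a$end,
        ".", "+", ".",
        sprintf("ID=%s;evidence=%s;n_spacers=%d;consensus=%s", aid,
                a$evidence, a$n_spacers, a$consensus_repeat)
      ))
      reps <- a$repeats[[1L]]
      lines <- c(lines, gff3_line(
        gff3_escape(a$seq_id), "phagecode", "direct_repeat", reps$start,
        reps$start + nchar(reps$seq), ".", "+", ".",
        sprintf("Parent=%s", aid)
      ))
      sps <- a$spacers[[1L]]
      lines <- c(lines, gff3_line(
        gff3_escape(a$seq_id), "phagecode", "binding_site", sps$start,
        sps$start + nchar(sps$seq), ".", "+", ".",
        sprintf("Parent=%s;spacer=%s", aid, sps$seq)
      ))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write a spacer database as FASTA and TSV
#'
#' @param db `spacer_db` tibble.
#' @param fasta_path,tsv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_spacer_db <- function(db, fasta_path = NULL, tsv_path = NULL) {
  if (!is.null(fasta_path)) {
    write_fasta(tibble(seq_id = db$spacer_id, seq = db$spacer), fasta_path)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(as_tibble(db), tsv_path)
  }
  invisible(c(fasta_path, tsv_path))
}

#' Read a host-group map
#'
#' Two-column TSV `genome_id`, `host_group`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_host_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}
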