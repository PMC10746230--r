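# Rule-based CRISPR-Cas subtype classification from cas gene labels, plus
# the genome fraction devoted to CRISPR-Cas defense.

CAS_LABELS <- c("cas9", "csn2", "cas1", "cas2", "cas4", "cpf1", "cas10",
                "cas7", "cas5", "csm2", "cmr5", "other")

# Gene-content rules, applied in order; several may fire for multi-system
# genomes. `forbid` handles the II-C1 "no csn2" clause.
CAS_RULES <- list(
  list(subtype = "II-A",  need = c("cas9", "csn2", "cas1", "cas2"), forbid = character(0)),
  list(subtype = "II-C1", need = c("cas9", "cas1", "cas2"),         forbid = "csn2"),
  list(subtype = "V-A",   need = c("cpf1", "cas1", "cas4", "cas2"), forbid = character(0)),
  list(subtype = "III-A", need = c("cas10", "cas7", "cas5", "csm2"), forbid = character(0)),
  list(subtype = "III-B", need = c("cas10", "cas7", "cas5", "cmr5"), forbid = character(0))
)

#' Classify a genome's CRISPR-Cas system subtype(s)
#'
#' Applies gene-content rules to the set of cas gene labels found in one
#' genome: (i) cas9+csn2+cas1+cas2 is type II-A; (ii) cas9+cas1+cas2
#' without csn2 is type II-C1; (iii) cpf1+cas1+cas4+cas2 is type V-A;
#' (iv) cas10+cas7+cas5+csm2 is type III-A; (v) cas10+cas7+cas5+cmr5 is
#' type III-B. Genomes with several complete gene sets return every
#' satisfied subtype. A genome without a high-evidence CRISPR array, or
#' matching no rule, is `"incomplete"`.
#'
#' @param labels Character vector of cas gene labels present in the genome
#'   (case-insensitive; unknown labels are dropped with a warning).
#' @param has_high_evidence_array Logical: does the genome carry at least
#'   one high-evidence CRISPR array?
#' @return Character vector of subtypes, or `"incomplete"`.
#' @export
#' @examples
#' classify_cas(c("cas9", "csn2", "cas1", "cas2"), TRUE)  # "II-A"
#' classify_cas(c("cas1", "cas2"), TRUE)                  # "incomplete"
classify_cas <- function(labels, has_high_evidence_array) {
  stopifnot(is.logical(has_high_evidence_array),
            length(has_high_evidence_array) == 1L)
  labels <- unique(tolower(labels))
  unknown <- setdiff(labels, CAS_LABELS)
  if (length(unknown) > 0L) {
    warn(sprintf("ignoring unknown cas gene label(s): %s",
                 paste(unknown, collapse = ", ")))
    labels <- intersect(labels, CAS_LABELS)
  }
  if (!has_high_evidence_array) return("incomplete")
  hits <- purrr::map_chr(CAS_RULES, function(r) {
    if (all(r$need %in% labels) && !any(r$forbid %in% labels)) r$subtype else NA_character_
  })
  hits <- hits[!is.na(hits)]
  if (length(hits) == 0L) "incomplete" else hits
}

#' Genome CRISPR-Cas budget
#'
#' Total bases and genome fraction devoted to CRISPR-Cas defense: the union
#' of cas gene intervals and CRISPR array intervals.
#'
#' @param genome_length Genome length in bp.
#' @param cas_intervals,array_intervals Data frames with 0-based half-open
#'   `start`, `end` columns (either may be empty or NULL).
#' @return A tibble with `total_bp` and `fraction`.
#' @export
#' @examples
#' crispr_budget(1000, data.frame(start = 0, end = 100),
#'               data.frame(start = 50, end = 150))
crispr_budget <- function(genome_length, cas_intervals = NULL,
                          array_intervals = NULL) {
  iv <- bind_rows(
    if (!is.null(cas_intervals)) as_tibble(cas_intervals)[, c("start", "end")],
    if (!is.null(array_intervals)) as_tibble(array_intervals)[, c("start", "end")]
  )
  if (is.null(iv) || nrow(iv) == 0L) {
    return(tibble(total_bp = 0L, fraction = 0))
  }
  if (any(iv$start < 0) || any(iv$end > genome_length)) {
    abort("interval outside [0, genome_length)", class = "phagecode_coord_error")
  }
  total <- interval_union_width(iv$start, iv$end)
  tibble(total_bp = total, fraction = total / genome_length)
}

#' Read cas gene annotations from TSV
#'
#' Expects columns `genome_id`, `seq_id`, `start`, `end` (0-based
#' half-open), `strand`, `label`. Labels are normalized to lower case.
#'
#' @param path TSV file path.
#' @return A tibble of cas annotations.
#' @export
read_cas_annotations <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    genome_id = "c", seq_id = "c", start = "i", end = "i",
    strand = "c", label = "c"
  ))
  mutate(x, label = tolower(.data$label))
}

#' Classify every genome in a cas annotation table
#'
#' Pools labels per genome (the default, mirroring genome-level
#' co-occurrence of cas genes) or per scaffold, joins the high-evidence
#' array flag, and applies [classify_cas()].
#'
#' @param cas_annotations Tibble as from [read_cas_annotations()].
#' @param arrays Array tibble from [detect_arrays()] (used for the
#'   high-evidence flag; scaffold `seq_id`s are matched to `genome_id` via
#'   `genome_map` when pooling per genome).
#' @param genome_map Optional tibble `seq_id`, `genome_id`; defaults to
#'   `seq_id == genome_id` (single-scaffold genomes).
#' @param per_scaffold Classify per scaffold instead of per genome.
#' @return A tibble: `genome_id`, `subtype` (one row per fired rule, or
#'   `"incomplete"`), `genes_matched`, `has_high_evidence_array`.
#' @export
classify_cas_table <- function(cas_annotations, arrays, genome_map = NULL,
                               per_scaffold = FALSE) {
  cas <- as_tibble(cas_annotations)
  if (is.null(genome_map)) {
    ids <- unique(c(cas$seq_id, arrays$seq_id))
    genome_map <- tibble(seq_id = ids, genome_id = ids)
  }
  key <- if (per_scaffold) "seq_id" else "genome_id"
  arr_flag <- arrays |>
    filter(.data$evidence == "high") |>
    left_join(genome_map, by = "seq_id")
  units <- unique(c(cas[[key]], arr_flag[[key]]))
  rows <- purrr::map(sort(units), function(u) {
    labs <- cas$label[cas[[key]] == u]
    flag <- u %in% arr_flag[[key]]
    subs <- classify_cas(labs, flag)
    tibble(genome_id = u, subtype = subs,
           genes_matched = paste(sort(unique(labs)), collapse = ","),
           has_high_evidence_array = flag)
  })
  bind_rows(rows)
}
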