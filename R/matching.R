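#' Match one spacer against a target sequence
#'
#' Ungapped, end-anchored matcher reproducing short-spacer BLASTn semantics
#' under the stated thresholds: every window of length `L'` between
#' `ceiling(min_coverage * L)` and the full spacer length `L` (truncations
#' anchored at either spacer end) is aligned without gaps at every target
#' offset on both strands, and windows with Hamming distance at most
#' `max_mismatch` are reported. Overlapping candidate hits on the same
#' strand are merged keeping minimal mismatches (ties: maximal matched
#' length, then leftmost).
#'
#' @param spacer Spacer DNA string (>= 15 nt; a warning is issued below 20
#'   nt, where chance matches become plausible).
#' @param target Target DNA string.
#' @param min_coverage Minimum fraction of the spacer that must align
#'   (default 0.95).
#' @param max_mismatch Maximum number of mismatches (default 1).
#' @return A tibble: `start`, `end` (0-based half-open on the target
#'   forward strand), `strand` (strand of the match), `matched_len`,
#'   `mismatches`, `coverage`.
#' @export
#' @examples
#' match_spacer("ACGTACGTACGTACGTACGTACGTACGTAC",
#'              paste0("TTTT", "ACGTACGTACGTACGTACGTACGTACGTAC", "TTTT"))
match_spacer <- function(spacer, target, min_coverage = 0.95,
                         max_mismatch = 1L) {
  spacer <- str_to_upper(spacer)
  target <- str_to_upper(target)
  L <- nchar(spacer)
  if (L < 15L) {
    abort("spacer shorter than 15 nt; matches would be spurious",
          class = "phagecode_short_spacer")
  }
  if (L < 20L) warn(sprintf("spacer of %d nt is unusually short", L))
  rc <- revcomp(spacer)
  hits <- bind_rows(
    if (seeds_present(spacer, target, min_coverage, max_mismatch)) {
      scan_windows(spacer, target, "+", min_coverage, max_mismatch)
    },
    if (seeds_present(rc, target, min_coverage, max_mismatch)) {
      scan_windows(rc, target, "-", min_coverage, max_mismatch)
    }
  )
  if (nrow(hits) == 0L) return(hits_tbl_empty())
  hits$coverage <- hits$matched_len / L
  merge_hits(hits)
}

hits_tbl_empty <- function() {
  tibble(start = integer(0), end = integer(0), strand = character(0),
         matched_len = integer(0), mismatches = integer(0),
         coverage = double(0))
}

# Pigeonhole prefilter: every admissible window keeps pattern positions
# (L - lmin + 1)..lmin intact up to max_mismatch substitutions, so at least
# one of max_mismatch + 1 equal slices of that interior must occur exactly
# in the target. Skipped (returns TRUE) when slices would be too short to
# be selective.
seeds_present <- function(pat, target, min_coverage, max_mismatch) {
  L <- nchar(pat)
  lmin <- as.integer(ceiling(min_coverage * L))
  lo <- L - lmin + 1L
  hi <- lmin
  k <- max_mismatch + 1L
  slice <- (hi - lo + 1L) %/% k
  if (slice < 8L) return(TRUE)
  for (i in seq_len(k)) {
    seed <- substr(pat, lo + (i - 1L) * slice, lo + i * slice - 1L)
    if (grepl(seed, target, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

# All candidate (window, offset) hits of `pat` on the target forward
# strand. Truncated windows are anchored at either end of the pattern.
scan_windows <- function(pat, target, strand, min_coverage, max_mismatch) {
  L <- nchar(pat)
  lmin <- as.integer(ceiling(min_coverage * L))
  tch <- seq_chars(target)
  n <- length(tch)
  out <- list()
  for (Lp in lmin:L) {
    anchors <- if (Lp == L) "prefix" else c("prefix", "suffix")
    for (anc in anchors) {
      w <- if (anc == "prefix") substr(pat, 1L, Lp) else
        substr(pat, L - Lp + 1L, L)
      if (n < Lp) next
      wch <- seq_chars(w)
      noff <- n - Lp + 1L
      mism <- integer(noff)
      for (j in seq_len(Lp)) {
        mism <- mism + (tch[j:(j + noff - 1L)] != wch[j])
      }
      ok <- which(mism <= max_mismatch)
      if (length(ok) > 0L) {
        out[[length(out) + 1L]] <- tibble(
          start = ok - 1L, end = ok - 1L + Lp, strand = strand,
          matched_len = Lp, mismatches = mism[ok]
        )
      }
    }
  }
  bind_rows(out)
}

# Cluster candidate hits by interval overlap per strand; keep the best hit
# per cluster (min mismatches, then max matched_len, then leftmost).
merge_hits <- function(hits) {
  res <- purrr::map(split(hits, hits$strand), function(h) {
    ir <- IRanges::IRanges(h$start + 1L, h$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    h |>
      mutate(.grp = grp) |>
      group_by(.data$.grp) |>
      arrange(.data$mismatches, desc(.data$matched_len), .data$start,
              .by_group = TRUE) |>
      slice(1L) |>
      ungroup() |>
      select(-".grp")
  })
  bind_rows(res) |> arrange(.data$start, .data$strand)
}

#' Match a spacer database against target sequences and derive host links
#'
#' Runs [match_spacer()] for every spacer/target pair, then aggregates one
#' host link per target with at least one hit, carrying the host groups of
#' the spacers' source genomes.
#'
#' @param spacer_db A `spacer_db` tibble with a `host_group` column (join
#'   one from a `genome_id`/`host_group` map, e.g. via [run_pipeline()]).
#' @param targets Sequence tibble (`seq_id`, `seq`) of candidate phages.
#' @param min_coverage,max_mismatch Matching thresholds (defaults 0.95, 1).
#' @return A list with two tibbles: `hits` (`spacer_id`, `target_id`,
#'   coordinates, `strand`, `matched_len`, `mismatches`, `coverage`,
#'   `host_group`) and `links` (`target_id`, `n_hits`, `n_spacers`,
#'   `host_groups` list-column), both deterministically ordered.
#' @export
link_hosts <- function(spacer_db, targets, min_coverage = 0.95,
                       max_mismatch = 1L) {
  targets <- as_seq_tbl(targets)
  db <- as_tibble(spacer_db)
  if (!"host_group" %in% names(db)) {
    abort("spacer_db needs a host_group column (join a host map first)")
  }
  if (nrow(db) == 0L) {
    hits <- tibble(spacer_id = character(0), target_id = character(0),
                   start = integer(0), end = integer(0),
                   strand = character(0), matched_len = integer(0),
                   mismatches = integer(0), coverage = double(0),
                   host_group = character(0))
    return(list(hits = hits, links = tibble(
      target_id = character(0), n_hits = integer(0), n_spacers = integer(0),
      host_groups = list()
    )))
  }
  combos <- tidyr::expand_grid(si = seq_len(nrow(db)),
                               ti = seq_len(nrow(targets)))
  hit_rows <- purrr::pmap(combos, function(si, ti) {
    h <- match_spacer(db$spacer[si], targets$seq[ti], min_coverage,
                      max_mismatch)
    if (nrow(h) == 0L) return(NULL)
    mutate(h, spacer_id = db$spacer_id[si], target_id = targets$seq_id[ti],
           host_group = db$host_group[si], .before = 1L)
  })
  hits <- bind_rows(hit_rows) |>
    (\(h) if (nrow(h) == 0L) h else
      arrange(h, .data$target_id, .data$spacer_id, .data$start))()
  if (nrow(hits) == 0L) {
    links <- tibble(target_id = character(0), n_hits = integer(0),
                    n_spacers = integer(0), host_groups = list())
  } else {
    links <- hits |>
      group_by(.data$target_id) |>
      summarise(
        n_hits = dplyr::n(),
        n_spacers = dplyr::n_distinct(.data$spacer_id),
        host_groups = list(sort(unique(.data$host_group)))
      ) |>
      arrange(.data$target_id)
  }
  list(hits = hits, links = links)
}

#' Identify co-targeted phages
#'
#' A phage is co-targeted when its supporting spacer hits span at least one
#' SGA host group and at least one non-SGA host group.
#'
#' @param links Links tibble from [link_hosts()] (element `links`).
#' @param sga Character vector of host groups counted as SGA
#'   (default [sga_groups()]).
#' @return The subset of `links` that is co-targeted, with `sga_groups` and
#'   `non_sga_groups` list-columns.
#' @export
find_cotargeted <- function(links, sga = sga_groups()) {
  if (nrow(links) == 0L) {
    return(mutate(links, sga_groups = list(), non_sga_groups = list()))
  }
  links |>
    mutate(
      sga_groups = purrr::map(.data$host_groups, ~ intersect(.x, sga)),
      non_sga_groups = purrr::map(.data$host_groups, ~ setdiff(.x, sga))
    ) |>
    filter(purrr::map_int(.data$sga_groups, length) >= 1L,
           purrr::map_int(.data$non_sga_groups, length) >= 1L)
}

#' Shared spacers between two inventories
#'
#' Full-length, 100%-identity intersection of two spacer sets, checking
#' both orientations; an empty result argues against horizontal transfer of
#' spacers between the two sources.
#'
#' @param inventory_a,inventory_b Character vectors of spacer sequences.
#' @return A tibble: `spacer` (as present in `inventory_a`), `orientation`
#'   (`"forward"` or `"reverse_complement"`).
#' @export
shared_spacers <- function(inventory_a, inventory_b) {
  a <- unique(str_to_upper(inventory_a))
  b <- unique(str_to_upper(inventory_b))
  b_rc <- vapply(b, revcomp, character(1), USE.NAMES = FALSE)
  fwd <- intersect(a, b)
  rev <- setdiff(intersect(a, b_rc), fwd)
  bind_rows(
    tibble(spacer = sort(fwd), orientation = rep("forward", length(fwd))),
    tibble(spacer = sort(rev),
           orientation = rep("reverse_complement", length(rev)))
  )
}
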