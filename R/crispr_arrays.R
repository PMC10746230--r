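#' Detect CRISPR arrays (CRT-style seed-and-extend)
#'
#' Finds runs of near-identical direct repeats separated by unique spacers.
#' Exact 8-mer recurrences at an admissible period seed candidate repeats,
#' which are then extended column-wise across all copies while columns stay
#' unanimous (a single non-unanimous column is absorbed when followed by
#' three unanimous ones, tolerating isolated point mutations). Candidates
#' are kept when they have at least `min_spacers + 1` repeat copies, repeat
#' length 23-55 nt, every spacer 20-60 nt, and mean repeat identity against
#' the column consensus of at least `min_repeat_identity`.
#'
#' The `evidence` field is a proxy for a high-confidence array: `"high"`
#' requires >= `min_spacers` spacers, mean repeat identity >= 0.90 and
#' maximal pairwise spacer identity < `max_spacer_identity` (near-identical
#' "spacers" usually indicate a tandem repeat, not a CRISPR array). This is
#' an approximation of CRISPRCasFinder's evidence levels 3-4, not a
#' reimplementation.
#'
#' @param seqs Sequence tibble (`seq_id`, `seq`) or a single DNA string.
#' @param k_seed Seed k-mer length (default 8).
#' @param repeat_len Admissible repeat length range, nt (default c(23, 55)).
#' @param spacer_len Admissible spacer length range, nt (default c(20, 60)).
#' @param min_spacers Minimum number of spacers (default 3).
#' @param min_repeat_identity Minimum mean repeat identity to the consensus
#'   (default 0.90).
#' @param max_spacer_identity Pairwise spacer identity at or above which an
#'   array is demoted to `"low"` evidence (default 0.60).
#' @return A tibble with one row per array: `seq_id`, `array_index`,
#'   `start`, `end` (0-based half-open), `n_repeats`, `n_spacers`,
#'   `consensus_repeat`, `mean_repeat_identity`, `max_spacer_pair_identity`,
#'   `evidence`, and list-columns `repeats`, `spacers` (each a tibble with
#'   `start`, `seq`). Sorted by `seq_id`, `start`.
#' @export
detect_arrays <- function(seqs, k_seed = 8L, repeat_len = c(23L, 55L),
                          spacer_len = c(20L, 60L), min_spacers = 3L,
                          min_repeat_identity = 0.90,
                          max_spacer_identity = 0.60) {
  seqs <- as_seq_tbl(seqs)
  res <- purrr::map2(seqs$seq_id, seqs$seq, function(id, s) {
    arr <- detect_arrays_one(str_to_upper(s), k_seed, repeat_len, spacer_len,
                             min_spacers, min_repeat_identity,
                             max_spacer_identity)
    if (nrow(arr) > 0) arr$seq_id <- id
    arr
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) return(array_tbl_empty())
  out |>
    arrange(.data$seq_id, .data$start) |>
    group_by(.data$seq_id) |>
    mutate(array_index = row_number()) |>
    ungroup() |>
    select("seq_id", "array_index", dplyr::everything())
}

array_tbl_empty <- function() {
  tibble(
    seq_id = character(0), array_index = integer(0), start = integer(0),
    end = integer(0), n_repeats = integer(0), n_spacers = integer(0),
    consensus_repeat = character(0), mean_repeat_identity = double(0),
    max_spacer_pair_identity = double(0), evidence = character(0),
    repeats = list(), spacers = list()
  )
}

detect_arrays_one <- function(s, k, repeat_len, spacer_len, min_spacers,
                              min_repeat_identity, max_spacer_identity) {
  n <- nchar(s)
  empty <- array_tbl_empty()[, -(1:2)]
  if (n < 200L) return(empty)
  ch <- seq_chars(s)
  nk <- n - k + 1L
  kmers <- substring(s, 1:nk, (1:nk) + k - 1L)
  valid_km <- !str_detect(kmers, "[^ACGT]")
  occ <- split(which(valid_km), kmers[valid_km])
  dmin <- repeat_len[1L] + spacer_len[1L]
  dmax <- repeat_len[2L] + spacer_len[2L]
  claimed <- logical(n)
  min_copies <- min_spacers + 1L
  found <- list()

  col_unanimous <- function(idx) {
    if (any(idx < 1L) || any(idx > n) || any(claimed[idx])) return(FALSE)
    b <- ch[idx]
    b[1L] %in% DNA_BASES && all(b == b[1L])
  }
  claimed_any <- function(a, b) {
    a < 1L || b > n || any(claimed[a:b])
  }

  i <- 1L
  while (i <= nk) {
    if (claimed[i] || !valid_km[i]) { i <- i + 1L; next }
    pos <- occ[[kmers[i]]]
    cand <- pos[pos >= i + dmin & pos <= i + dmax & !claimed[pos]]
    if (length(cand) == 0L) { i <- i + 1L; next }
    P <- c(i, cand[1L])
    repeat {
      last <- P[length(P)]
      nxt <- pos[pos >= last + dmin & pos <= last + dmax & !claimed[pos]]
      if (length(nxt) == 0L) break
      P <- c(P, nxt[1L])
    }
    if (length(P) < min_copies) { i <- i + 1L; next }
    arr <- build_array(s, ch, n, P, k, repeat_len, spacer_len, min_spacers,
                       min_repeat_identity, max_spacer_identity,
                       col_unanimous, claimed_any)
    if (is.null(arr)) { i <- i + 1L; next }
    claimed[(arr$start + 1L):arr$end] <- TRUE
    found <- c(found, list(arr))
    i <- arr$end + 1L
  }
  if (length(found) == 0L) return(empty)
  bind_rows(found)
}

# Extend a seeded repeat chain to its maximal extent and validate it.
build_array <- function(s, ch, n, P, k, repeat_len, spacer_len, min_spacers,
                        min_repeat_identity, max_spacer_identity,
                        col_unanimous, claimed_any) {
  # cap keeps the shortest gap an admissible spacer and the repeat <= max
  cap_gap <- min(diff(P)) - k - spacer_len[1L]
  extend_dir <- function(offsets_fun, budget) {
    ext <- 0L
    while (ext < budget) {
      if (col_unanimous(offsets_fun(ext + 1L))) { ext <- ext + 1L; next }
      la_ok <- all(vapply(2:4, function(d) {
        ext + d <= budget && col_unanimous(offsets_fun(ext + d))
      }, logical(1)))
      if (la_ok) ext <- ext + 1L else break
    }
    ext
  }
  budget_r <- min(repeat_len[2L] - k, cap_gap)
  ext_r <- if (budget_r > 0L) {
    extend_dir(function(d) P + k - 1L + d, budget_r)
  } else 0L
  budget_l <- min(repeat_len[2L] - k - ext_r, cap_gap - ext_r)
  ext_l <- if (budget_l > 0L) {
    extend_dir(function(d) P - d, budget_l)
  } else 0L
  rep_len <- k + ext_l + ext_r
  if (rep_len < repeat_len[1L] || rep_len > repeat_len[2L]) return(NULL)
  R <- P - ext_l

  # Augment: a seed straddling a flank can chain onto a subset of copies
  # (those whose neighbouring base happens to match the flank); recover
  # missed copies by scanning for the consensus just beyond both ends.
  get_cons <- function() consensus_string(substring(s, R, R + rep_len - 1L))
  seek_copy <- function(from, to) {
    from <- max(1L, from); to <- min(n - rep_len + 1L, to)
    if (from > to) return(NA_integer_)
    cand <- from:to
    cons <- get_cons()
    idents <- vapply(cand, function(q) {
      string_identity(substr(s, q, q + rep_len - 1L), cons)
    }, double(1))
    best <- which(idents >= min_repeat_identity)
    if (length(best) == 0L) return(NA_integer_)
    cand[best[which.max(idents[best])]]
  }
  repeat {
    q <- seek_copy(R[length(R)] + rep_len + spacer_len[1L],
                   R[length(R)] + rep_len + spacer_len[2L])
    if (is.na(q) || claimed_any(q, q + rep_len - 1L)) break
    R <- c(R, q)
  }
  repeat {
    q <- seek_copy(R[1L] - rep_len - spacer_len[2L],
                   R[1L] - rep_len - spacer_len[1L])
    if (is.na(q) || claimed_any(q, q + rep_len - 1L)) break
    R <- c(q, R)
  }

  # Trim: with the full copy set, boundary columns contaminated by flank
  # or spacer bases are no longer unanimous; shrink to the identifiable
  # repeat extent.
  col_u <- function(idx) {
    b <- ch[idx]
    all(idx >= 1L) && all(idx <= n) && b[1L] %in% DNA_BASES &&
      all(b == b[1L])
  }
  while (rep_len > repeat_len[1L] && !col_u(R)) {
    R <- R + 1L
    rep_len <- rep_len - 1L
  }
  while (rep_len > repeat_len[1L] && !col_u(R + rep_len - 1L)) {
    rep_len <- rep_len - 1L
  }

  copies <- substring(s, R, R + rep_len - 1L)
  gaps <- diff(R) - rep_len
  ok_gap <- gaps >= spacer_len[1L] & gaps <= spacer_len[2L]
  run <- longest_true_run(ok_gap)
  if (is.null(run) || run$len + 1L < min_spacers + 1L) return(NULL)
  keep <- run$from:(run$from + run$len)
  R <- R[keep]; copies <- copies[keep]
  m <- length(R)
  cons <- consensus_string(copies)
  ident <- vapply(copies, function(x) string_identity(x, cons), double(1))
  mri <- mean(ident)
  if (mri < min_repeat_identity) return(NULL)
  sp_start <- R[-m] + rep_len
  sp_end <- R[-1L]
  spacers <- substring(s, sp_start, sp_end - 1L)
  mspi <- max_pairwise_identity(spacers)
  evidence <- if (length(spacers) >= min_spacers && mri >= 0.90 &&
                  mspi < max_spacer_identity) "high" else "low"
  tibble(
    start = R[1L] - 1L, end = R[m] + rep_len - 1L,
    n_repeats = m, n_spacers = m - 1L,
    consensus_repeat = cons, mean_repeat_identity = mri,
    max_spacer_pair_identity = mspi, evidence = evidence,
    repeats = list(tibble(start = R - 1L, seq = unname(copies))),
    spacers = list(tibble(start = sp_start - 1L, seq = unname(spacers)))
  )
}

longest_true_run <- function(x) {
  if (length(x) == 0L || !any(x)) return(NULL)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tr <- which(r$values)
  best <- tr[which.max(r$lengths[tr])]
  list(from = starts[best], len = r$lengths[best])
}

consensus_string <- function(copies) {
  mat <- do.call(rbind, strsplit(copies, "", fixed = TRUE))
  paste(apply(mat, 2L, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    # deterministic tie-break: alphabetically first among most frequent
    cand <- names(tab)[tab == tab[1L]]
    sort(cand)[1L]
  }), collapse = "")
}

# Fraction of matching positions, left-aligned, over the longer length.
string_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  m <- min(la, lb)
  if (m == 0L) return(0)
  ca <- substring(a, 1:m, 1:m)
  cb <- substring(b, 1:m, 1:m)
  sum(ca == cb) / max(la, lb)
}

max_pairwise_identity <- function(x) {
  if (length(x) < 2L) return(0)
  mx <- 0
  for (a in seq_len(length(x) - 1L)) {
    for (b in (a + 1L):length(x)) {
      mx <- max(mx, string_identity(x[a], x[b]))
    }
  }
  mx
}

#' Build a dereplicated spacer database from detected arrays
#'
#' Extracts spacers from (by default) high-evidence arrays only and
#' dereplicates them by exact full-length string identity. Reverse
#' complements are not collapsed; downstream matching scans both strands, so
#' orientation only affects database size.
#'
#' @param arrays Array tibble from [detect_arrays()].
#' @param only_high Keep spacers from `evidence == "high"` arrays only
#'   (default TRUE).
#' @return A tibble of class `spacer_db`: `spacer_id`, `seq_id`,
#'   `array_index`, `position_index`, `spacer`. One row per distinct spacer
#'   sequence (first occurrence kept, in `seq_id`/array/position order).
#' @export
extract_spacers <- function(arrays, only_high = TRUE) {
  if (only_high && nrow(arrays) > 0L) {
    arrays <- arrays[arrays$evidence == "high", , drop = FALSE]
  }
  if (nrow(arrays) == 0L) {
    return(spacer_db(tibble(spacer_id = character(0), seq_id = character(0),
                            array_index = integer(0),
                            position_index = integer(0),
                            spacer = character(0))))
  }
  long <- arrays |>
    select("seq_id", "array_index", "spacers") |>
    mutate(spacers = purrr::map(.data$spacers, ~ mutate(.x, position_index = row_number()))) |>
    tidyr::unnest("spacers") |>
    mutate(
      spacer_id = sprintf("%s|arr%d|sp%d", .data$seq_id, .data$array_index,
                          .data$position_index),
      spacer = .data$seq
    ) |>
    select("spacer_id", "seq_id", "array_index", "position_index", "spacer")
  spacer_db(distinct(long, .data$spacer, .keep_all = TRUE))
}

spacer_db <- function(x) {
  class(x) <- unique(c("spacer_db", class(x)))
  x
}

#' Import externally supplied spacers into a spacer database
#'
#' Adds spacers (for example, ones recovered from read-level array
#' expansion) from a two-column TSV (`spacer_id`, `spacer`) or an equivalent
#' data frame, then re-dereplicates by exact sequence identity; existing
#' entries win ties.
#'
#' @param db A `spacer_db` tibble from [extract_spacers()] (may be empty).
#' @param extra Path to a two-column TSV or a data frame with columns
#'   `spacer_id` and `spacer`.
#' @return The merged, dereplicated `spacer_db`.
#' @export
import_spacers <- function(db, extra) {
  if (is.character(extra)) {
    extra <- readr::read_tsv(extra, col_types = readr::cols(.default = "c"))
  }
  if (!all(c("spacer_id", "spacer") %in% names(extra))) {
    abort("extra spacers need columns spacer_id and spacer")
  }
  extra <- as_tibble(extra) |>
    mutate(
      spacer = str_to_upper(.data$spacer),
      seq_id = .data$spacer_id %||% NA_character_,
      array_index = NA_integer_, position_index = NA_integer_
    ) |>
    select("spacer_id", "seq_id", "array_index", "position_index", "spacer")
  spacer_db(distinct(bind_rows(as_tibble(db), extra),
                     .data$spacer, .keep_all = TRUE))
}
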