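# Seed-reproducible synthetic genomes, CRISPR arrays, cas operons and phage
# sets with planted ground truth. The generator realizes the study
# conditions every pipeline stage is validated against: genomes written in
# code 11 or code 25 (the latter spelling a configurable fraction of
# glycines as TGA), dense gene packing with stop-enriched random intergenic
# sequence, planted repeat/spacer arrays, labeled cas operons, and phages
# carrying protospacers with a controlled number of injected mismatches.

#' Specification of one synthetic genome
#'
#' @param genome_id Sequence identifier.
#' @param length Target length in bp; the realized genome is at least this
#'   long (generation stops at the first gene unit crossing the target, so
#'   the overshoot is below one gene unit, about 1 kb).
#' @param code_id 11 or 25.
#' @param gene_fraction Target fraction of the genome covered by genes
#'   (default 0.9, dense prokaryotic/phage-like packing).
#' @param mean_gene_len Mean gene length, nt (default 900).
#' @param tga_gly_fraction For code 25: probability that a glycine codon is
#'   written as TGA (default 0.3; forced to 0 under code 11).
#' @param backup_stop_prob Probability that a gene terminus is followed by
#'   a planted TAA/TAG backup stop within 10 in-frame codons (default 0.8,
#'   the backup-stop-rich regime seen at gene termini of dual-code-viable
#'   genomes).
#' @param array_specs List of CRISPR arrays to plant; each element a list
#'   with `n_spacers` (default 5), `repeat_len` (default 30) and
#'   `spacer_len_range` (default c(26, 40)).
#' @param cas_labels Character vector of cas gene labels to plant as one
#'   operon (NULL for none).
#' @param seed Integer seed; identical specs give byte-identical output.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(genome_id, length = 30000L, code_id = 11L,
                        gene_fraction = 0.9, mean_gene_len = 900L,
                        tga_gly_fraction = 0.3, backup_stop_prob = 0.8,
                        array_specs = list(), cas_labels = NULL,
                        seed = 1L) {
  if (code_id == 11L) tga_gly_fraction <- 0
  stopifnot(gene_fraction > 0, gene_fraction <= 1,
            tga_gly_fraction >= 0, tga_gly_fraction <= 1,
            backup_stop_prob >= 0, backup_stop_prob <= 1)
  structure(list(
    genome_id = genome_id, length = as.integer(length),
    code_id = as.integer(code_id), gene_fraction = gene_fraction,
    mean_gene_len = as.integer(mean_gene_len),
    tga_gly_fraction = tga_gly_fraction,
    backup_stop_prob = backup_stop_prob,
    array_specs = array_specs, cas_labels = cas_labels,
    seed = as.integer(seed)
  ), class = "genome_spec")
}

SENSE11 <- local({
  tab <- Biostrings::getGeneticCode("11")
  names(tab)[tab != "*"]
})
GLY_CODONS <- c("GGA", "GGC", "GGG", "GGT")
STOPS11 <- c("TAA", "TAG", "TGA")

CAS_GENE_LEN <- c(
  cas9 = 3100L, cpf1 = 3800L, cas1 = 900L, cas2 = 300L, csn2 = 650L,
  cas4 = 550L, cas10 = 2400L, cas7 = 1000L, cas5 = 700L, csm2 = 400L,
  cmr5 = 400L, other = 800L
)

# A protein-coding gene as a string: start codon, sense codons (glycine
# spelled TGA with probability tga_frac under code 25), terminal stop drawn
# from the code's stop set.
make_gene <- function(n_codons, code_id, tga_frac) {
  body <- sample(SENSE11, n_codons - 2L, replace = TRUE)
  if (code_id == 25L && tga_frac > 0) {
    gly <- which(body %in% GLY_CODONS)
    flip <- gly[runif(length(gly)) < tga_frac]
    body[flip] <- "TGA"
  }
  start <- sample(c("ATG", "GTG", "TTG"), 1L, prob = c(0.7, 0.2, 0.1))
  stop <- if (code_id == 25L) sample(c("TAA", "TAG"), 1L) else
    sample(STOPS11, 1L)
  paste(c(start, body, stop), collapse = "")
}

# One gene unit in gene orientation: gene followed by its downstream
# intergenic stretch, with an optional in-frame TAA/TAG backup stop planted
# 1-10 codons after the terminal stop. Minus-strand units are
# reverse-complemented as a whole, which keeps the backup stop downstream
# of the gene in its own reading direction.
make_unit <- function(spec, mean_ig) {
  n_codons <- max(60L, round(rnorm(1L, spec$mean_gene_len / 3,
                                   spec$mean_gene_len / 9)))
  gene <- make_gene(n_codons, spec$code_id, spec$tga_gly_fraction)
  ig_len <- as.integer(max(33L, min(round(rnorm(1L, mean_ig, mean_ig / 4)),
                                    3L * mean_ig)))
  ig <- seq_chars(random_dna(ig_len))
  backup_offset <- NA_integer_
  backup_codon <- NA_character_
  if (runif(1L) < spec$backup_stop_prob) {
    backup_offset <- sample.int(min(10L, ig_len %/% 3L), 1L)
    backup_codon <- sample(c("TAA", "TAG"), 1L)
    at <- 3L * (backup_offset - 1L)
    ig[(at + 1L):(at + 3L)] <- seq_chars(backup_codon)
  }
  strand <- sample(c("+", "-"), 1L)
  unit <- paste0(gene, paste(ig, collapse = ""))
  if (strand == "-") unit <- revcomp(unit)
  list(seq = unit, type = "unit", strand = strand,
       gene_len = nchar(gene), backup_offset = backup_offset,
       backup_codon = backup_codon)
}

# Repeat/spacer array segment. Spacer bases adjacent to the repeat copies
# are resampled so that no boundary column is unanimous across copies:
# without this guard, chance agreement of flanking bases would make the
# true repeat boundary unidentifiable for any consensus-based detector.
make_array_segment <- function(aspec) {
  n_spacers <- aspec$n_spacers %||% 5L
  repeat_len <- aspec$repeat_len %||% 30L
  rng <- aspec$spacer_len_range %||% c(26L, 40L)
  rep_seq <- random_dna(repeat_len)
  lens <- sample(seq.int(rng[1L], rng[2L]), n_spacers, replace = TRUE)
  spacers <- vapply(lens, random_dna, character(1))
  fix_col <- function(chars_get, chars_set) {
    v <- vapply(seq_along(spacers), function(i) chars_get(spacers[i]),
                character(1))
    if (length(unique(v)) == 1L) {
      alt <- sample(setdiff(DNA_BASES, v[1L]), 1L)
      spacers[1L] <<- chars_set(spacers[1L], alt)
    }
  }
  if (n_spacers >= 2L) {
    fix_col(function(s) substr(s, nchar(s), nchar(s)),
            function(s, b) paste0(substr(s, 1L, nchar(s) - 1L), b))
    fix_col(function(s) substr(s, 1L, 1L),
            function(s, b) paste0(b, substr(s, 2L, nchar(s))))
  }
  pieces <- character(2L * n_spacers + 1L)
  pieces[seq(1L, length(pieces), 2L)] <- rep_seq
  pieces[seq(2L, length(pieces), 2L)] <- spacers
  seg <- paste(pieces, collapse = "")
  starts <- cumsum(c(0L, nchar(pieces)[-length(pieces)]))
  list(seq = seg, type = "array", repeat_seq = rep_seq,
       repeat_starts = starts[seq(1L, length(pieces), 2L)],
       spacer_starts = starts[seq(2L, length(pieces), 2L)],
       spacers = spacers)
}

make_cas_segment <- function(labels, code_id, tga_frac) {
  gaps <- 20L
  genes <- vapply(labels, function(lab) {
    len <- CAS_GENE_LEN[[match.arg(lab, names(CAS_GENE_LEN))]]
    make_gene(len %/% 3L, code_id, tga_frac)
  }, character(1))
  pieces <- as.vector(rbind(genes, vapply(seq_along(genes), function(i)
    random_dna(gaps), character(1))))
  pieces <- pieces[-length(pieces)]
  starts <- cumsum(c(0L, nchar(pieces)[-length(pieces)]))
  list(seq = paste(pieces, collapse = ""), type = "cas", labels = labels,
       gene_starts = starts[seq(1L, length(pieces), 2L)],
       gene_lens = nchar(genes))
}

#' Generate one synthetic genome with planted truth
#'
#' @param spec A [genome_spec()].
#' @return A list with `seq` (one-row tibble `seq_id`, `seq`) and `truth`,
#'   a list holding the planted gene intervals (0-based half-open, with
#'   strand and backup-stop bookkeeping), array coordinates with repeat and
#'   spacer decompositions, and cas gene intervals with labels.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, simulate_genome_impl(spec))
}

simulate_genome_impl <- function(spec) {
  mean_ig <- max(36, spec$mean_gene_len * (1 - spec$gene_fraction) /
                   spec$gene_fraction)
  planted <- c(
    purrr::map(spec$array_specs, make_array_segment),
    if (!is.null(spec$cas_labels)) {
      list(make_cas_segment(spec$cas_labels, spec$code_id,
                            spec$tga_gly_fraction))
    }
  )
  planted_len <- sum(purrr::map_int(planted, ~ nchar(.x$seq)))
  core_target <- spec$length - planted_len
  if (core_target < 2L * (spec$mean_gene_len + mean_ig)) {
    abort("genome too short to fit the planted elements",
          class = "phagecode_capacity_error")
  }
  units <- list()
  total <- 0L
  while (total < core_target) {
    u <- make_unit(spec, mean_ig)
    units <- c(units, list(u))
    total <- total + nchar(u$seq)
  }
  # splice planted segments between gene units (never inside a gene)
  segs <- units
  if (length(planted) > 0L) {
    slots <- sort(sample.int(length(units) - 1L, length(planted)))
    for (idx in rev(seq_along(planted))) {
      at <- slots[idx]
      segs <- append(segs, planted[idx], after = at)
    }
  }
  seq_str <- paste(purrr::map_chr(segs, "seq"), collapse = "")
  offsets <- cumsum(c(0L, purrr::map_int(segs, ~ nchar(.x$seq))))
  genes <- list(); arrays <- list(); cas <- list()
  for (i in seq_along(segs)) {
    sg <- segs[[i]]
    off <- offsets[i]
    U <- nchar(sg$seq)
    if (sg$type == "unit") {
      gs <- if (sg$strand == "+") off else off + U - sg$gene_len
      genes[[length(genes) + 1L]] <- tibble(
        start = gs, end = gs + sg$gene_len, strand = sg$strand,
        code_id = spec$code_id, backup_offset = sg$backup_offset,
        backup_codon = sg$backup_codon
      )
    } else if (sg$type == "array") {
      arrays[[length(arrays) + 1L]] <- tibble(
        start = off, end = off + U,
        repeat_seq = sg$repeat_seq,
        repeat_starts = list(off + sg$repeat_starts),
        spacer_starts = list(off + sg$spacer_starts),
        spacers = list(sg$spacers)
      )
    } else {
      cas[[length(cas) + 1L]] <- tibble(
        start = off + sg$gene_starts, end = off + sg$gene_starts + sg$gene_lens,
        strand = "+", label = sg$labels
      )
    }
  }
  truth <- list(
    genome_id = spec$genome_id, code_id = spec$code_id,
    length = nchar(seq_str), tga_gly_fraction = spec$tga_gly_fraction,
    genes = bind_rows(genes),
    arrays = if (length(arrays)) bind_rows(arrays) else NULL,
    cas = if (length(cas)) bind_rows(cas) else NULL
  )
  list(seq = tibble(seq_id = spec$genome_id, seq = seq_str), truth = truth)
}

#' Plant protospacers into a set of synthetic phage genomes
#'
#' Generates one genome per phage spec (no arrays or cas operons) and
#' plants protospacer copies of the scheduled spacers at random non-genic
#' positions. Mismatches are injected at interior spacer positions (inside
#' every admissible matching window), so the scheduled mismatch count is
#' the effective Hamming distance at any coverage-compliant alignment.
#'
#' @param specs List of [genome_spec()] objects, one per phage.
#' @param schedule Tibble with columns `phage_id`, `spacer` (sequence to
#'   plant), `n_mismatch` (0 = exact copy) and optionally `strand`
#'   (`"+"`/`"-"`, random when absent). Phages absent from the schedule are
#'   decoys.
#' @param min_coverage Matching coverage the mismatch placement must defeat
#'   (default 0.95, kept in sync with [match_spacer()]).
#' @return A list with `seqs` (tibble of phage sequences), `truth`
#'   (per-phage genome truths) and `planted` (tibble of planted
#'   protospacers: `phage_id`, `spacer`, `planted_seq`, `start`, `end`,
#'   `strand`, `n_mismatch`).
#' @export
simulate_phage_set <- function(specs, schedule = NULL, min_coverage = 0.95) {
  sims <- purrr::map(specs, simulate_genome)
  seqs <- bind_rows(purrr::map(sims, "seq"))
  truths <- purrr::map(sims, "truth")
  names(truths) <- seqs$seq_id
  planted <- tibble(
    phage_id = character(0), spacer = character(0),
    planted_seq = character(0), start = integer(0), end = integer(0),
    strand = character(0), n_mismatch = integer(0)
  )
  if (!is.null(schedule) && nrow(schedule) > 0L) {
    if (!all(schedule$phage_id %in% seqs$seq_id)) {
      abort("schedule references unknown phage_id",
            class = "phagecode_reference_error")
    }
    seed0 <- (specs[[1L]]$seed + 7919L) %% 2147483647L
    planted <- withr::with_seed(seed0, plant_all(seqs, truths, schedule,
                                                 min_coverage))
    for (i in seq_len(nrow(planted))) {
      r <- planted[i, ]
      j <- match(r$phage_id, seqs$seq_id)
      s <- seqs$seq[j]
      substr(s, r$start + 1L, r$end) <- r$planted_seq
      seqs$seq[j] <- s
    }
  }
  list(seqs = seqs, truth = truths, planted = planted)
}

plant_all <- function(seqs, truths, schedule, min_coverage) {
  used <- purrr::map(seqs$seq_id, ~ tibble(start = integer(0),
                                           end = integer(0)))
  names(used) <- seqs$seq_id
  rows <- purrr::pmap(
    list(schedule$phage_id, schedule$spacer, schedule$n_mismatch,
         if ("strand" %in% names(schedule)) schedule$strand else
           rep(NA_character_, nrow(schedule))),
    function(pid, spacer, n_mm, strand) {
      spacer <- str_to_upper(spacer)
      L <- nchar(spacer)
      if (is.na(strand)) strand <- sample(c("+", "-"), 1L)
      proto <- inject_mismatches(spacer, n_mm, min_coverage)
      if (strand == "-") proto <- revcomp(proto)
      genes <- truths[[pid]]$genes
      glen <- nchar(seqs$seq[seqs$seq_id == pid])
      blocked <- bind_rows(genes[, c("start", "end")], used[[pid]])
      slot <- pick_gap(glen, blocked, L)
      used[[pid]] <<- bind_rows(used[[pid]],
                                tibble(start = slot, end = slot + L))
      tibble(phage_id = pid, spacer = spacer, planted_seq = proto,
             start = slot, end = slot + L, strand = strand,
             n_mismatch = as.integer(n_mm))
    }
  )
  bind_rows(rows)
}

# Substitutions at interior positions shared by every admissible
# end-anchored window of length >= ceiling(min_coverage * L).
inject_mismatches <- function(spacer, n_mm, min_coverage) {
  if (n_mm == 0L) return(spacer)
  L <- nchar(spacer)
  lmin <- as.integer(ceiling(min_coverage * L))
  lo <- L - lmin + 1L + 1L
  hi <- lmin - 1L
  pos <- sample(seq.int(lo, hi), n_mm)
  ch <- seq_chars(spacer)
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

# A random start inside a non-genic, non-used gap wide enough for len.
pick_gap <- function(glen, blocked, len) {
  ir <- IRanges::IRanges(start = blocked$start + 1L, end = blocked$end)
  gaps <- IRanges::gaps(IRanges::reduce(ir), start = 1L, end = glen)
  gaps <- gaps[IRanges::width(gaps) >= len + 2L]
  if (length(gaps) == 0L) {
    abort("no non-genic gap wide enough for protospacer",
          class = "phagecode_capacity_error")
  }
  g <- gaps[sample.int(length(gaps), 1L)]
  s1 <- IRanges::start(g) + sample.int(IRanges::width(g) - len + 1L, 1L) - 1L
  s1 - 1L  # 0-based
}
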