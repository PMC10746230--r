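# Independent brute-force oracles. These deliberately share no code with
# the package internals: stop scanning is a plain codon-by-codon walk, ORF
# enumeration walks forward from every start codon and keeps the maximal
# candidate per terminus, density rasterises ORFs onto a per-base mask, and
# spacer matching enumerates every window/offset with an outer-product
# mismatch count.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(toupper(s), "")[[1]]])), collapse = "")
}

oracle_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# stop codon start positions, forward coordinates, one frame/strand
oracle_stops <- function(seq, code_id, frame, strand) {
  stops <- if (code_id == 11) c("TAA", "TAG", "TGA") else c("TAA", "TAG")
  s <- toupper(seq)
  if (strand == "-") s <- oracle_revcomp(s)
  L <- nchar(s)
  out <- integer(0)
  p <- frame + 1
  while (p + 2 <= L) {
    if (substr(s, p, p + 2) %in% stops) {
      fwd <- if (strand == "+") p - 1 else L - (p - 1) - 3
      out <- c(out, fwd)
    }
    p <- p + 3
  }
  sort(out)
}

# Maximal ORFs by exhaustive start-walks: from every start codon walk to
# the terminating event (stop codon, broken codon, or edge); the maximal
# ORF for a terminus is the candidate with the smallest start.
oracle_orfs <- function(seq, code_id, min_orf_len) {
  stops <- if (code_id == 11) c("TAA", "TAG", "TGA") else c("TAA", "TAG")
  starts <- c("ATG", "GTG", "TTG")
  res <- list()
  for (strand in c("+", "-")) {
    s <- toupper(seq)
    if (strand == "-") s <- oracle_revcomp(s)
    L <- nchar(s)
    for (frame in 0:2) {
      cand <- list()
      p <- frame + 1
      while (p + 2 <= L) {
        if (substr(s, p, p + 2) %in% starts) {
          q <- p
          terminal <- FALSE
          end_q <- NA
          while (q + 2 <= L) {
            cod <- substr(s, q, q + 2)
            if (grepl("[^ACGT]", cod)) { end_q <- q - 3; break }
            if (cod %in% stops) { end_q <- q; terminal <- TRUE; break }
            q <- q + 3
          }
          if (is.na(end_q)) end_q <- q - 3  # ran off the edge
          if (end_q >= p) {
            cand[[length(cand) + 1]] <-
              data.frame(from = p, to = end_q + 2, terminal = terminal)
          }
        }
        p <- p + 3
      }
      if (length(cand) > 0) {
        cand <- do.call(rbind, cand)
        for (to in unique(cand$to)) {
          sub <- cand[cand$to == to, ]
          from <- min(sub$from)
          len <- to - from + 1
          if (len >= min_orf_len) {
            if (strand == "+") {
              st0 <- from - 1; en0 <- to
            } else {
              st0 <- L - to; en0 <- L - (from - 1)
            }
            res[[length(res) + 1]] <- data.frame(
              start = st0, end = en0, strand = strand, frame = frame,
              has_terminal_stop = sub$terminal[1]
            )
          }
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      has_terminal_stop = logical(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$strand, out$frame), , drop = FALSE]
}

# per-base mask density from oracle ORFs
oracle_density <- function(seq, code_id, min_orf_len) {
  o <- oracle_orfs(seq, code_id, min_orf_len)
  mask <- logical(nchar(seq))
  for (i in seq_len(nrow(o))) {
    mask[(o$start[i] + 1):o$end[i]] <- TRUE
  }
  sum(mask) / nchar(seq)
}

# exhaustive ungapped spacer matching with end-anchored truncations,
# merged per overlap cluster by (mismatches, -matched_len, start)
oracle_match <- function(spacer, target, min_coverage = 0.95,
                         max_mismatch = 1) {
  tch <- strsplit(toupper(target), "")[[1]]
  n <- length(tch)
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") toupper(spacer) else oracle_revcomp(spacer)
    L <- nchar(pat)
    lmin <- ceiling(min_coverage * L)
    for (Lp in lmin:L) {
      wins <- unique(c(substr(pat, 1, Lp), substr(pat, L - Lp + 1, L)))
      for (w in wins) {
        if (n < Lp) next
        wch <- strsplit(w, "")[[1]]
        noff <- n - Lp + 1
        mat <- matrix(tch[outer(seq_len(noff) - 1, seq_len(Lp), "+")],
                      nrow = noff)
        mm <- rowSums(mat != matrix(wch, nrow = noff, ncol = Lp,
                                    byrow = TRUE))
        hit <- which(mm <= max_mismatch)
        for (h in hit) {
          rows[[length(rows) + 1]] <- data.frame(
            start = h - 1, end = h - 1 + Lp, strand = strand,
            matched_len = Lp, mismatches = mm[h]
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), matched_len = integer(0),
                      mismatches = integer(0)))
  }
  all <- do.call(rbind, rows)
  out <- list()
  for (strand in unique(all$strand)) {
    h <- all[all$strand == strand, ]
    h <- h[order(h$start, h$end), ]
    cl <- integer(nrow(h))
    cur <- 1; cl[1] <- 1; reach <- h$end[1]
    for (i in seq_len(nrow(h))[-1]) {
      if (h$start[i] < reach) {
        cl[i] <- cur
        reach <- max(reach, h$end[i])
      } else {
        cur <- cur + 1; cl[i] <- cur; reach <- h$end[i]
      }
    }
    for (g in unique(cl)) {
      sub <- h[cl == g, ]
      sub <- sub[order(sub$mismatches, -sub$matched_len, sub$start), ]
      out[[length(out) + 1]] <- sub[1, ]
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

# hand-written subtype truth table oracle (independent conditionals)
oracle_cas <- function(labels, has_array) {
  if (!has_array) return("incomplete")
  has <- function(g) g %in% labels
  out <- character(0)
  if (has("cas9") && has("csn2") && has("cas1") && has("cas2")) {
    out <- c(out, "II-A")
  }
  if (has("cas9") && has("cas1") && has("cas2") && !has("csn2")) {
    out <- c(out, "II-C1")
  }
  if (has("cpf1") && has("cas1") && has("cas4") && has("cas2")) {
    out <- c(out, "V-A")
  }
  if (has("cas10") && has("cas7") && has("cas5") && has("csm2")) {
    out <- c(out, "III-A")
  }
  if (has("cas10") && has("cas7") && has("cas5") && has("cmr5")) {
    out <- c(out, "III-B")
  }
  if (length(out) == 0) "incomplete" else out
}

# compare package ORF table with oracle data frame
expect_orfs_equal <- function(got, want) {
  g <- as.data.frame(got[, c("start", "end", "strand", "frame",
                             "has_terminal_stop")])
  g <- g[order(g$start, g$strand, g$frame), , drop = FALSE]
  w <- want[order(want$start, want$strand, want$frame), , drop = FALSE]
  rownames(g) <- rownames(w) <- NULL
  expect_equal(g, w)
}

# cached synthetic world + pipeline run shared across test files
world_cache <- new.env(parent = emptyenv())

cached_world <- function() {
  if (is.null(world_cache$world)) {
    world_cache$world <- simulate_world(20260928 %% 99991)
  }
  world_cache$world
}

cached_run <- function() {
  if (is.null(world_cache$run)) {
    w <- cached_world()
    world_cache$run <- run_pipeline(
      pipeline_config(seed = 1), genomes = w$genomes, phages = w$phages,
      cas_annotations = w$cas_annotations, host_map = w$host_map
    )
  }
  world_cache$run
}
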