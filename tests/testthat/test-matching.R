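plant_in <- function(spacer, target_len, at, strand = "+", n_mm = 0) {
  set_chars <- strsplit(toupper(spacer), "")[[1]]
  if (n_mm > 0) {
    L <- length(set_chars)
    pos <- sample(seq(3, L - 2), n_mm)
    for (p in pos) {
      set_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), set_chars[p]), 1)
    }
  }
  proto <- paste(set_chars, collapse = "")
  if (strand == "-") proto <- oracle_revcomp(proto)
  t <- oracle_random_dna(target_len)
  paste0(substr(t, 1, at), proto, substr(t, at + nchar(proto) + 1, target_len))
}

test_that("an exactly planted spacer gives one full-coverage hit", {
  set.seed(430)
  sp <- oracle_random_dna(30)
  tg <- plant_in(sp, 300, 100)
  h <- match_spacer(sp, tg)
  expect_identical(nrow(h), 1L)
  expect_identical(h$mismatches, 0L)
  expect_identical(h$coverage, 1)
  expect_identical(c(h$start, h$end), c(100L, 130L))
})

test_that("two interior substitutions defeat the match", {
  set.seed(431)
  for (i in 1:20) {
    sp <- oracle_random_dna(sample(26:40, 1))
    tg <- plant_in(sp, 300, 120, n_mm = 2)
    expect_identical(nrow(match_spacer(sp, tg)), 0L)
  }
})

test_that("hits equal the exhaustive enumeration oracle", {
  set.seed(432)
  for (i in 1:120) {
    sp <- oracle_random_dna(sample(20:36, 1))
    scenario <- i %% 3
    tg <- if (scenario == 0) {
      oracle_random_dna(200)
    } else {
      plant_in(sp, 200, sample(20:150, 1),
               strand = sample(c("+", "-"), 1), n_mm = scenario - 1)
    }
    got <- as.data.frame(match_spacer(
      sp, tg))[, c("start", "end", "strand", "matched_len", "mismatches")]
    want <- oracle_match(sp, tg)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("case", i))
  }
})

test_that("matching is strand-symmetric", {
  set.seed(433)
  for (i in 1:20) {
    sp <- oracle_random_dna(30)
    tg <- plant_in(sp, 250, 90, strand = sample(c("+", "-"), 1),
                   n_mm = sample(0:1, 1))
    a <- match_spacer(sp, tg)
    b <- match_spacer(revcomp(sp), tg)
    b$strand <- ifelse(b$strand == "+", "-", "+")
    b <- b[order(b$start, b$strand), ]
    expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
  }
})

test_that("planted protospacers are recovered iff within thresholds", {
  set.seed(434)
  n_trials <- 500
  ok <- TRUE
  for (i in seq_len(n_trials)) {
    sp <- oracle_random_dna(sample(26:40, 1))
    n_mm <- sample(0:2, 1)
    tg <- plant_in(sp, 300, sample(30:200, 1),
                   strand = sample(c("+", "-"), 1), n_mm = n_mm)
    n_hits <- nrow(match_spacer(sp, tg))
    ok <- ok && if (n_mm <= 1) n_hits >= 1 else n_hits == 0
  }
  expect_true(ok)
})

test_that("relaxing thresholds never removes a hit", {
  set.seed(435)
  for (i in 1:25) {
    sp <- oracle_random_dna(30)
    tg <- plant_in(sp, 250, 80, n_mm = sample(0:1, 1))
    strict <- match_spacer(sp, tg, min_coverage = 0.95, max_mismatch = 1)
    loose_mm <- match_spacer(sp, tg, min_coverage = 0.95, max_mismatch = 2)
    loose_cov <- match_spacer(sp, tg, min_coverage = 0.90, max_mismatch = 1)
    covered <- function(h, by) {
      all(vapply(seq_len(nrow(h)), function(j) {
        any(by$strand == h$strand[j] & by$start < h$end[j] &
              by$end > h$start[j])
      }, logical(1)))
    }
    expect_true(covered(strict, loose_mm))
    expect_true(covered(strict, loose_cov))
  }
})

test_that("random spacers essentially never hit random targets", {
  set.seed(436)
  hits <- 0
  for (i in 1:40) {
    sp <- oracle_random_dna(30)
    tg <- oracle_random_dna(50000)
    hits <- hits + nrow(match_spacer(sp, tg))
  }
  expect_identical(hits, 0)
})

test_that("full-length hits agree with Biostrings matchPattern", {
  set.seed(437)
  for (i in 1:10) {
    sp <- oracle_random_dna(30)
    tg <- plant_in(sp, 400, 150, n_mm = sample(0:1, 1))
    ours <- match_spacer(sp, tg)
    ours <- ours[ours$strand == "+" & ours$matched_len == 30, ]
    ref <- Biostrings::matchPattern(sp, Biostrings::DNAString(tg),
                                    max.mismatch = 1)
    expect_true(all(ours$start %in% (Biostrings::start(ref) - 1)))
  }
})

test_that("short spacers are rejected or warned about", {
  expect_error(match_spacer("ACGTACGTACGTAC", oracle_random_dna(100)),
               class = "phagecode_short_spacer")
  set.seed(438)
  expect_warning(match_spacer(oracle_random_dna(16), oracle_random_dna(100)),
                 "unusually short")
})

test_that("host links aggregate hits per target with host groups", {
  set.seed(439)
  sp <- oracle_random_dna(30)
  db <- tibble::tibble(
    spacer_id = "s1", seq_id = "G1", array_index = 1L, position_index = 1L,
    spacer = sp, host_group = "Gracilibacteria"
  )
  targets <- tibble::tibble(
    seq_id = c("p1", "p2", "p3"),
    seq = c(plant_in(sp, 400, 100), oracle_random_dna(400),
            oracle_random_dna(400))
  )
  res <- link_hosts(db, targets)
  expect_identical(res$links$target_id, "p1")
  expect_identical(res$links$host_groups[[1]], "Gracilibacteria")
  empty <- link_hosts(db[0, ], targets)
  expect_identical(nrow(empty$hits), 0L)
  expect_identical(nrow(empty$links), 0L)
})

test_that("co-targeting requires an SGA and a non-SGA group", {
  links <- tibble::tibble(
    target_id = c("pA", "pB", "pC"),
    n_hits = c(2L, 3L, 2L),
    n_spacers = c(2L, 3L, 2L),
    host_groups = list(
      c("Gracilibacteria", "Firmicutes"),
      c("Saccharibacteria", "Saccharibacteria", "Saccharibacteria"),
      c("Absconditabacteria", "Actinobacteria")
    )
  )
  cot <- find_cotargeted(links)
  expect_setequal(cot$target_id, c("pA", "pC"))
  expect_identical(cot$non_sga_groups[[1]], "Firmicutes")
})

test_that("spacer sharing detects identity in both orientations", {
  set.seed(440)
  a <- c(oracle_random_dna(30), oracle_random_dna(31), oracle_random_dna(32))
  b <- c(oracle_random_dna(30), a[2], oracle_revcomp(a[3]))
  expect_identical(nrow(shared_spacers(a[1], b[1])), 0L)
  sh <- shared_spacers(a, b)
  expect_identical(nrow(sh), 2L)
  expect_identical(sh$orientation[sh$spacer == a[2]], "forward")
  expect_identical(sh$orientation[sh$spacer == a[3]], "reverse_complement")
})
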