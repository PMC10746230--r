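# build a repeat/spacer locus by hand: repeats interleaved with spacers
make_locus <- function(rep_seq, spacers) {
  pieces <- character(2 * length(spacers) + 1)
  pieces[seq(1, length(pieces), 2)] <- rep_seq
  pieces[seq(2, length(pieces), 2)] <- spacers
  paste(pieces, collapse = "")
}

test_that("planted arrays are recovered with byte-identical spacers", {
  for (seed in c(11, 57)) {
    g <- simulate_genome(genome_spec(
      "ag", 21000, code_id = 11,
      array_specs = list(list(n_spacers = 5)), seed = seed
    ))
    arr <- detect_arrays(g$seq)
    expect_identical(nrow(arr), 1L)
    truth <- g$truth$arrays
    expect_identical(arr$spacers[[1]]$seq, truth$spacers[[1]])
    expect_identical(arr$spacers[[1]]$start, truth$spacer_starts[[1]])
    expect_identical(arr$consensus_repeat, truth$repeat_seq)
    expect_identical(arr$evidence, "high")
    expect_identical(arr$n_repeats, 6L)
  }
})

test_that("random sequence without repeat structure yields no arrays", {
  set.seed(420)
  s <- oracle_random_dna(10000)
  expect_identical(nrow(detect_arrays(s)), 0L)
})

test_that("an array with a single spacer falls below the detection floor", {
  set.seed(421)
  locus <- make_locus(oracle_random_dna(30),
                      list(oracle_random_dna(32))[[1]])
  s <- paste0(oracle_random_dna(400), locus, oracle_random_dna(400))
  expect_identical(nrow(detect_arrays(s)), 0L)
})

test_that("near-identical spacers demote an array to low evidence", {
  set.seed(422)
  rep_seq <- oracle_random_dna(30)
  base <- oracle_random_dna(30)
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  # interior mutations only, so boundary columns stay non-unanimous-safe
  spacers <- c(base,
               mutate_at(base, c(5, 9, 14)),
               mutate_at(base, c(7, 12, 18)),
               mutate_at(base, c(4, 16, 22)))
  spacers[1] <- mutate_at(spacers[1], 1)    # break first-column unanimity
  spacers[2] <- mutate_at(spacers[2], 30)   # break last-column unanimity
  s <- paste0(oracle_random_dna(300), make_locus(rep_seq, spacers),
              oracle_random_dna(300))
  arr <- detect_arrays(s)
  expect_identical(nrow(arr), 1L)
  expect_identical(arr$evidence, "low")
  expect_gte(arr$max_spacer_pair_identity, 0.60)
  expect_identical(nrow(extract_spacers(arr, only_high = TRUE)), 0L)
  expect_identical(nrow(extract_spacers(arr, only_high = FALSE)), 4L)
})

test_that("detection is invariant to the flanking background", {
  seg <- withr::with_seed(423, phagecode:::make_array_segment(
    list(n_spacers = 5, repeat_len = 30)
  ))
  set.seed(424)
  decomp <- lapply(1:4, function(i) {
    lead <- oracle_random_dna(sample(300:900, 1))
    s <- paste0(lead, seg$seq, oracle_random_dna(400))
    arr <- detect_arrays(s)
    expect_identical(nrow(arr), 1L)
    list(spacers = arr$spacers[[1]]$seq,
         rel_repeat_starts = arr$repeats[[1]]$start - nchar(lead),
         consensus = arr$consensus_repeat)
  })
  for (d in decomp[-1]) expect_identical(d, decomp[[1]])
  expect_identical(decomp[[1]]$spacers, seg$spacers)
})

test_that("repeat and spacer intervals never overlap within an array", {
  g <- simulate_genome(genome_spec(
    "ov", 24000, code_id = 25,
    array_specs = list(list(n_spacers = 5), list(n_spacers = 4)), seed = 88
  ))
  arr <- detect_arrays(g$seq)
  expect_identical(nrow(arr), 2L)
  for (i in seq_len(nrow(arr))) {
    iv <- rbind(
      data.frame(s = arr$repeats[[i]]$start,
                 e = arr$repeats[[i]]$start + nchar(arr$repeats[[i]]$seq)),
      data.frame(s = arr$spacers[[i]]$start,
                 e = arr$spacers[[i]]$start + nchar(arr$spacers[[i]]$seq))
    )
    iv <- iv[order(iv$s), ]
    expect_true(all(iv$s[-1] >= iv$e[-nrow(iv)]))
    expect_identical(nrow(arr$repeats[[i]]), nrow(arr$spacers[[i]]) + 1L)
  }
})

test_that("spacer extraction dereplicates by exact sequence", {
  set.seed(425)
  shared <- oracle_random_dna(32)
  locus1 <- make_locus(oracle_random_dna(30),
                       c(shared, oracle_random_dna(30), oracle_random_dna(34),
                         oracle_random_dna(28)))
  locus2 <- make_locus(oracle_random_dna(30),
                       c(oracle_random_dna(29), shared, oracle_random_dna(33),
                         oracle_random_dna(31)))
  seqs <- tibble::tibble(
    seq_id = c("gA", "gB"),
    seq = c(paste0(oracle_random_dna(300), locus1, oracle_random_dna(300)),
            paste0(oracle_random_dna(300), locus2, oracle_random_dna(300)))
  )
  arr <- detect_arrays(seqs)
  expect_identical(nrow(arr), 2L)
  db <- extract_spacers(arr)
  expect_identical(nrow(db), 7L)               # 8 planted, 1 duplicate
  expect_identical(sum(db$spacer == shared), 1L)
  expect_false(anyDuplicated(db$spacer) > 0)
})

test_that("external spacers merge with precedence for existing entries", {
  db <- extract_spacers(detect_arrays(paste0(strrep("AC", 150))))
  expect_identical(nrow(db), 0L)
  set.seed(426)
  a <- toupper(oracle_random_dna(30))
  b <- toupper(oracle_random_dna(31))
  db <- import_spacers(db, tibble::tibble(spacer_id = c("x1", "x2"),
                                          spacer = c(a, b)))
  expect_identical(nrow(db), 2L)
  db2 <- import_spacers(db, tibble::tibble(spacer_id = c("y1", "y2"),
                                           spacer = c(a, oracle_random_dna(33))))
  expect_identical(nrow(db2), 3L)
  expect_identical(db2$spacer_id[db2$spacer == a], "x1")
})
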