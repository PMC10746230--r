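test_that("a sequence without start codons yields no ORFs", {
  s <- strrep("CCC", 40)
  expect_identical(nrow(find_orfs(s, 11, 90)), 0L)
  expect_error(find_orfs("", 11), class = "phagecode_empty_input")
})

test_that("a reassigned TGA extends the ORF under code 25 and is recorded", {
  s <- "ATGAAATGATAA"
  o11 <- find_orfs(s, 11, min_orf_len = 6)
  o25 <- find_orfs(s, 25, min_orf_len = 6)
  f11 <- o11[o11$frame == 0 & o11$strand == "+", ]
  f25 <- o25[o25$frame == 0 & o25$strand == "+", ]
  expect_identical(c(f11$start, f11$end), c(0L, 9L))    # stops at TGA
  expect_identical(c(f25$start, f25$end), c(0L, 12L))   # reads through
  expect_identical(f25$inframe_tga[[1]], 6L)
  expect_identical(f11$n_inframe_tga, 0L)
})

test_that("ORF calls equal the exhaustive start-walk oracle", {
  set.seed(410)
  for (i in 1:12) {
    s <- oracle_random_dna(2000)
    for (code_id in c(11, 25)) {
      got <- find_orfs(s, code_id, min_orf_len = 90)
      expect_orfs_equal(got, oracle_orfs(s, code_id, 90))
    }
  }
})

test_that("N-containing codons break ORFs without a terminal stop", {
  # 63 sense codons, then N codon, inside a long frame-0 context
  s <- paste0("ATG", strrep("GCA", 40), "NNN", strrep("GCA", 10), "TAA")
  o <- find_orfs(s, 11, min_orf_len = 30)
  first <- o[o$start == 0, ]
  expect_identical(first$end, 123L)  # ends before the N codon
  expect_false(first$has_terminal_stop)
  expect_orfs_equal(find_orfs(s, 11, 30), oracle_orfs(s, 11, 30))
})

test_that("reverse-complement symmetry: strands swap and coordinates mirror", {
  set.seed(411)
  for (i in 1:8) {
    s <- oracle_random_dna(1200)
    L <- nchar(s)
    a <- find_orfs(s, 25, 90)
    b <- find_orfs(revcomp(s), 25, 90)
    mirrored <- data.frame(
      start = L - b$end, end = L - b$start,
      strand = ifelse(b$strand == "+", "-", "+"), frame = b$frame,
      has_terminal_stop = b$has_terminal_stop
    )
    expect_orfs_equal(a, mirrored[order(mirrored$start, mirrored$strand,
                                        mirrored$frame), ])
  }
})

test_that("every code-11 ORF nests inside exactly one code-25 ORF", {
  set.seed(412)
  for (i in 1:8) {
    s <- oracle_random_dna(1500)
    o11 <- find_orfs(s, 11, 90)
    o25 <- find_orfs(s, 25, 90)
    for (j in seq_len(nrow(o11))) {
      host <- o25[o25$strand == o11$strand[j] & o25$frame == o11$frame[j] &
                    o25$start <= o11$start[j] & o25$end >= o11$end[j], ]
      expect_identical(nrow(host), 1L)
    }
  }
})

test_that("coding density equals the per-base mask oracle", {
  expect_identical(coding_density(strrep("C", 300), 11, 90)$density, 0)
  full <- paste0("ATG", strrep("GCT", 30), "TAA")
  expect_identical(coding_density(full, 11, nchar(full))$density, 1)
  set.seed(413)
  for (i in 1:6) {
    s <- oracle_random_dna(2000)
    for (code_id in c(11, 25)) {
      expect_equal(coding_density(s, code_id, 90)$density,
                   oracle_density(s, code_id, 90))
    }
  }
  g <- simulate_genome(genome_spec("dg", 21000, code_id = 25, seed = 77))
  expect_equal(coding_density(g$seq, 25, 300)$density,
               oracle_density(g$seq$seq, 25, 300))
})

test_that("density never decreases when TGA becomes a sense codon", {
  set.seed(414)
  for (i in 1:100) {
    s <- oracle_random_dna(sample(300:900, 1))
    d11 <- coding_density(s, 11, 90)$density
    d25 <- coding_density(s, 25, 90)$density
    expect_gte(d25, d11)
  }
})

test_that("code profiling separates planted codes and respects the size floor", {
  p25 <- profile_code(simulate_genome(
    genome_spec("p25", 22000, code_id = 25, seed = 501))$seq)
  p11 <- profile_code(simulate_genome(
    genome_spec("p11", 22000, code_id = 11, seed = 502))$seq)
  expect_identical(p25$call, "code25")
  expect_gte(p25$delta, 10)
  expect_identical(p11$call, "code11_compatible")
  expect_lt(abs(p11$delta), 10)
  set.seed(503)
  small <- oracle_random_dna(15000)
  expect_identical(profile_code(small)$call, "not_evaluated")
  expect_true(all(p25$d11 <= p25$d25, p11$d11 <= p11$d25))
})

test_that("planted genes are recovered by the caller under their own code", {
  for (code_id in c(11, 25)) {
    g <- simulate_genome(genome_spec(paste0("sens", code_id), 21000,
                                     code_id = code_id, seed = 600 + code_id))
    orfs <- find_orfs(g$seq, code_id, 90)
    mask <- logical(nchar(g$seq$seq))
    for (j in seq_len(nrow(orfs))) mask[(orfs$start[j] + 1):orfs$end[j]] <- TRUE
    genes <- g$truth$genes
    gene_bases <- sum(genes$end - genes$start)
    covered <- sum(vapply(seq_len(nrow(genes)), function(j) {
      sum(mask[(genes$start[j] + 1):genes$end[j]])
    }, numeric(1)))
    expect_gte(covered / gene_bases, 0.95)
  }
})

test_that("terminus reports find backup stops and code-11-viable ends", {
  # frame-0 gene ending TGA, then one filler codon, then TAG backup
  s <- paste0("ATG", strrep("GCT", 30), "TGA", "CAC", "TAG", strrep("C", 20))
  orfs <- find_orfs(s, 25, min_orf_len = 90)
  # under code 25 the ORF reads through the TGA to the TAG
  expect_identical(max(orfs$end), 102L)
  # force the TGA terminus by analysing the code-11 call under a code-25 label
  o11 <- find_orfs(s, 11, min_orf_len = 90)
  o11$code_id <- 25L
  rep1 <- analyze_termini(s, o11[o11$start == 0, ], window = 10)
  expect_identical(rep1$terminal_stop, "TGA")
  expect_identical(rep1$backup_stops[[1]]$codon, "TAG")
  expect_identical(rep1$backup_stops[[1]]$offset, 2L)
  expect_true(rep1$code11_viable_terminus)
  expect_true(rep1$code11_translatable)

  # TAA terminus is viable by itself, also on the minus strand
  gene <- paste0("ATG", strrep("GGT", 31), "TAA")
  s2 <- paste0(strrep("C", 30), revcomp(gene), strrep("C", 30))
  o2 <- find_orfs(s2, 25, min_orf_len = 90)
  o2 <- o2[o2$strand == "-" & o2$start == 30, ]
  expect_identical(nrow(o2), 1L)
  rep2 <- analyze_termini(s2, o2, window = 10)
  expect_identical(rep2$terminal_stop, "TAA")
  expect_true(rep2$code11_viable_terminus)

  # TGA terminus with no TAA/TAG in reach is not code-11 viable
  s3 <- paste0("ATG", strrep("GCT", 30), "TGA", strrep("CAC", 12))
  o3 <- find_orfs(s3, 11, min_orf_len = 90)
  o3$code_id <- 25L
  rep3 <- analyze_termini(s3, o3[o3$start == 0, ], window = 10)
  expect_identical(rep3$terminal_stop, "TGA")
  expect_false(rep3$code11_viable_terminus)

  # out-of-range coordinates are refused
  bad <- o3[o3$start == 0, ]
  bad$end <- nchar(s3) + 30L
  expect_error(analyze_termini(s3, bad), class = "phagecode_coord_error")
})
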