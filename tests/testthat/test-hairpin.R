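test_that("candidate windows are excised with correct arithmetic, clipping and strand", {
  genome <- c(chr1 = random_dna(1, 2000))
  locus <- data.frame(chrom = "chr1", start = 500, end = 522, strand = "+",
                      stringsAsFactors = FALSE)
  w <- excise_candidates(locus, genome, flank = 150)
  expect_true(any(w$start == 350 & w$end == 672))
  expect_identical(w$sequence[1], unname(substr(genome, 351, 672)))

  near0 <- data.frame(chrom = "chr1", start = 10, end = 32, strand = "+")
  w0 <- excise_candidates(near0, genome, flank = 150)
  expect_true(all(w0$start >= 0))

  minus <- data.frame(chrom = "chr1", start = 500, end = 522, strand = "-")
  wm <- excise_candidates(minus, genome, flank = 150)
  expect_identical(wm$sequence[1],
                   unname(revcomp_chr(substr(genome, 351, 672))))

  bad <- data.frame(chrom = "chr1", start = 1990, end = 2012, strand = "+")
  expect_error(excise_candidates(bad, genome), "bounds")
})

test_that("planted precursors are accepted under both folding engines", {
  fx <- sim_fixture()
  pr <- fx$bundle$precursors
  for (eng in c("nussinov", if (protomir:::has_vienna()) "vienna")) {
    ok <- vapply(seq_len(nrow(pr)), function(i)
      evaluate_hairpin(pr$sequence[i], pr$mature[i], 100,
                       engine = eng)$accepted, NA)
    expect_gte(mean(ok), 0.9)
  }
})

test_that("a mature read spanning the terminal loop is rejected for the arm criterion", {
  # symmetric hairpin: loop-spanning read pairs with itself
  stem <- "GCATGCAAGGCTACGGATCC"
  hp <- paste0(stem, "GAAAAC", revcomp_chr(stem))
  mature <- substr(hp, 14, 34)  # covers the loop
  ev <- evaluate_hairpin(hp, mature, 100, engine = "nussinov")
  expect_false(ev$accepted)
  expect_identical(ev$reason, "arm")
})

test_that("a perfect inverted repeat gives a zero-mismatch duplex", {
  arm <- "ACGGATCCGTAGCCTTGCATGC"  # 22 nt
  hp <- paste0(arm, "CAAAAG", revcomp_chr(arm))
  ev <- evaluate_hairpin(hp, arm, 50, engine = "nussinov")
  expect_equal(ev$duplex_mismatches, 0)
  expect_true(ev$accepted)
  expect_identical(ev$arm, "5p")
})

test_that("rejection reports the first failing criterion in order", {
  arm <- "ACGGATCCGTAGCCTTGCATGC"
  hp <- paste0(arm, "CAAAAG", revcomp_chr(arm))
  # low expression: everything else passes, so the reason is 'reads'
  ev <- evaluate_hairpin(hp, arm, 2, engine = "nussinov", min_reads = 5)
  expect_false(ev$accepted)
  expect_identical(ev$reason, "reads")
  # an 18-nt mature fails the length criterion before the read criterion
  arm18 <- substr(arm, 1, 18)
  hp18 <- paste0(arm18, "CAAAAG", revcomp_chr(arm18))
  ev18 <- evaluate_hairpin(hp18, arm18, 2, engine = "nussinov")
  expect_identical(ev18$reason, "length")
  # unstable fold fails on energy before either
  weak <- paste0("ACGGATCCGTAGCCTTGCATGCAA", strrep("A", 40))
  evw <- evaluate_hairpin(weak, substr(weak, 1, 21), 2, engine = "nussinov",
                          mfe_max = -18)
  expect_false(evw$accepted)
})

test_that("acceptance is monotone in the energy threshold", {
  fx <- sim_fixture()
  pr <- fx$bundle$precursors[1, ]
  cuts <- c(-5, -10, -18, -25, -30)
  acc <- vapply(cuts, function(m)
    evaluate_hairpin(pr$sequence, pr$mature, 100, engine = "nussinov",
                     mfe_max = m)$accepted, NA)
  # once rejected at a strict (very negative) cut, never re-accepted at an
  # even stricter one; acceptance can only flip once along the sweep
  expect_true(all(diff(as.integer(acc)) <= 0))
})

test_that("novel catalogue naming is deduplicated, ordered and reproducible", {
  cand <- data.frame(
    mature = c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA",
               "TTGCACGTACGTACGTACGTA"),
    chrom = "chr1", start = c(5000, 100, 300), end = c(5021, 121, 321),
    strand = "+", stringsAsFactors = FALSE)
  out <- name_novel(cand)
  expect_identical(nrow(out), 2L)
  expect_identical(out$name, c("novel_mir_1", "novel_mir_2"))
  # both loci of the duplicated mature listed on one row
  expect_match(out$loci[out$mature == "ACGTACGTACGTACGTACGTA"], ";")
  expect_identical(out, name_novel(cand[c(3, 1, 2), ]))
  empty <- name_novel(NULL)
  expect_identical(nrow(empty), 0L)
})

test_that("novel discovery recovers planted uncatalogued miRNAs from the simulation", {
  fx <- sim_fixture()
  nov <- predict_novel_mirnas(fx$annotations, fx$bundle$genome,
                              engine = "nussinov")
  tot <- tapply(
    c(fx$libs$calli$truth$mirna_counts$count,
      fx$libs$protoplasts$truth$mirna_counts$count),
    c(fx$libs$calli$truth$mirna_counts$mirna,
      fx$libs$protoplasts$truth$mirna_counts$mirna), sum)
  expressed <- names(fx$bundle$novel_mirnas)[
    tot[names(fx$bundle$novel_mirnas)] >= 5]
  hit <- fx$bundle$novel_mirnas[expressed] %in% nov$mature
  expect_gte(mean(hit), 0.9)
  # every accepted mature is a substring of its reported precursor
  expect_true(all(mapply(grepl, nov$mature, nov$precursor, fixed = TRUE)))
  # determinism
  nov2 <- predict_novel_mirnas(fx$annotations, fx$bundle$genome,
                               engine = "nussinov")
  expect_identical(nov, nov2)
})
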