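test_that("a perfect antisense site aligns all-WC with score zero", {
  m <- "TGGAGCTCCCTTCATTCCAAT"  # 21 nt
  tx <- paste0(random_dna(1, 50), revcomp_chr(m), random_dna(1, 50))
  hits <- duplex_align(m, tx)
  best <- hits[hits$score == 0, ]
  expect_identical(nrow(best), 1L)
  expect_identical(best$start, 50L)
  expect_identical(best$classes, strrep("W", 21))
  expect_identical(best$bulge_side, "none")
})

test_that("a single G.U-compatible substitution scores one half mismatch", {
  m <- "TGGAGCTCCCTTCATTCCAAT"
  site <- revcomp_chr(m)
  # miRNA position 15 is T; pairing target base A -> G gives a U.G wobble
  ch <- strsplit(site, "")[[1]]
  ch[21 - 15 + 1] <- "G"
  tx <- paste0(strrep("C", 30), paste(ch, collapse = ""), strrep("C", 30))
  hits <- duplex_align(m, tx)
  best <- hits[hits$start == 30, ]
  expect_equal(best$score, 0.5)
  expect_identical(substr(best$classes, 15, 15), "G")
})

test_that("alignment rejects invalid alphabets and impossible lengths", {
  expect_error(duplex_align("ACGTN" , "ACGTACGT"), "alphabet|length")
  expect_error(duplex_align("ACGT", "ACGTACGTACGTACGTACGTACGT"), "18-26")
  expect_error(duplex_align("ACGTACGTACGTACGTACGT", "ACGT"), "shorter")
})

test_that("window scanning agrees with the exhaustive per-window oracle", {
  set.seed(33)
  for (rep in 1:3) {
    m <- random_dna(1, sample(19:23, 1))
    tx <- paste0(random_dna(1, 400), revcomp_chr(m), random_dna(1, 400))
    # plant two degraded sites to populate mid-range scores
    mm_site <- strsplit(revcomp_chr(m), "")[[1]]
    mm_site[c(2, 9)] <- c("A", "A")
    tx <- paste0(tx, paste(mm_site, collapse = ""), random_dna(1, 100))
    got <- duplex_align(m, tx, max_score = 4)
    want <- oracle_duplex_hits(m, tx, max_score = 4)
    expect_identical(got$start, want$start)
    expect_equal(got$score, want$score)
    # reported classes are consistent with the reported score
    w <- c(W = 0, G = 0.5, M = 1, B = 1)
    cls_score <- vapply(strsplit(got$classes, ""), function(ch) sum(w[ch]), 0) +
      (got$bulge_side == "target")
    expect_equal(cls_score, got$score)
  }
})

test_that("rule flags follow the stated criteria on crafted alignments", {
  mk <- function(classes, score = NULL, bulge_side = "none", bulge_pos = 0L) {
    w <- c(W = 0, G = 0.5, M = 1, B = 1)
    sc <- score %||% (sum(w[strsplit(classes, "")[[1]]]) +
                        (bulge_side == "target"))
    data.frame(start = 0L, end = nchar(classes), score = sc,
               classes = classes, bulge_side = bulge_side,
               bulge_pos = bulge_pos, stringsAsFactors = FALSE)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  allw <- mk(strrep("W", 21))
  f <- apply_rules(allw)
  expect_true(all(unlist(f[1, c("flag1", "flag2", "flag3", "flag4", "flag5")])))

  # mismatch at position 10 kills rule 4 regardless of everything else
  p10 <- mk(paste0(strrep("W", 9), "M", strrep("W", 11)))
  expect_false(apply_rules(p10)$flag4)

  # adjacent wobbles at 3-4 violate the seed adjacency rule (strict G.U)
  gu34 <- mk(paste0("WW", "GG", strrep("W", 17)))
  expect_false(apply_rules(gu34)$flag3)
  expect_true(apply_rules(gu34, gu_as_adjacent_mismatch = FALSE)$flag3)

  # three consecutive mismatches anywhere violate rule 2
  run3 <- mk(paste0(strrep("W", 13), "MMM", strrep("W", 5)))
  expect_false(apply_rules(run3)$flag2)
  run2 <- mk(paste0(strrep("W", 13), "MM", strrep("W", 6)))
  expect_true(apply_rules(run2)$flag2)

  # 5' region score: 2.5 in positions 1-12 is still allowed, 3 is not
  edge5p <- mk(paste0("MWMWG", strrep("W", 16)))
  expect_true(apply_rules(edge5p)$flag5)
  heavy5p <- mk(paste0("MWMWM", strrep("W", 16)))
  expect_false(apply_rules(heavy5p)$flag5)

  # crafted flags agree with the independently re-derived rule semantics
  set.seed(44)
  for (i in 1:25) {
    cls <- paste(sample(c("W", "G", "M"), 21, replace = TRUE,
                        prob = c(0.8, 0.1, 0.1)), collapse = "")
    a <- mk(cls)
    got <- apply_rules(a)
    want <- oracle_rule_flags(cls, a$score, "none", 0L)
    expect_identical(unlist(got[1, c("flag1", "flag2", "flag3", "flag4",
                                     "flag5")]), want)
  }
})

test_that("rules are monotone under MM -> GU -> WC improvement", {
  set.seed(55)
  for (i in 1:20) {
    cls <- sample(c("W", "G", "M"), 21, replace = TRUE, prob = c(0.7, 0.15, 0.15))
    mk1 <- function(ch) {
      w <- c(W = 0, G = 0.5, M = 1)
      data.frame(start = 0L, end = 21L, score = sum(w[ch]),
                 classes = paste(ch, collapse = ""), bulge_side = "none",
                 bulge_pos = 0L, stringsAsFactors = FALSE)
    }
    before <- apply_rules(mk1(cls))
    pos <- sample(which(cls != "W"), 1)
    cls2 <- cls
    cls2[pos] <- if (cls[pos] == "M") "G" else "W"
    after <- apply_rules(mk1(cls2))
    for (fl in c("flag1", "flag2", "flag3", "flag4", "flag5")) {
      expect_true(!before[[fl]] || after[[fl]], label = fl)
    }
  }
})

test_that("duplex energies give ratio 1 for perfect complements and degrade sensibly", {
  m <- "TGGAGCTCCCTTCATTCCAAT"
  perfect <- duplex_energy(m, revcomp_chr(m), classes = strrep("W", 21))
  expect_equal(perfect$mfe_ratio, 1)
  # four terminal mismatches: ratio below 1 but above the 0.75 criterion
  frayed <- duplex_energy(m, revcomp_chr(m),
                          classes = paste0("MM", strrep("W", 17), "MM"))
  expect_lt(frayed$mfe_ratio, 1)
  expect_gte(frayed$mfe_ratio, 0.75)
  # a fully unpaired "duplex" carries no binding energy
  none <- duplex_energy(m, revcomp_chr(m), classes = strrep("M", 21))
  expect_equal(none$duplex_mfe, 0)
  expect_equal(none$mfe_ratio, 0)
})

test_that("nearest-neighbour duplex energies order like the pair-count model", {
  skip_if(!nzchar(Sys.which("RNAduplex")))
  m <- "TGGAGCTCCCTTCATTCCAAT"
  perfect <- duplex_energy(m, revcomp_chr(m), engine = "vienna")
  expect_equal(perfect$mfe_ratio, 1, tolerance = 1e-6)
  site <- strsplit(revcomp_chr(m), "")[[1]]
  site[c(1, 2, 20, 21)] <- c("A", "A", "T", "T")
  frayed <- duplex_energy(m, paste(site, collapse = ""), engine = "vienna")
  expect_lt(frayed$mfe_ratio, 1)
  expect_gt(frayed$mfe_ratio, 0.5)
})

test_that("target prediction recovers planted sites and rejects scrambled queries", {
  fx <- sim_fixture()
  b <- fx$bundle
  all_mat <- c(b$mature_mirnas, b$novel_mirnas)
  site_mirs <- unique(b$target_sites$mirna)
  hits <- predict_targets(all_mat[site_mirs], b$transcripts)
  for (i in seq_len(nrow(b$target_sites))) {
    ts <- b$target_sites[i, ]
    expect_true(any(hits$mirna == ts$mirna & hits$transcript == ts$transcript &
                      hits$start == ts$start),
                label = paste("planted site of", ts$mirna))
  }
  # scrambling a miRNA destroys its hits (specificity)
  set.seed(66)
  scram <- vapply(strsplit(unname(all_mat[site_mirs[1:4]]), ""),
                  function(ch) paste(sample(ch), collapse = ""), "")
  names(scram) <- paste0("scrambled_", seq_along(scram))
  shits <- predict_targets(scram, b$transcripts)
  expect_identical(nrow(shits), 0L)
  expect_identical(sort(attr(shits, "no_target")), sort(names(scram)))
})

test_that("reported class vectors faithfully describe the underlying duplex", {
  set.seed(77)
  m <- random_dna(1, 21)
  tx <- paste0(random_dna(1, 300), revcomp_chr(m), random_dna(1, 300))
  hits <- duplex_align(m, tx, max_score = 4)
  ung <- hits[hits$bulge_side == "none", ]
  mch <- strsplit(m, "")[[1]]
  for (r in seq_len(nrow(ung))) {
    win <- strsplit(substr(tx, ung$start[r] + 1, ung$end[r]), "")[[1]]
    L <- length(mch)
    want <- vapply(1:L, function(i) oracle_pair_class(mch[i], win[L - i + 1]), "")
    expect_identical(ung$classes[r], paste(want, collapse = ""))
  }
})
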