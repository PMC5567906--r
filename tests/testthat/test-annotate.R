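test_that("genome mapping finds exact loci on both strands and agrees with a naive scan", {
  set.seed(3)
  genome <- c(chrT = random_dna(1, 5000))
  q_fwd <- substr(genome, 1001, 1020)
  q_rev <- revcomp_chr(substr(genome, 2001, 2020))
  hits <- map_to_genome(c(q_fwd, q_rev), genome)
  expect_true(any(hits$sequence == q_fwd & hits$start == 1000 &
                    hits$end == 1020 & hits$strand == "+"))
  expect_true(any(hits$sequence == q_rev & hits$start == 2000 &
                    hits$end == 2020 & hits$strand == "-"))

  # naive O(n*m) substring scan as oracle over random queries
  queries <- c(random_dna(10, 20),
               vapply(sample(100:4000, 10), function(s)
                 substr(genome, s, s + 24), ""))
  hits <- map_to_genome(queries, genome)
  for (q in queries) {
    fwd_true <- gregexpr(q, genome, fixed = TRUE)[[1]]
    fwd_true <- fwd_true[fwd_true > 0] - 1L
    got <- hits[hits$sequence == q & hits$strand == "+", "start"]
    expect_identical(sort(got), sort(fwd_true))
    rc <- revcomp_chr(q)
    rev_true <- gregexpr(rc, genome, fixed = TRUE)[[1]]
    rev_true <- rev_true[rev_true > 0] - 1L
    got <- hits[hits$sequence == q & hits$strand == "-", "start"]
    expect_identical(sort(got), sort(rev_true))
  }
})

test_that("hit capping flags repeat-derived sequences", {
  genome <- c(chr1 = paste(rep("ACGTACGTAACCGGTTACGATCGT", 40), collapse = ""))
  q <- substr(genome, 1, 20)
  hits <- map_to_genome(q, genome, max_hits = 5)
  expect_identical(nrow(hits), 5L)
  expect_identical(attr(hits, "overflow"), unname(q))
})

test_that("classification priority puts ncRNA classes above the mature catalogue", {
  seq_both <- paste(rep("ACGT", 6), collapse = "")  # 24 nt
  refs <- list(ncrna = list(rRNA = c(r1 = paste0("GG", seq_both, "CC")),
                            tRNA = character(0), snRNA = character(0),
                            snoRNA = character(0)),
               mature_mirnas = c(mir1 = seq_both),
               genome = c(chr1 = random_dna(1, 2000)),
               genes = GenomicRanges::GRanges())
  prof <- protomir:::new_library_profile(setNames(4L, seq_both))
  ann <- classify(prof, refs)
  expect_identical(ann$per_sequence$category, "rRNA")
  # remove the rRNA entry: same sequence now reports as known miRNA
  refs$ncrna$rRNA <- character(0)
  ann2 <- classify(prof, refs)
  expect_identical(ann2$per_sequence$category, "known_miRNA")
})

test_that("exon and intron assignment respects strand and majority overlap", {
  set.seed(8)
  genome <- c(chr1 = random_dna(1, 3000))
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1001, 1201), end = c(1200, 1400)),
    strand = "+", type = c("exon", "intron"), gene_id = "g1")
  exon_read <- substr(genome, 1050, 1073)            # sense exon
  anti_read <- revcomp_chr(substr(genome, 1100, 1123))
  intron_read <- substr(genome, 1250, 1273)
  junction <- substr(genome, 1190, 1213)             # 11 exon / 13 intron nt
  prof <- protomir:::new_library_profile(
    setNames(rep(1L, 4), c(exon_read, anti_read, intron_read, junction)))
  refs <- list(ncrna = list(rRNA = character(0), tRNA = character(0),
                            snRNA = character(0), snoRNA = character(0)),
               mature_mirnas = c(m = random_dna(1, 21)),
               genome = genome, genes = genes)
  ann <- classify(prof, refs)
  got <- setNames(ann$per_sequence$category, ann$per_sequence$sequence)
  expect_identical(unname(got[exon_read]), "exon_sense")
  expect_identical(unname(got[anti_read]), "exon_antisense")
  expect_identical(unname(got[intron_read]), "intron_sense")
  expect_identical(unname(got[junction]), "intron_sense")  # majority intron
})

test_that("classification of a simulated library matches the generator truth", {
  fx <- sim_fixture()
  for (cond in names(fx$libs)) {
    truth <- fx$libs[[cond]]$truth
    summ <- fx$annotations[[cond]]$summary
    reads_of <- function(cat) summ$reads[summ$category == cat]
    # ncRNA class read counts are exact
    expect_identical(vapply(truth$ncrna_classes, reads_of, 0L),
                     setNames(truth$ncrna_class_counts, truth$ncrna_classes))
    # known miRNA reads = planted counts of catalogued miRNAs
    expect_identical(reads_of("known_miRNA"),
                     sum(truth$mirna_counts$count[truth$mirna_counts$known]))
    # categories partition the clean reads
    expect_identical(sum(summ$reads), fx$profiles[[cond]]$total_clean)

    # degradation-derived exon/intron mass agrees with plain-interval logic
    gdf <- as.data.frame(fx$bundle$genes)
    orig <- truth$degradation_origin
    expected <- table(vapply(seq_len(nrow(orig)), function(i)
      oracle_feature_category(orig$start[i], orig$width[i], orig$strand[i],
                              gdf), ""))
    for (cat in c("exon_sense", "exon_antisense", "intron_sense",
                  "intron_antisense")) {
      exp_n <- if (cat %in% names(expected)) expected[[cat]] else 0L
      # small slack: identical degradation fragments drawn from two loci
      # collapse onto one sequence and may take the other locus's category
      expect_lt(abs(reads_of(cat) - exp_n),
                max(5, 0.005 * nrow(orig)))
    }
  }
})

test_that("known miRNA identification is exact-match only, U/T-insensitive", {
  prof <- protomir:::new_library_profile(
    setNames(c(10L, 3L), c("ACGTACGTACGTACGTACGTA", "TTTTACGTACGTACGTACGTA")))
  mature <- c(mirU = "ACGUACGUACGUACGUACGUA",    # U-form of sequence 1
              mirMM = "ACGTACGTACGTACGTACGTT")   # 1 mismatch to sequence 1
  cat <- identify_known_mirnas(prof, mature)
  expect_identical(cat$count_library[cat$name == "mirU"], 10L)
  expect_identical(cat$count_library[cat$name == "mirMM"], 0L)
  expect_error(identify_known_mirnas(prof, character(0)), "non-empty")
  dup <- c(a = "ACGTACGTACGTACGTACGTA", b = "ACGTACGTACGTACGTACGTA")
  expect_warning(identify_known_mirnas(prof, dup), "duplicate")
})

test_that("known miRNA counts in the simulation equal the planted counts", {
  fx <- sim_fixture()
  cat <- identify_known_mirnas(fx$profiles, fx$bundle$mature_mirnas)
  for (cond in names(fx$libs)) {
    tm <- fx$libs[[cond]]$truth$mirna_counts
    planted <- setNames(tm$count, tm$mirna)[cat$name]
    expect_identical(unname(cat[[paste0("count_", cond)]]),
                     as.integer(unname(planted)))
  }
})

test_that("family labels group catalogue members by name stem", {
  expect_identical(mirna_family(c("crt-miR166e*", "crt-miR166a", "crt-miR171.3",
                                  "sim-miR003b", "novel_mir_12")),
                   c("miR166", "miR166", "miR171", "miR003", NA))
  fx <- sim_fixture()
  cat <- identify_known_mirnas(fx$profiles$calli, fx$bundle$mature_mirnas)
  expect_identical(cat$family, unname(fx$bundle$families[cat$name]))
})

test_that("a missing reference set raises a named configuration error", {
  prof <- protomir:::new_library_profile(setNames(1L, random_dna(1, 20)))
  refs <- list(ncrna = list(rRNA = character(0), tRNA = character(0),
                            snRNA = character(0)),
               mature_mirnas = c(m = "ACGTACGTACGTACGTACGT"),
               genome = c(chr1 = "ACGT"), genes = GenomicRanges::GRanges())
  expect_error(classify(prof, refs), "snoRNA")
})
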