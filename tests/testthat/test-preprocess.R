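test_that("ledger arithmetic derives clean reads and percentage from categories", {
  l <- read_ledger(1000, 990, no_3adapter = 10, insert_null = 5,
                   contaminant_5adapter = 3, shorter_than_18 = 20, poly_a = 2)
  expect_identical(l$clean_reads, 990 - 40)
  expect_equal(l$clean_pct, round(100 * 950 / 990, 2))
  expect_error(read_ledger(100, 200), "exceeds")
  expect_error(read_ledger(100, 90, no_3adapter = 95), "exceeds")
})

test_that("each read lands in exactly one category by the fixed precedence", {
  a3 <- "TCGTATGCCGTCTTCTGCTTG"
  a5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  pad <- function(x) substr(paste0(x, strrep("A", 50)), 1, 50)
  reads <- c(
    lowq = pad(paste0("ACGTNACGTACGTACGTACGT", a3)),          # N => low quality
    no3 = strrep("C", 50),                                     # no adapter
    null = pad(a3),                                            # adapter at 0
    contam = pad(paste0(substr(a5, 1, 12), "ACGTACGT", a3)),   # 5' contaminant
    short = pad(paste0("ACGTACGTACGT", a3)),                   # 12 nt insert
    polya = pad(paste0(strrep("A", 22), a3)),                  # poly-A insert
    clean = pad(paste0("ACGTACGTACGTACGTACGTAC", a3)))         # 22 nt insert
  res <- clean_reads(unname(reads), a3, a5)
  l <- res$ledger
  expect_identical(l$total_reads, 7L)
  expect_identical(l$high_quality, 6L)
  expect_identical(l$no_3adapter, 1L)
  expect_identical(l$insert_null, 1L)
  expect_identical(l$contaminant_5adapter, 1L)
  expect_identical(l$shorter_than_18, 1L)
  expect_identical(l$poly_a, 1L)
  expect_identical(l$clean_reads, 1L)
  expect_identical(names(res$profile$seq_counts), "ACGTACGTACGTACGTACGTAC")
})

test_that("empty input yields an empty profile with a zeroed ledger", {
  res <- clean_reads(character(0), "TCGTATGCCGTCTTCTGCTTG")
  expect_identical(res$ledger$total_reads, 0)
  expect_identical(res$profile$total_clean, 0L)
  expect_identical(nrow(length_distribution(res$profile)), 0L)
})

test_that("cleaning a simulated library reproduces the injected truth exactly", {
  fx <- sim_fixture()
  for (cond in names(fx$libs)) {
    tc <- fx$libs[[cond]]$truth$category_counts
    l <- fx$ledgers[[cond]]
    expect_identical(l$high_quality, sum(tc) - tc[["low_quality"]])
    expect_identical(l$no_3adapter, tc[["no_3adapter"]])
    expect_identical(l$insert_null, tc[["insert_null"]])
    expect_identical(l$contaminant_5adapter, tc[["contaminant_5adapter"]])
    expect_identical(l$shorter_than_18, tc[["shorter_than_18"]])
    expect_identical(l$poly_a, tc[["poly_a"]])
    expect_identical(l$clean_reads, sum(tc[c("ncrna", "degradation", "mirna")]))
    # collapsing is count-preserving
    p <- fx$profiles[[cond]]
    expect_identical(sum(p$seq_counts), p$total_clean)
    expect_identical(p$total_clean, l$clean_reads)
    expect_true(all(nchar(names(p$seq_counts)) >= 18 &
                      nchar(names(p$seq_counts)) <= 30))
  }
})

test_that("ledger conservation holds on random fuzzed read sets", {
  a3 <- "TCGTATGCCGTCTTCTGCTTG"
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    reads <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T", "N"), sample(20:60, 1),
                   replace = TRUE, prob = c(24, 24, 24, 24, 1)),
            collapse = ""), "")
    l <- clean_reads(reads, a3)$ledger
    cats <- l$no_3adapter + l$insert_null + l$contaminant_5adapter +
      l$shorter_than_18 + l$poly_a
    expect_identical(l$clean_reads, l$high_quality - cats)
    expect_true(l$high_quality <= l$total_reads)
  }
})

test_that("length distribution is read-count weighted and sums to one", {
  p <- protomir:::new_library_profile(
    setNames(c(3L, 1L), c(strrep("A", 24), strrep("G", 21))))
  h <- length_distribution(p)
  expect_equal(h$fraction[h$length == 24], 0.75)
  expect_equal(h$fraction[h$length == 21], 0.25)
  expect_equal(sum(h$fraction), 1)

  single <- protomir:::new_library_profile(setNames(5L, strrep("C", 22)))
  hs <- length_distribution(single)
  expect_identical(nrow(hs), 1L)
  expect_equal(hs$fraction, 1)

  # simulated libraries: 24 nt is the modal degradation length by design
  fx <- sim_fixture()
  hd <- length_distribution(fx$profiles$calli)
  expect_equal(sum(hd$fraction), 1)
})

test_that("collapsed FASTA profiles round-trip with multiplicities", {
  fx <- sim_fixture()
  f <- tempfile(fileext = ".fa")
  write_profile_fasta(fx$profiles$calli, f)
  back <- read_srna_file(f)
  res <- clean_reads(paste0(back$reads, fx$params$adapter3),
                     fx$params$adapter3, fx$params$adapter5,
                     counts = back$counts)
  expect_identical(res$profile$seq_counts, fx$profiles$calli$seq_counts)
  unlink(f)
})
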