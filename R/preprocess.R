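#' Read-accounting ledger for small RNA cleaning
#'
#' Constructs the per-category accounting ledger used during read cleaning.
#' Categories follow the conventional BGI-style summary: total raw reads,
#' high-quality reads, and the mutually exclusive removal categories
#' (3' adapter absent, empty insert, 5' adapter contamination, insert
#' shorter than the length window, poly-A insert). Clean reads and the clean
#' percentage are derived, never supplied:
#' \code{clean_reads = high_quality - sum(removal categories)} and
#' \code{clean_pct = 100 * clean_reads / high_quality} (2 decimals).
#'
#' @param total_reads,high_quality,no_3adapter,insert_null,contaminant_5adapter,shorter_than_18,poly_a
#'   non-negative integer category counts.
#' @return An object of class \code{ReadLedger}.
#' @examples
#' read_ledger(17975734, 17945812, 11146, 700, 9082, 23368, 2476)
#' @export
read_ledger <- function(total_reads, high_quality, no_3adapter = 0,
                        insert_null = 0, contaminant_5adapter = 0,
                        shorter_than_18 = 0, poly_a = 0) {
  cats <- c(no_3adapter = no_3adapter, insert_null = insert_null,
            contaminant_5adapter = contaminant_5adapter,
            shorter_than_18 = shorter_than_18, poly_a = poly_a)
  if (any(c(total_reads, high_quality, cats) < 0)) stop("counts must be >= 0")
  if (high_quality > total_reads) stop("high_quality exceeds total_reads")
  if (any(cats > high_quality)) stop("a category exceeds high_quality")
  clean <- high_quality - sum(cats)
  if (clean < 0) stop("removal categories exceed high_quality")
  structure(list(total_reads = total_reads, high_quality = high_quality,
                 no_3adapter = cats[["no_3adapter"]],
                 insert_null = cats[["insert_null"]],
                 contaminant_5adapter = cats[["contaminant_5adapter"]],
                 shorter_than_18 = cats[["shorter_than_18"]],
                 poly_a = cats[["poly_a"]],
                 clean_reads = clean,
                 clean_pct = if (high_quality > 0)
                   round(100 * clean / high_quality, 2) else NA_real_),
            class = "ReadLedger")
}

#' @export
print.ReadLedger <- function(x, ...) {
  cat("Read ledger\n")
  fmt <- function(v) formatC(v, big.mark = ",", format = "d")
  cat(sprintf("  Total reads            %s\n", fmt(x$total_reads)))
  cat(sprintf("  High quality           %s\n", fmt(x$high_quality)))
  cat(sprintf("  3' adaptor null        %s\n", fmt(x$no_3adapter)))
  cat(sprintf("  Insert null            %s\n", fmt(x$insert_null)))
  cat(sprintf("  5' adaptor contaminants %s\n", fmt(x$contaminant_5adapter)))
  cat(sprintf("  Smaller than 18 nt     %s\n", fmt(x$shorter_than_18)))
  cat(sprintf("  Poly A                 %s\n", fmt(x$poly_a)))
  cat(sprintf("  Clean reads            %s (%.2f%%)\n", fmt(x$clean_reads),
              x$clean_pct))
  invisible(x)
}

new_library_profile <- function(seq_counts, condition = "library") {
  if (length(seq_counts) == 0) seq_counts <- setNames(integer(0), character(0))
  seq_counts <- seq_counts[order(names(seq_counts))]
  structure(list(condition = condition,
                 seq_counts = seq_counts,
                 total_clean = sum(seq_counts),
                 unique_count = length(seq_counts)),
            class = "LibraryProfile")
}

#' @export
print.LibraryProfile <- function(x, ...) {
  cat(sprintf("LibraryProfile '%s': %s clean reads, %s unique sequences\n",
              x$condition, formatC(x$total_clean, big.mark = ","),
              formatC(x$unique_count, big.mark = ",")))
  invisible(x)
}

#' Clean raw small RNA reads into a collapsed library profile
#'
#' Assigns every read to exactly one ledger category by the first failing
#' test in fixed order: low quality (any N, or mean Phred below
#' \code{min_mean_q}) -> 3' adapter absent -> empty insert -> 5' adapter
#' contamination -> insert outside the length window -> poly-A insert ->
#' clean. Clean inserts are collapsed into a unique-sequence count profile.
#'
#' The 3' adapter is located as the first read position where the adapter
#' prefix (overlap at least \code{min_overlap} nt, at most \code{max_mm}
#' mismatches) matches; a full-length match at the insert/adapter junction
#' therefore dominates short spurious matches near the read end. A 5'
#' adapter contaminant is an insert containing the first 10 nt of the 5'
#' adapter with at most one mismatch. A poly-A insert is at least 80\%
#' adenine. Inserts longer than \code{max_len} (possible when the adapter
#' sits late in the read) are counted in the length-filter category together
#' with those shorter than \code{min_len}.
#'
#' @param reads character vector of raw reads (or a
#'   \code{SimulatedLibrary}, whose reads and condition are taken).
#' @param adapter3 3' adapter sequence (required, non-empty).
#' @param adapter5 5' adapter sequence used for contamination screening.
#' @param min_len,max_len insert length window kept for analysis (nt).
#' @param qualities optional Phred33 quality strings (same length as reads).
#' @param min_mean_q mean Phred threshold below which a read is low quality.
#' @param counts optional per-read multiplicities (collapsed input).
#' @param condition label stored in the profile.
#' @param min_overlap,max_mm adapter match parameters.
#' @param polya_min minimum adenine fraction calling a poly-A insert.
#' @return A list with elements \code{profile} (a \code{LibraryProfile})
#'   and \code{ledger} (a \code{ReadLedger}).
#' @export
clean_reads <- function(reads, adapter3, adapter5 = "", min_len = 18,
                        max_len = 30, qualities = NULL, min_mean_q = 20,
                        counts = NULL, condition = "library",
                        min_overlap = 6, max_mm = 1, polya_min = 0.8) {
  if (inherits(reads, "SimulatedLibrary")) {
    lib <- reads
    reads <- lib$reads
    qualities <- qualities %||% lib$qualities
    if (identical(condition, "library")) condition <- lib$condition
  }
  adapter3 <- norm_dna(adapter3)
  if (!nzchar(adapter3)) stop("adapter3 must be non-empty")
  adapter5 <- norm_dna(adapter5)
  n <- length(reads)
  if (n == 0) {
    return(list(profile = new_library_profile(integer(0), condition),
                ledger = read_ledger(0, 0)))
  }
  if (is.null(counts)) counts <- rep(1L, n)
  stopifnot(length(counts) == n)
  reads <- toupper(reads)

  # 1. low quality: any non-ACGT character, or mean Phred < min_mean_q
  lowq <- grepl("[^ACGT]", reads)
  if (!is.null(qualities)) {
    uq <- unique(qualities)
    mq <- vapply(uq, function(q) mean(utf8ToInt(q)) - 33, 0)
    lowq <- lowq | (mq[match(qualities, uq)] < min_mean_q)
  }

  # 2. 3' adapter localisation on high-quality reads
  apos <- rep(NA_integer_, n)
  hq <- which(!lowq)
  apos[hq] <- cpp_find_adapter(reads[hq], adapter3, min_overlap, max_mm)
  inserts <- substr(reads, 1, pmax(apos, 0))

  no3ad <- !lowq & apos < 0
  nullins <- !lowq & !no3ad & apos == 0
  contam <- rep(FALSE, n)
  if (nzchar(adapter5)) {
    cand <- which(!lowq & !no3ad & !nullins)
    contam[cand] <- cpp_contains_pattern(inserts[cand],
                                         substr(adapter5, 1, 10), 1L)
  }
  ilen <- nchar(inserts)
  badlen <- !lowq & !no3ad & !nullins & !contam &
    (ilen < min_len | ilen > max_len)
  polya <- !lowq & !no3ad & !nullins & !contam & !badlen &
    polya_fraction(inserts) >= polya_min
  clean <- !lowq & !no3ad & !nullins & !contam & !badlen & !polya

  wsum <- function(sel) sum(counts[sel])
  ledger <- read_ledger(
    total_reads = sum(counts),
    high_quality = sum(counts) - wsum(lowq),
    no_3adapter = wsum(no3ad),
    insert_null = wsum(nullins),
    contaminant_5adapter = wsum(contam),
    shorter_than_18 = wsum(badlen),
    poly_a = wsum(polya))

  sc <- tapply(counts[clean], inserts[clean], sum)
  seq_counts <- setNames(as.integer(sc), names(sc))
  list(profile = new_library_profile(seq_counts, condition), ledger = ledger)
}

#' Length distribution of a cleaned library
#'
#' Read-count-weighted histogram of insert lengths over the analysis window.
#'
#' @param profile a \code{LibraryProfile}.
#' @return A data.frame with columns \code{length}, \code{reads} and
#'   \code{fraction}; fractions sum to 1 (empty profile gives zero rows).
#' @export
length_distribution <- function(profile) {
  stopifnot(inherits(profile, "LibraryProfile"))
  if (profile$unique_count == 0) {
    return(data.frame(length = integer(), reads = integer(),
                      fraction = numeric()))
  }
  lens <- nchar(names(profile$seq_counts))
  agg <- tapply(profile$seq_counts, lens, sum)
  data.frame(length = as.integer(names(agg)),
             reads = as.integer(agg),
             fraction = as.numeric(agg) / profile$total_clean,
             row.names = NULL)
}

#' Read raw reads from FASTQ or collapsed FASTA
#'
#' FASTQ files (Phred33) yield per-read sequences and qualities; collapsed
#' FASTA files with \code{>id_xCOUNT} headers yield unique sequences with
#' multiplicities.
#'
#' @param path input file.
#' @return A list with \code{reads}, \code{qualities} (NULL for FASTA) and
#'   \code{counts}.
#' @export
read_srna_file <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "@")) {
    # Biostrings warns about dropping per-read metadata columns it carries
    # internally; the reads and qualities are unaffected
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    list(reads = unname(as.character(x)),
         qualities = unname(as.character(Biostrings::quality(x))),
         counts = rep(1L, length(x)))
  } else {
    x <- Biostrings::readDNAStringSet(path)
    cnt <- suppressWarnings(as.integer(sub(".*_x(\\d+)$", "\\1", names(x))))
    cnt[is.na(cnt)] <- 1L
    list(reads = unname(as.character(x)), qualities = NULL, counts = cnt)
  }
}

#' Write a collapsed library profile as FASTA
#'
#' Headers follow the \code{>sN_xCOUNT} convention.
#'
#' @param profile a \code{LibraryProfile}.
#' @param path output path.
#' @export
write_profile_fasta <- function(profile, path) {
  seqs <- Biostrings::DNAStringSet(names(profile$seq_counts))
  names(seqs) <- sprintf("s%d_x%d", seq_along(seqs), profile$seq_counts)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Ledger as a two-column summary table
#'
#' @param ... named \code{ReadLedger} objects (one column each).
#' @return A data.frame shaped like a per-library cleaning summary.
#' @export
ledger_table <- function(...) {
  ledgers <- list(...)
  rows <- c("Total reads", "High quality", "3' adaptor null", "Insert null",
            "5' adaptor contaminants", "Smaller than 18 nt", "Poly A",
            "Clean reads")
  out <- data.frame(Category = rows, stringsAsFactors = FALSE)
  for (nm in names(ledgers)) {
    l <- ledgers[[nm]]
    out[[nm]] <- c(l$total_reads, l$high_quality, l$no_3adapter,
                   l$insert_null, l$contaminant_5adapter, l$shorter_than_18,
                   l$poly_a, l$clean_reads)
  }
  out
}
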