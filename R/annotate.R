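ANNOT_CATEGORIES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "known_miRNA",
                      "exon_sense", "exon_antisense", "intron_sense",
                      "intron_antisense", "unannotated")

#' Map sequences to a genome by exact match
#'
#' Finds all exact-match loci of each query on both strands of a single
#' reference chromosome. Matching is case- and U/T-insensitive. Hits per
#' sequence are capped at \code{max_hits} (repeat-derived sequences), with
#' the overflow recorded.
#'
#' @param sequences character vector of queries (length >= 15 recommended;
#'   queries with ambiguous characters return no hits).
#' @param genome reference sequence (character or \code{DNAString});
#'   chromosome name taken from its name, default \code{"chr1"}.
#' @param max_hits cap on reported loci per sequence.
#' @return A data.frame with columns \code{sequence}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand}; the
#'   attribute \code{"overflow"} names sequences whose hits were capped.
#' @export
map_to_genome <- function(sequences, genome, max_hits = 25) {
  chrom <- names(genome)[1] %||% "chr1"
  subj <- Biostrings::DNAString(norm_dna(as.character(genome)[1]))
  sequences <- norm_dna(sequences)
  empty <- data.frame(sequence = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  usable <- !grepl("[^ACGT]", sequences) & nchar(sequences) > 0
  if (!any(usable)) {
    attr(empty, "overflow") <- character(0)
    return(empty)
  }
  uq <- unique(sequences[usable])
  res <- list()
  collect <- function(m, grp, w, strand) {
    nh <- S4Vectors::elementNROWS(m)
    if (sum(nh) == 0) return(NULL)
    ir <- unlist(m)
    st <- IRanges::start(ir) - 1L
    data.frame(sequence = rep(grp, nh), chrom = chrom, start = st,
               end = st + w, strand = strand, stringsAsFactors = FALSE)
  }
  for (w in sort(unique(nchar(uq)))) {
    grp <- uq[nchar(uq) == w]
    fwd <- Biostrings::DNAStringSet(grp)
    m <- Biostrings::matchPDict(Biostrings::PDict(fwd), subj)
    res[[length(res) + 1]] <- collect(m, grp, w, "+")
    m <- Biostrings::matchPDict(
      Biostrings::PDict(Biostrings::reverseComplement(fwd)), subj)
    res[[length(res) + 1]] <- collect(m, grp, w, "-")
  }
  res <- Filter(Negate(is.null), res)
  if (length(res) == 0) {
    attr(empty, "overflow") <- character(0)
    return(empty)
  }
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$sequence, hits$start, hits$strand), ]
  nh <- table(hits$sequence)
  overflow <- names(nh)[nh > max_hits]
  if (length(overflow) > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$sequence),
                          function(ix) head(ix, max_hits)), use.names = FALSE)
    hits <- hits[sort(keep), ]
  }
  rownames(hits) <- NULL
  attr(hits, "overflow") <- overflow
  hits
}

# which sequences occur as exact substrings of any reference in `refs`;
# N-joined concatenation prevents matches across reference boundaries
match_in_set <- function(sequences, refs) {
  if (length(refs) == 0 || length(sequences) == 0) {
    return(rep(FALSE, length(sequences)))
  }
  subj <- Biostrings::DNAString(paste(norm_dna(refs), collapse = "NNNN"))
  out <- rep(FALSE, length(sequences))
  usable <- !grepl("[^ACGT]", sequences)
  uq <- sequences[usable]
  for (w in unique(nchar(uq))) {
    grp_ix <- which(usable & nchar(sequences) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sequences[grp_ix]))
    cnt <- Biostrings::countPDict(pd, subj)
    out[grp_ix] <- cnt > 0
  }
  out
}

#' Hierarchically classify a cleaned library
#'
#' Assigns each unique sequence the first matching category in fixed
#' priority order: rRNA > tRNA > snRNA > snoRNA > known miRNA > exon/intron
#' (exon before intron, sense before antisense) > unannotated. ncRNA and
#' miRNA matching is exact (substring for ncRNA classes, full-length for the
#' mature catalogue); genome placement uses exact matching on both strands.
#' A genome-mapped sequence overlapping both exon and intron is classified
#' by majority overlap (ties go to exon); sequences mapping to several loci
#' take the highest-priority category across loci.
#'
#' @param profile a \code{LibraryProfile}.
#' @param refs a \code{ReferenceBundle}, or a list with elements
#'   \code{ncrna} (named list of the four class sets), \code{mature_mirnas},
#'   \code{genome} and \code{genes} (GRanges with \code{type} exon/intron).
#' @param max_hits genome hit cap per sequence (see
#'   \code{\link{map_to_genome}}).
#' @return An object of class \code{AnnotationTable}: list with
#'   \code{per_sequence} (sequence, count, category, n_loci),
#'   \code{summary} (per-category read and unique counts with unique-based
#'   percentages), \code{mapped} (unique mapped count and percentage) and
#'   \code{loci} (the genome hit table).
#' @export
classify <- function(profile, refs, max_hits = 25) {
  stopifnot(inherits(profile, "LibraryProfile"))
  for (need in c("ncrna", "mature_mirnas", "genome", "genes")) {
    if (is.null(refs[[need]])) {
      stop("reference set '", need, "' is missing from refs")
    }
  }
  seqs <- names(profile$seq_counts)
  cnt <- unname(profile$seq_counts)
  category <- rep(NA_character_, length(seqs))

  for (cl in c("rRNA", "tRNA", "snRNA", "snoRNA")) {
    if (is.null(refs$ncrna[[cl]])) {
      stop("reference set '", cl, "' is missing from refs$ncrna")
    }
    todo <- is.na(category)
    hit <- match_in_set(seqs[todo], refs$ncrna[[cl]])
    category[todo][hit] <- cl
  }

  todo <- is.na(category)
  mat <- norm_dna(refs$mature_mirnas)
  category[todo][seqs[todo] %in% mat] <- "known_miRNA"

  # genome mapping of all unique sequences (for the mapped statistic), but
  # feature classification only for the still-unassigned ones
  loci <- map_to_genome(seqs, refs$genome, max_hits = max_hits)
  n_loci <- integer(length(seqs))
  if (nrow(loci) > 0) {
    tl <- table(loci$sequence)
    n_loci[match(names(tl), seqs)] <- as.integer(tl)
  }

  todo <- which(is.na(category))
  if (length(todo) > 0 && nrow(loci) > 0) {
    sub <- loci[loci$sequence %in% seqs[todo], ]
    if (nrow(sub) > 0) {
      gr <- GenomicRanges::GRanges(sub$chrom,
              IRanges::IRanges(sub$start + 1L, sub$end), strand = sub$strand)
      feat <- refs$genes
      ov <- GenomicRanges::findOverlaps(gr, feat, ignore.strand = TRUE)
      locus_cat <- rep("unannotated", nrow(sub))
      if (length(ov) > 0) {
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        ow <- IRanges::width(IRanges::pintersect(
          IRanges::ranges(gr)[qh], IRanges::ranges(feat)[sh]))
        ftype <- feat$type[sh]
        sense <- as.character(GenomicRanges::strand(gr))[qh] ==
          as.character(GenomicRanges::strand(feat))[sh]
        # most loci overlap a single feature; resolve those vectorised and
        # apply the majority-overlap rule only to junction-spanning loci
        single <- !(qh %in% qh[duplicated(qh)])
        locus_cat[qh[single]] <- paste0(
          ftype[single], ifelse(sense[single], "_sense", "_antisense"))
        multi <- unique(qh[!single])
        for (q in multi) {
          sel <- which(qh == q)
          wex <- sum(ow[sel][ftype[sel] == "exon"])
          win <- sum(ow[sel][ftype[sel] == "intron"])
          ty <- if (wex >= win) "exon" else "intron"
          tsel <- sel[ftype[sel] == ty]
          sn <- sense[tsel][which.max(ow[tsel])]
          locus_cat[q] <- paste0(ty, if (sn) "_sense" else "_antisense")
        }
      }
      prio <- c(exon_sense = 1, exon_antisense = 2, intron_sense = 3,
                intron_antisense = 4, unannotated = 5)
      best <- tapply(prio[locus_cat], sub$sequence, min)
      cat_of <- names(prio)[best]
      ix <- match(names(best), seqs)
      category[ix] <- cat_of
    }
  }
  category[is.na(category)] <- "unannotated"

  reads_by <- tapply(cnt, factor(category, levels = ANNOT_CATEGORIES), sum)
  uniq_by <- table(factor(category, levels = ANNOT_CATEGORIES))
  reads_by[is.na(reads_by)] <- 0
  n_unique <- length(seqs)
  summary <- data.frame(
    category = ANNOT_CATEGORIES,
    reads = as.integer(reads_by),
    unique = as.integer(uniq_by),
    unique_pct = if (n_unique > 0)
      round(100 * as.integer(uniq_by) / n_unique, 2) else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE)
  mapped_unique <- sum(n_loci > 0)
  structure(list(
    per_sequence = data.frame(sequence = seqs, count = cnt,
                              category = category, n_loci = n_loci,
                              stringsAsFactors = FALSE),
    summary = summary,
    mapped = list(unique = mapped_unique,
                  pct = if (n_unique > 0)
                    round(100 * mapped_unique / n_unique, 2) else NA_real_),
    loci = loci), class = "AnnotationTable")
}

#' @export
print.AnnotationTable <- function(x, ...) {
  cat("Annotation summary (", nrow(x$per_sequence), " unique sequences, ",
      x$mapped$unique, " mapped to genome = ", sprintf("%.2f%%", x$mapped$pct),
      ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' miRNA family from a catalogue name
#'
#' Strips species prefixes, member letters, sub-numbering and the star
#' suffix: \code{"crt-miR166e*"} and \code{"crt-miR166a"} both give
#' \code{"miR166"}; names without a \code{miR<number>} stem give \code{NA}.
#'
#' @param name character vector of miRNA names.
#' @return Character vector of family labels.
#' @export
mirna_family <- function(name) {
  m <- regmatches(name, regexpr("miR[0-9]+", name))
  out <- rep(NA_character_, length(name))
  out[regexpr("miR[0-9]+", name) > 0] <- m
  out
}

#' Identify known miRNAs by exact match to a mature catalogue
#'
#' A profile sequence is assigned to a known miRNA if and only if it is an
#' exact, full-length, case- and U/T-insensitive match to a catalogued
#' mature sequence; per-library read counts are attached. Catalogue entries
#' sharing one mature sequence under different names collapse to the first
#' name, with a warning.
#'
#' @param profiles a \code{LibraryProfile} or named list of them (the names
#'   become count column suffixes).
#' @param mature_ref named character vector of mature miRNA sequences.
#' @return A data.frame with columns \code{name}, \code{family},
#'   \code{mature} and one \code{count_<label>} column per profile. All
#'   catalogued miRNAs are reported, including zero-count ones.
#' @export
identify_known_mirnas <- function(profiles, mature_ref) {
  if (length(mature_ref) == 0) stop("mature_ref must be non-empty")
  if (inherits(profiles, "LibraryProfile")) {
    profiles <- setNames(list(profiles), profiles$condition)
  }
  mat <- norm_dna(mature_ref)
  dup <- duplicated(mat)
  if (any(dup)) {
    warning("duplicate mature sequences; keeping first name(s): ",
            paste(names(mat)[dup], collapse = ", "))
    mat <- mat[!dup]
  }
  out <- data.frame(name = names(mat), family = mirna_family(names(mat)),
                    mature = unname(mat), stringsAsFactors = FALSE)
  for (lab in names(profiles)) {
    p <- profiles[[lab]]
    ix <- match(mat, names(p$seq_counts))
    cc <- ifelse(is.na(ix), 0L, unname(p$seq_counts)[ix])
    out[[paste0("count_", lab)]] <- as.integer(cc)
  }
  out
}
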