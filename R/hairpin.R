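#' Excise candidate precursor windows around a mapped read
#'
#' Returns genome windows from which a hairpin precursor containing the
#' read could fold: the symmetric window extending \code{flank} nt on each
#' side of the read, plus two read-anchored sub-windows placing the read
#' near the 5' or the 3' arm. Windows are clipped at the contig bounds and
#' strand-corrected to the transcribed sequence.
#'
#' @param locus one-row data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{strand}; 0-based half-open) as returned by
#'   \code{\link{map_to_genome}}.
#' @param genome the reference sequence (character, optionally named).
#' @param flank nt of genomic context on each side.
#' @return A data.frame with \code{start}, \code{end} (0-based half-open),
#'   \code{strand} and \code{sequence} (transcribed orientation).
#' @export
excise_candidates <- function(locus, genome, flank = 150) {
  g <- unname(norm_dna(as.character(genome)[1]))
  glen <- nchar(g)
  if (locus$start < 0 || locus$end > glen) stop("locus outside genome bounds")
  s <- locus$start; e <- locus$end
  wins <- rbind(
    data.frame(start = s - flank, end = e + flank),        # symmetric
    data.frame(start = s - 15L,   end = e + flank),        # read on 5' arm
    data.frame(start = s - flank, end = e + 15L))          # read on 3' arm
  wins$start <- pmax(0L, as.integer(wins$start))
  wins$end <- pmin(glen, as.integer(wins$end))
  wins <- unique(wins)
  seqs <- substr(rep(g, nrow(wins)), wins$start + 1L, wins$end)
  if (locus$strand == "-") seqs <- revcomp(seqs)
  data.frame(start = wins$start, end = wins$end, strand = locus$strand,
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Evaluate a precursor window against plant miRNA hairpin criteria
#'
#' Folds the window and accepts it as a miRNA precursor if and only if all
#' of the following hold (checked in order; a rejection carries the first
#' failed criterion):
#' \describe{
#'   \item{arm}{the mature read lies entirely on one stem arm — no base
#'     pair joins two mature positions, and the mature is not fully
#'     unpaired;}
#'   \item{duplex}{the mature/star duplex has at most \code{max_mismatch}
#'     unpaired mature positions and at most \code{max_bulge} asymmetric
#'     bulged nucleotides (absolute difference between the mature and star
#'     spans of the duplex);}
#'   \item{mfe}{folding energy at most \code{mfe_max} kcal/mol;}
#'   \item{length}{mature length within \code{mature_len};}
#'   \item{reads}{mature read count (summed over libraries) at least
#'     \code{min_reads}.}
#' }
#' Star presence among sequenced reads is not required; the duplex
#' criterion operates on the predicted structure.
#'
#' @param window_seq precursor window sequence (transcribed orientation).
#' @param mature mature read sequence (must occur in the window).
#' @param mature_count read count of the mature read summed over libraries.
#' @param engine folding engine (see \code{\link{fold_rna}}).
#' @param mfe_max maximum folding energy (kcal/mol).
#' @param mature_len allowed mature length range.
#' @param max_mismatch maximum unpaired mature positions in the duplex.
#' @param max_bulge maximum asymmetric bulged nucleotides.
#' @param min_reads minimum mature read count.
#' @return A list of class \code{HairpinCandidate} with \code{accepted},
#'   \code{reason} (\code{NA} if accepted), \code{structure}, \code{mfe},
#'   \code{mature_start}/\code{mature_end} (0-based within the window),
#'   \code{arm} (\code{"5p"}/\code{"3p"}), \code{star_start}/\code{star_end}
#'   and \code{duplex_mismatches}.
#' @export
evaluate_hairpin <- function(window_seq, mature, mature_count,
                             engine = "auto", mfe_max = -18,
                             mature_len = c(20, 24), max_mismatch = 4,
                             max_bulge = 2, min_reads = 5) {
  window_seq <- norm_dna(window_seq)
  mature <- norm_dna(mature)
  res <- list(accepted = FALSE, reason = NA_character_, structure = NA,
              mfe = NA_real_, mature_start = NA_integer_,
              mature_end = NA_integer_, arm = NA_character_,
              star_start = NA_integer_, star_end = NA_integer_,
              duplex_mismatches = NA_real_)
  class(res) <- "HairpinCandidate"
  reject <- function(why) { res$reason <- why; res }

  pos <- regexpr(mature, window_seq, fixed = TRUE)
  if (pos < 0) stop("mature read does not occur in the window")
  L <- nchar(mature)
  mi <- as.integer(pos):(as.integer(pos) + L - 1L)   # 1-based positions
  res$mature_start <- as.integer(pos) - 1L
  res$mature_end <- res$mature_start + L

  f <- fold_rna(window_seq, engine = engine)
  res$structure <- f$structure
  res$mfe <- f$mfe
  pt <- pair_table(f$structure)

  partners <- pt[mi]
  paired <- partners > 0
  # (a) mature on one arm: no pair joins two mature positions
  if (any(partners %in% mi) || !any(paired)) return(reject("arm"))
  res$arm <- if (all(partners[paired] > max(mi))) "5p" else
    if (all(partners[paired] < min(mi))) "3p" else NA
  if (is.na(res$arm)) return(reject("arm"))

  # (b) mature/star duplex quality
  mm <- sum(!paired)
  res$duplex_mismatches <- mm
  star <- range(partners[paired])
  res$star_start <- star[1] - 1L
  res$star_end <- star[2]
  paired_span <- diff(range(mi[paired])) + 1L
  asym <- abs((star[2] - star[1] + 1L) - paired_span)
  if (mm > max_mismatch || asym > max_bulge) return(reject("duplex"))

  # (c) folding energy, (d) mature length, (e) expression support
  if (f$mfe > mfe_max) return(reject("mfe"))
  if (L < mature_len[1] || L > mature_len[2]) return(reject("length"))
  if (mature_count < min_reads) return(reject("reads"))

  res$accepted <- TRUE
  res
}

#' Name and deduplicate accepted novel miRNA candidates
#'
#' Candidates sharing a mature sequence collapse into one catalogue entry
#' listing all loci; entries are ordered by locus (chrom, start, strand)
#' then mature sequence, and named \code{novel_mir_1 ... novel_mir_N}, so
#' naming is reproducible for a fixed input.
#'
#' @param candidates data.frame with at least \code{mature}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} (plus any evidence columns,
#'   kept from the first locus).
#' @return The deduplicated catalogue with a \code{name} column and a
#'   \code{loci} column (semicolon-separated \code{chrom:start-end(strand)}).
#' @export
name_novel <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    out <- data.frame(name = character(), mature = character(),
                      loci = character(), stringsAsFactors = FALSE)
    return(out)
  }
  candidates <- candidates[order(candidates$chrom, candidates$start,
                                 candidates$strand, candidates$mature), ]
  first <- !duplicated(candidates$mature)
  loci_str <- tapply(
    sprintf("%s:%d-%d(%s)", candidates$chrom, candidates$start,
            candidates$end, candidates$strand),
    candidates$mature, paste, collapse = ";")
  out <- candidates[first, , drop = FALSE]
  out$loci <- as.character(loci_str[out$mature])
  out$name <- sprintf("novel_mir_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("name", setdiff(names(out), "name"))]
}

#' Predict novel miRNAs from unannotated genome-mapped reads
#'
#' Runs the full discovery procedure: unannotated sequences with enough
#' read support and an acceptable number of genomic loci are clustered by
#' locus; in each cluster the most abundant read is the mature candidate;
#' precursor windows are excised around it, folded, and evaluated under the
#' plant hairpin criteria; accepted candidates are deduplicated and named.
#'
#' @param annotation an \code{\link{classify}} result (or a list of them,
#'   one per library; counts are summed).
#' @param genome the reference sequence.
#' @param engine folding engine.
#' @param min_reads minimum mature read count summed over libraries.
#' @param max_hits sequences at this many or more genomic loci are excluded
#'   as repeat-derived.
#' @param flank precursor window flank (nt).
#' @param cluster_gap loci closer than this are clustered together (nt).
#' @param ... further criteria passed to \code{\link{evaluate_hairpin}}.
#' @return The \code{\link{name_novel}} catalogue with structure, energy
#'   and count evidence columns.
#' @export
predict_novel_mirnas <- function(annotation, genome, engine = "auto",
                                 min_reads = 5, max_hits = 25, flank = 150,
                                 cluster_gap = 50, ...) {
  if (inherits(annotation, "AnnotationTable")) annotation <- list(annotation)
  # pool unannotated sequences and their counts across libraries
  pool <- do.call(rbind, lapply(annotation, function(a)
    a$per_sequence[a$per_sequence$category == "unannotated" &
                     a$per_sequence$n_loci > 0 &
                     a$per_sequence$n_loci < max_hits,
                   c("sequence", "count")]))
  if (is.null(pool) || nrow(pool) == 0) return(name_novel(NULL))
  cnt <- tapply(pool$count, pool$sequence, sum)
  cand_seq <- names(cnt)[cnt >= min_reads]
  if (length(cand_seq) == 0) return(name_novel(NULL))

  loci <- do.call(rbind, lapply(annotation, function(a) a$loci))
  loci <- unique(loci[loci$sequence %in% cand_seq, ])
  if (nrow(loci) == 0) return(name_novel(NULL))
  loci$count <- as.integer(cnt[loci$sequence])

  # cluster loci along the genome; the most abundant read leads the cluster
  loci <- loci[order(loci$chrom, loci$strand, loci$start), ]
  brk <- c(TRUE, diff(loci$start) > cluster_gap |
             loci$chrom[-1] != loci$chrom[-nrow(loci)] |
             loci$strand[-1] != loci$strand[-nrow(loci)])
  loci$cluster <- cumsum(brk)

  rows <- list()
  for (cl in unique(loci$cluster)) {
    d <- loci[loci$cluster == cl, ]
    lead <- d[which.max(d$count), ]
    wins <- excise_candidates(lead, genome, flank = flank)
    # windows are strand-corrected to the transcribed sequence, which is
    # exactly what was sequenced: the read occurs verbatim in the window
    mature_w <- lead$sequence
    for (w in seq_len(nrow(wins))) {
      if (!grepl(mature_w, wins$sequence[w], fixed = TRUE)) next
      ev <- evaluate_hairpin(wins$sequence[w], mature_w, lead$count,
                             engine = engine, min_reads = min_reads, ...)
      if (ev$accepted) {
        rows[[length(rows) + 1]] <- data.frame(
          mature = lead$sequence, chrom = lead$chrom, start = lead$start,
          end = lead$end, strand = lead$strand, count = lead$count,
          precursor = wins$sequence[w], structure = ev$structure,
          mfe = ev$mfe, arm = ev$arm, stringsAsFactors = FALSE)
        break
      }
    }
  }
  name_novel(if (length(rows) > 0) do.call(rbind, rows) else NULL)
}
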