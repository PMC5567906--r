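#' Antisense duplex alignment of a miRNA against a transcript
#'
#' Scans every transcript window for the best gapped antisense alignment to
#' the miRNA (read 5' to 3'; miRNA position 1 pairs the 3'-most target base
#' of the window). Per-position classes are WC (Watson-Crick pair, weight
#' 0), GU (G-U wobble, weight 0.5), MM (mismatch, weight 1) or BULGE
#' (weight 1). At most one single-nucleotide bulge is allowed on either
#' strand, disallowed while flanking miRNA positions 2-12; a target-side
#' bulge is recorded against the 5'-flanking miRNA position. Windows whose
#' best mismatch score is at most \code{max_score} are returned.
#'
#' @param mirna miRNA sequence, 5' to 3' (18-26 nt).
#' @param transcript target transcript sequence (at least as long as the
#'   miRNA).
#' @param max_score maximum total mismatch score reported.
#' @param allow_bulge allow one single-nucleotide bulge.
#' @return A data.frame of class \code{DuplexAlignment} rows: \code{start},
#'   \code{end} (0-based half-open window on the transcript), \code{score},
#'   \code{classes} (string of W/G/M/B over miRNA positions 1..L),
#'   \code{bulge_side} (\code{"none"}, \code{"mirna"}, \code{"target"}) and
#'   \code{bulge_pos} (flanking miRNA position, 0 if none).
#' @export
duplex_align <- function(mirna, transcript, max_score = 4, allow_bulge = TRUE) {
  mirna <- norm_dna(mirna)
  transcript <- norm_dna(transcript)
  if (grepl("[^ACGT]", mirna) || grepl("[^ACGT]", transcript)) {
    stop("invalid nucleotide alphabet")
  }
  L <- nchar(mirna)
  if (L < 18 || L > 26) stop("miRNA length must be 18-26 nt")
  if (nchar(transcript) < L) stop("transcript shorter than the miRNA")
  hits <- cpp_duplex_scan(mirna, transcript, max_score = max_score,
                          allow_bulge = allow_bulge)
  hits$bulge_side <- c("none", "mirna", "target")[hits$bulge_side + 1L]
  class(hits) <- c("DuplexAlignment", "data.frame")
  hits
}

duplex_weights <- c(W = 0, G = 0.5, M = 1, B = 1)

#' Apply the six plant miRNA target-site rules to duplex alignments
#'
#' Rule flags over each alignment (G-U wobble weighs 0.5 towards scores but
#' counts as a mismatch event for the positional rules under the default
#' strict reading):
#' \enumerate{
#'   \item total mismatch score at most 4;
#'   \item no run of more than 2 consecutive non-WC positions anywhere;
#'   \item no two adjacent non-WC positions within miRNA positions 2-12;
#'   \item miRNA positions 10 and 11 both WC;
#'   \item mismatch score restricted to positions 1-12 at most 2.5;
#'   \item duplex free energy at least 75\% of the perfect-complement
#'     energy — set by \code{\link{duplex_energy}}, reported here as
#'     \code{NA} unless the alignment carries an \code{mfe_ratio} column.
#' }
#'
#' @param alignments a \code{\link{duplex_align}} result (one or more rows).
#' @param gu_as_adjacent_mismatch count G-U wobbles as mismatch events in
#'   rules 2-4 (strict reading, default) or as pairs.
#' @param max_total,max_run,max_5p thresholds of rules 1, 2 and 5.
#' @param mfe_ratio_min threshold of rule 6.
#' @return A data.frame of logical columns \code{flag1}..\code{flag6} plus
#'   \code{all_pass_1_5} and \code{accepted} (all six, \code{NA} when
#'   \code{flag6} is unknown).
#' @export
apply_rules <- function(alignments, gu_as_adjacent_mismatch = TRUE,
                        max_total = 4, max_run = 2, max_5p = 2.5,
                        mfe_ratio_min = 0.75) {
  n <- nrow(alignments)
  cls <- strsplit(alignments$classes, "")
  out <- data.frame(flag1 = logical(n), flag2 = logical(n),
                    flag3 = logical(n), flag4 = logical(n),
                    flag5 = logical(n), flag6 = rep(NA, n))
  for (i in seq_len(n)) {
    ch <- cls[[i]]
    L <- length(ch)
    w <- duplex_weights[ch]
    score <- alignments$score[i]
    ev <- ch != "W"
    if (!gu_as_adjacent_mismatch) ev <- !(ch %in% c("W", "G"))
    # a target-side bulge is an event (and a score unit) at its flanking
    # miRNA position
    tb <- alignments$bulge_side[i] == "target"
    if (tb) ev[alignments$bulge_pos[i]] <- TRUE
    runs <- rle(ev)
    out$flag1[i] <- score <= max_total
    out$flag2[i] <- !any(runs$values & runs$lengths > max_run)
    ix <- 2:min(11, L - 1)
    out$flag3[i] <- !any(ev[ix] & ev[ix + 1])
    out$flag4[i] <- L >= 11 && ch[10] == "W" && ch[11] == "W"
    s5 <- sum(w[seq_len(min(12, L))])
    if (tb && alignments$bulge_pos[i] <= 12) s5 <- s5 + 1
    out$flag5[i] <- s5 <= max_5p
  }
  if (!is.null(alignments$mfe_ratio)) {
    out$flag6 <- alignments$mfe_ratio >= mfe_ratio_min
  }
  out$all_pass_1_5 <- out$flag1 & out$flag2 & out$flag3 & out$flag4 & out$flag5
  out$accepted <- out$all_pass_1_5 & out$flag6
  out
}

#' Duplex free energy and the perfect-complement ratio
#'
#' Computes the free energy of the miRNA/target duplex, the energy of the
#' miRNA bound to its exact complement with the same engine, and their
#' ratio. Engines:
#' \describe{
#'   \item{\code{"paircount"}}{pseudo-energy -1.0 kcal/mol per Watson-Crick
#'     pair and -0.5 per G-U wobble of the aligned duplex; the perfect
#'     complement scores -L. Deterministic and alignment-faithful.}
#'   \item{\code{"vienna"}}{nearest-neighbour duplex MFE via the ViennaRNA
#'     \code{RNAduplex} tool (batched), when available.}
#' }
#'
#' @param mirna miRNA sequence.
#' @param target_window aligned target window sequence(s).
#' @param classes optional per-position class string(s) from
#'   \code{\link{duplex_align}} (required by the paircount engine; when
#'   missing, the best full-window alignment is recomputed).
#' @param engine \code{"paircount"} or \code{"vienna"}.
#' @return A data.frame with \code{duplex_mfe}, \code{perfect_mfe} and
#'   \code{mfe_ratio} (clamped to 0 when the duplex energy is positive).
#' @export
duplex_energy <- function(mirna, target_window, classes = NULL,
                          engine = c("paircount", "vienna")) {
  engine <- match.arg(engine)
  mirna <- norm_dna(mirna)
  L <- nchar(mirna)
  if (engine == "vienna") {
    if (!nzchar(Sys.which("RNAduplex"))) {
      stop("engine 'vienna' requested but RNAduplex was not found on the PATH")
    }
    dup <- rnaduplex_batch(rep(norm_rna(mirna), length(target_window)),
                           norm_rna(target_window))
    perf <- rnaduplex_batch(norm_rna(mirna), norm_rna(revcomp(mirna)))
    if (perf >= 0) stop("perfect-complement duplex has non-negative energy")
    ratio <- pmax(0, dup / perf)
    return(data.frame(duplex_mfe = dup, perfect_mfe = perf, mfe_ratio = ratio))
  }
  if (is.null(classes)) {
    classes <- vapply(target_window, function(w) {
      sc <- cpp_duplex_scan(mirna, w, max_score = 1e9, allow_bulge = TRUE)
      full <- sc[sc$start == 0 & sc$end == nchar(w), ]
      if (nrow(full) == 0) strrep("M", L) else full$classes[1]
    }, "", USE.NAMES = FALSE)
  }
  nW <- nchar(gsub("[^W]", "", classes))
  nG <- nchar(gsub("[^G]", "", classes))
  dup <- -(nW + 0.5 * nG)
  perf <- -L
  data.frame(duplex_mfe = dup, perfect_mfe = perf,
             mfe_ratio = pmax(0, dup / perf))
}

# batched RNAduplex energies for paired sequence vectors
rnaduplex_batch <- function(a, b) {
  input <- as.vector(rbind(a, b))
  out <- system2("RNAduplex", stdout = TRUE, stderr = FALSE, input = input)
  as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", out))
}

#' Predict miRNA target transcripts under the six-rule filter
#'
#' Aligns every miRNA against every transcript, applies the six target-site
#' rules, and reports all accepted hits (one row per miRNA x transcript x
#' window). miRNAs without any accepted hit are listed in the
#' \code{"no_target"} attribute.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param max_score alignment score cap (rule 1 threshold).
#' @param engine energy engine for rule 6 (see \code{\link{duplex_energy}}).
#' @param mfe_ratio_min rule 6 threshold.
#' @param gu_as_adjacent_mismatch see \code{\link{apply_rules}}.
#' @return A data.frame of accepted hits: \code{mirna}, \code{transcript},
#'   \code{start}, \code{end}, \code{score}, \code{classes},
#'   \code{mfe_ratio}; attribute \code{"no_target"} names target-less
#'   miRNAs.
#' @export
predict_targets <- function(mirnas, transcripts, max_score = 4,
                            engine = c("paircount", "vienna"),
                            mfe_ratio_min = 0.75,
                            gu_as_adjacent_mismatch = TRUE) {
  engine <- match.arg(engine)
  stopifnot(length(mirnas) > 0, length(transcripts) > 0)
  hits <- list()
  for (mn in names(mirnas)) {
    m <- norm_dna(mirnas[[mn]])
    for (tn in names(transcripts)) {
      tx <- norm_dna(transcripts[[tn]])
      if (nchar(tx) < nchar(m)) next
      aln <- duplex_align(m, tx, max_score = max_score)
      if (nrow(aln) == 0) next
      win <- substr(rep(tx, nrow(aln)), aln$start + 1L, aln$end)
      en <- duplex_energy(m, win, classes = aln$classes, engine = engine)
      aln$mfe_ratio <- en$mfe_ratio
      fl <- apply_rules(aln, gu_as_adjacent_mismatch = gu_as_adjacent_mismatch,
                        max_total = max_score, mfe_ratio_min = mfe_ratio_min)
      keep <- which(fl$accepted)
      if (length(keep) > 0) {
        hits[[length(hits) + 1]] <- data.frame(
          mirna = mn, transcript = tn,
          start = aln$start[keep], end = aln$end[keep],
          score = aln$score[keep], classes = aln$classes[keep],
          mfe_ratio = aln$mfe_ratio[keep], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(mirna = character(), transcript = character(),
               start = integer(), end = integer(), score = numeric(),
               classes = character(), mfe_ratio = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "no_target") <- setdiff(names(mirnas), unique(out$mirna))
  out
}
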