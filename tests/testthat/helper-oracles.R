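# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity from first principles with
# naive algorithms; they share no code with the package internals.

# --- maximum base pairing by plain memoized recursion ------------------
oracle_max_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  n <- length(s)
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  memo <- matrix(NA_integer_, n, n)
  f <- function(i, j) {
    if (i >= j || j - i <= min_loop) return(0L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- f(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (paste0(s[i], s[k]) %in% ok) {
        v <- 1L + (if (k - i > min_loop + 1L) f(i + 1L, k - 1L) else 0L) +
          (if (k < j) f(k + 1L, j) else 0L)
        if (v > best) best <- v
      }
    }
    memo[i, j] <<- best
    best
  }
  if (n < 2) 0L else f(1L, n)
}

# --- exact conditional count test by direct tail summation -------------
oracle_count_pvalue <- function(x, y, N1, N2) {
  r <- N2 / N1
  ymax <- max(ceiling(10 * (x + y + 1) * max(1, r)), y + 100)
  yy <- 0:ymax
  lp <- yy * log(r) + lgamma(x + yy + 1) - lgamma(x + 1) - lgamma(yy + 1) -
    (x + yy + 1) * log1p(r)
  P <- exp(lp)
  lo <- sum(P[yy <= y])
  up <- sum(P[yy >= y])
  min(1, 2 * min(lo, up))
}

# --- exhaustive per-window antisense duplex scoring --------------------
oracle_pair_class <- function(m, t) {
  key <- paste0(m, t)
  if (key %in% c("AT", "TA", "GC", "CG")) "W"
  else if (key %in% c("GT", "TG")) "G"
  else "M"
}

oracle_class_weight <- c(W = 0, G = 0.5, M = 1, B = 1)

# best alignment score at one window start (1-based s), enumerating the
# ungapped variant and every admissible single-nucleotide bulge placement
oracle_best_score <- function(m, tx, s, allow_bulge = TRUE) {
  L <- length(m); n <- length(tx)
  scores <- numeric(0)
  if (s + L - 1 <= n) {
    w <- tx[s:(s + L - 1)]
    cls <- vapply(1:L, function(i) oracle_pair_class(m[i], w[L - i + 1]), "")
    scores <- c(scores, sum(oracle_class_weight[cls]))
  }
  if (allow_bulge && s + L <= n) {
    w <- tx[s:(s + L)]
    for (k in setdiff(1:(L - 1), 1:12)) {
      cls <- vapply(1:L, function(i)
        oracle_pair_class(m[i], if (i <= k) w[L + 2 - i] else w[L + 1 - i]), "")
      scores <- c(scores, 1 + sum(oracle_class_weight[cls]))
    }
  }
  if (allow_bulge && s + L - 2 <= n) {
    w <- tx[s:(s + L - 2)]
    for (b in setdiff(1:L, 2:12)) {
      cls <- vapply(setdiff(1:L, b), function(i)
        oracle_pair_class(m[i], if (i < b) w[L - i] else w[L - i + 1]), "")
      scores <- c(scores, 1 + sum(oracle_class_weight[cls]))
    }
  }
  if (length(scores) == 0) Inf else min(scores)
}

oracle_duplex_hits <- function(mirna, transcript, max_score = 4,
                               allow_bulge = TRUE) {
  m <- strsplit(toupper(mirna), "")[[1]]
  tx <- strsplit(toupper(transcript), "")[[1]]
  L <- length(m); n <- length(tx)
  out <- data.frame(start = integer(), score = numeric())
  for (s in 1:(n - L + 1)) {
    sc <- oracle_best_score(m, tx, s, allow_bulge)
    if (sc <= max_score) {
      out <- rbind(out, data.frame(start = s - 1L, score = sc))
    }
  }
  out
}

# --- rule semantics re-derived from the stated criteria ----------------
oracle_rule_flags <- function(classes, score, bulge_side, bulge_pos) {
  ch <- strsplit(classes, "")[[1]]
  L <- length(ch)
  ev <- ch != "W"
  if (bulge_side == "target") ev[bulge_pos] <- TRUE
  w <- oracle_class_weight[ch]
  runlen <- 0; worst <- 0
  for (i in 1:L) { runlen <- if (ev[i]) runlen + 1 else 0; worst <- max(worst, runlen) }
  adj <- any(vapply(2:11, function(i) ev[i] && ev[i + 1], NA))
  s5 <- sum(w[1:12]) + (bulge_side == "target" && bulge_pos <= 12)
  c(flag1 = score <= 4, flag2 = worst <= 2, flag3 = !adj,
    flag4 = ch[10] == "W" && ch[11] == "W", flag5 = s5 <= 2.5)
}

# --- plain-interval exon/intron categorisation of a genome fragment ----
oracle_feature_category <- function(start0, width, strand, genes_df) {
  s <- start0 + 1; e <- start0 + width
  ov <- pmax(0, pmin(e, genes_df$end) - pmax(s, genes_df$start) + 1)
  if (all(ov == 0)) return("unannotated")
  wex <- sum(ov[genes_df$type == "exon"])
  win <- sum(ov[genes_df$type == "intron"])
  ty <- if (wex >= win) "exon" else "intron"
  sel <- which(genes_df$type == ty & ov > 0)
  sn <- genes_df$strand[sel[which.max(ov[sel])]] == strand
  paste0(ty, if (sn) "_sense" else "_antisense")
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE),
          collapse = ""), "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
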