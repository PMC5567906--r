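#' Simulation parameters for the synthetic small RNA study
#'
#' Builds the parameter object controlling the ground-truthed toy reference
#' and the two simulated libraries (callus tissue and freshly isolated
#' protoplasts). Defaults emulate an unreplicated two-library plant small
#' RNA experiment: reads are insert + 3' adapter concatenations with small,
#' known fractions of defective reads, ncRNA contamination, a large mass of
#' mRNA degradation fragments, and miRNA expression drawn from a
#' gamma-overdispersed (negative-binomial-like) model with planted log2
#' effects in the protoplast condition.
#'
#' @param seed integer seed; fixes the reference and both libraries.
#' @param n_reads_per_library reads per simulated library.
#' @param read_length raw read length in nt.
#' @param adapter3,adapter5 adapter sequences ligated 3' and 5' of the
#'   insert (defaults: classic Illumina small RNA adapters).
#' @param frac_low_quality,frac_no_3adapter,frac_insert_null,frac_5adapter_contaminant,frac_short,frac_polya
#'   fractions of reads planted into each defect category of the cleaning
#'   ledger (low quality; 3' adapter absent; empty insert / adapter dimer;
#'   5' adapter contamination; insert shorter than 18 nt; poly-A insert).
#' @param frac_ncrna,frac_degradation fractions of clean reads drawn from
#'   the rRNA/tRNA/snRNA/snoRNA reference sets and from random genome
#'   fragments (degraded mRNA / intergenic mass); the remainder of the
#'   library is miRNA reads.
#' @param expression_dispersion overdispersion of per-miRNA abundance
#'   between libraries (gamma variance; 0 = pure multinomial/Poisson).
#' @param planted_log2_effects named numeric vector of log2 fold effects
#'   applied to the protoplast condition, names matching miRNA names of the
#'   generated reference; \code{NULL} plants +3 on six and -3 on six of the
#'   known miRNAs.
#' @param genome_length toy chromosome length (nt).
#' @param n_known,n_novel numbers of planted miRNA precursors whose mature
#'   sequence is (known) or is not (novel) included in the mature catalogue.
#' @param n_ncrna_per_class,n_genes,n_transcripts sizes of the ncRNA,
#'   gene-model and transcript reference sets.
#' @param mean_weight_range log-uniform range of relative miRNA abundances.
#' @return An object of class \code{SimParams} (a validated list).
#' @export
sim_params <- function(seed = 1,
                       n_reads_per_library = 100000,
                       read_length = 50,
                       adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       frac_low_quality = 0.002,
                       frac_no_3adapter = 0.010,
                       frac_insert_null = 0.002,
                       frac_5adapter_contaminant = 0.005,
                       frac_short = 0.010,
                       frac_polya = 0.003,
                       frac_ncrna = 0.060,
                       frac_degradation = 0.650,
                       expression_dispersion = 0.15,
                       planted_log2_effects = NULL,
                       genome_length = 100000,
                       n_known = 20,
                       n_novel = 10,
                       n_ncrna_per_class = 4,
                       n_genes = 20,
                       n_transcripts = 20,
                       mean_weight_range = c(30, 3000)) {
  p <- list(seed = as.integer(seed),
            n_reads_per_library = as.integer(n_reads_per_library),
            read_length = as.integer(read_length),
            adapter3 = norm_dna(adapter3), adapter5 = norm_dna(adapter5),
            frac_low_quality = frac_low_quality,
            frac_no_3adapter = frac_no_3adapter,
            frac_insert_null = frac_insert_null,
            frac_5adapter_contaminant = frac_5adapter_contaminant,
            frac_short = frac_short, frac_polya = frac_polya,
            frac_ncrna = frac_ncrna, frac_degradation = frac_degradation,
            expression_dispersion = expression_dispersion,
            planted_log2_effects = planted_log2_effects,
            genome_length = as.integer(genome_length),
            n_known = as.integer(n_known), n_novel = as.integer(n_novel),
            n_ncrna_per_class = as.integer(n_ncrna_per_class),
            n_genes = as.integer(n_genes),
            n_transcripts = as.integer(n_transcripts),
            mean_weight_range = mean_weight_range)
  fr <- unlist(p[grep("^frac_", names(p))])
  if (any(fr < 0) || any(fr > 1) || sum(fr) >= 1) {
    stop("contamination fractions must lie in [0,1] and sum to < 1")
  }
  if (p$n_reads_per_library <= 0) stop("n_reads_per_library must be > 0")
  if (!nzchar(p$adapter3) || !nzchar(p$adapter5)) stop("adapters must be non-empty")
  if (p$expression_dispersion < 0) stop("expression_dispersion must be >= 0")
  structure(p, class = "SimParams")
}

# run code with a derived seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

# place n non-overlapping intervals of the given widths on [1, glen]
place_intervals <- function(widths, glen, occupied = NULL, gap = 50) {
  starts <- integer(length(widths))
  occ_s <- occ_e <- integer(0)
  if (!is.null(occupied)) { occ_s <- occupied$start; occ_e <- occupied$end }
  for (i in seq_along(widths)) {
    w <- widths[i]
    for (try in 1:500) {
      s <- sample.int(glen - w - gap, 1L)
      e <- s + w - 1L
      if (!any(s <= occ_e + gap & e >= occ_s - gap)) break
      if (try == 500) stop("could not place interval; genome too crowded")
    }
    starts[i] <- s
    occ_s <- c(occ_s, s); occ_e <- c(occ_e, e)
  }
  data.frame(start = starts, end = starts + widths - 1L)
}

mutate_bases <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a ground-truthed toy reference bundle
#'
#' Builds a single toy chromosome carrying planted miRNA hairpin precursors
#' and exon/intron gene models, plus mature miRNA, ncRNA, and transcript
#' reference sets. Every mature miRNA occurs verbatim in exactly one arm of
#' exactly one planted precursor; a subset of precursors is withheld from the
#' mature catalogue so that novel miRNA discovery has a measurable ground
#' truth. Planted transcript target sites satisfy the package's six-rule
#' target filter by construction (asserted at build time).
#'
#' @param params a \code{\link{sim_params}} object.
#' @return An object of class \code{ReferenceBundle}: a list with elements
#'   \code{genome} (character), \code{mature_mirnas} (named character, the
#'   known catalogue), \code{families} (named character), \code{precursors}
#'   (data.frame: name, chrom, start, end, strand, arm, mature, star,
#'   sequence, known; coordinates 0-based half-open), \code{ncrna} (named
#'   list of named character vectors for rRNA/tRNA/snRNA/snoRNA),
#'   \code{genes} (GRanges of exons and introns), \code{transcripts}
#'   (named character), \code{target_sites} (data.frame) and
#'   \code{truth_expr} (data.frame: mirna, known, base_weight, log2_effect).
#' @export
generate_reference <- function(params = sim_params()) {
  stopifnot(inherits(params, "SimParams"))
  with_seed(params$seed, {
    n_mir <- params$n_known + params$n_novel
    glen <- params$genome_length

    # --- mature miRNAs with family structure (letter-suffixed members)
    n_fam <- max(1L, ceiling(params$n_known * 0.6))
    fam_of <- sort(c(seq_len(n_fam),
                     sample.int(n_fam, params$n_known - n_fam, replace = TRUE)))
    memb <- stats::ave(fam_of, fam_of, FUN = seq_along)
    known_names <- sprintf("sim-miR%03d%s", fam_of, letters[memb])
    novel_names <- sprintf("sim-candidate-%02d", seq_len(params$n_novel))
    mir_names <- c(known_names, novel_names)
    families <- c(sprintf("miR%03d", fam_of), rep(NA_character_, params$n_novel))
    names(families) <- mir_names

    repeat {
      lens <- sample(20:24, n_mir, replace = TRUE,
                     prob = c(0.15, 0.35, 0.20, 0.05, 0.25))
      matures <- vapply(lens, function(l) rand_dna(1, l), "")
      ok <- !anyDuplicated(matures) &&
        all(polya_fraction(matures) < 0.8) &&
        !any(cpp_contains_pattern(matures, substr(params$adapter5, 1, 10), 1L))
      if (ok) break
    }
    names(matures) <- mir_names

    # --- precursors: ext5 + [mature|star] + loop + [star|mature] + rc(ext5)
    prec <- lapply(seq_len(n_mir), function(i) {
      mat <- matures[i]
      L <- nchar(mat)
      ext <- rand_dna(1, sample(8:12, 1))
      loop <- rand_dna(1, sample(10:15, 1))
      n_mm <- sample(0:2, 1)
      star <- revcomp(mat)
      if (n_mm > 0) star <- mutate_bases(star, sample(4:(L - 4), n_mm))
      arm <- sample(c("5p", "3p"), 1)
      seqs <- if (arm == "5p") c(ext, mat, loop, star, revcomp(ext))
              else c(ext, star, loop, mat, revcomp(ext))
      list(sequence = paste(seqs, collapse = ""), arm = arm, star = star,
           mature_off = if (arm == "5p") nchar(ext)
                        else nchar(ext) + nchar(star) + nchar(loop))
    })
    prec_len <- vapply(prec, function(p) nchar(p$sequence), 0L)

    # --- genome layout: genes first, then precursors in the gaps
    gene_w <- sample(800:1600, params$n_genes, replace = TRUE)
    gene_iv <- place_intervals(gene_w, glen)
    prec_iv <- place_intervals(prec_len, glen, occupied = gene_iv)

    genome <- rand_dna(1, glen)
    strands <- sample(c("+", "-"), n_mir, replace = TRUE)
    for (i in seq_len(n_mir)) {
      s <- prec_iv$start[i]
      ins <- if (strands[i] == "+") prec[[i]]$sequence else revcomp(prec[[i]]$sequence)
      substr(genome, s, s + prec_len[i] - 1L) <- ins
    }

    precursors <- data.frame(
      name = mir_names,
      chrom = "chr1",
      start = prec_iv$start - 1L,             # 0-based half-open
      end = prec_iv$start - 1L + prec_len,
      strand = strands,
      arm = vapply(prec, `[[`, "", "arm"),
      mature = unname(matures),
      star = vapply(prec, `[[`, "", "star"),
      mature_offset = vapply(prec, `[[`, 0, "mature_off"),
      sequence = vapply(prec, `[[`, "", "sequence"),
      known = c(rep(TRUE, params$n_known), rep(FALSE, params$n_novel)),
      stringsAsFactors = FALSE)

    # --- gene models: alternating exons/introns inside each gene interval
    gr_list <- lapply(seq_len(params$n_genes), function(g) {
      s <- gene_iv$start[g]; e <- gene_iv$end[g]
      n_ex <- sample(2:4, 1)
      cuts <- sort(sample(seq(s + 100, e - 100, by = 10), 2 * n_ex - 2))
      bounds <- c(s, cuts, e)
      types <- rep(c("exon", "intron"), length.out = 2 * n_ex - 1)
      GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = bounds[-length(bounds)] + c(0, rep(1, length(bounds) - 2)),
                         end = bounds[-1]),
        strand = sample(c("+", "-"), 1),
        type = types, gene_id = sprintf("gene%02d", g))
    })
    genes <- suppressWarnings(do.call(c, gr_list))

    # --- ncRNA reference sets (absent from the genome by construction:
    #     independent random sequences; collision with a 100 kb genome at
    #     60+ nt is vanishingly unlikely)
    classes <- c("rRNA", "tRNA", "snRNA", "snoRNA")
    ncrna <- lapply(classes, function(cl) {
      s <- rand_dna(params$n_ncrna_per_class, sample(60:120, 1))
      names(s) <- sprintf("%s_%02d", cl, seq_along(s))
      s
    })
    names(ncrna) <- classes

    # --- transcripts with planted target sites
    transcripts <- rand_dna(params$n_transcripts, 1)
    transcripts <- vapply(sample(400:800, params$n_transcripts, replace = TRUE),
                          function(l) rand_dna(1, l), "")
    names(transcripts) <- sprintf("tx%02d", seq_len(params$n_transcripts))
    n_sites <- min(params$n_transcripts, n_mir, 12L)
    site_mir <- seq_len(n_sites)          # first miRNAs get a planted site
    target_sites <- data.frame(mirna = character(), transcript = character(),
                               start = integer(), end = integer(),
                               stringsAsFactors = FALSE)
    for (k in seq_len(n_sites)) {
      i <- site_mir[k]
      mat <- matures[i]; L <- nchar(mat)
      site <- revcomp(mat)                # perfect antisense site
      # half the sites carry one G.U wobble in the 3' half of the miRNA
      # (outside positions 2-12 and the 10-11 cleavage-site positions)
      if (k %% 2 == 0) {
        mch <- strsplit(mat, "")[[1]]
        cand <- which(mch %in% c("T", "G"))
        cand <- cand[cand >= 13 & cand < L]
        if (length(cand) > 0) {
          i_m <- cand[1]
          sch <- strsplit(site, "")[[1]]
          # miRNA position i pairs site position L - i + 1
          sch[L - i_m + 1] <- if (mch[i_m] == "T") "G" else "T"
          site <- paste(sch, collapse = "")
        }
      }
      tx <- names(transcripts)[k]
      pos <- sample(seq(50, nchar(transcripts[tx]) - L - 50), 1)
      substr(transcripts[tx], pos, pos + L - 1L) <- site
      target_sites <- rbind(target_sites, data.frame(
        mirna = mir_names[i], transcript = tx, start = pos - 1L,
        end = pos - 1L + L, stringsAsFactors = FALSE))
    }

    # --- expression truth: log-uniform base weights; planted effects
    w <- exp(runif(n_mir, log(params$mean_weight_range[1]),
                   log(params$mean_weight_range[2])))
    effects <- params$planted_log2_effects
    if (is.null(effects)) {
      n_eff <- min(12L, params$n_known)
      effects <- setNames(rep(c(3, -3), length.out = n_eff),
                          known_names[seq_len(n_eff)])
    }
    eff_vec <- setNames(rep(0, n_mir), mir_names)
    if (length(effects)) {
      unknown <- setdiff(names(effects), mir_names)
      if (length(unknown)) stop("planted_log2_effects names not in reference: ",
                                paste(unknown, collapse = ", "))
      eff_vec[names(effects)] <- effects
      # planted-effect miRNAs get solidly measurable abundance
      w[match(names(effects), mir_names)] <-
        exp(runif(length(effects), log(300), log(params$mean_weight_range[2])))
    }
    truth_expr <- data.frame(mirna = mir_names, known = precursors$known,
                             base_weight = w, log2_effect = unname(eff_vec),
                             stringsAsFactors = FALSE)

    bundle <- structure(list(
      genome = genome,
      mature_mirnas = matures[seq_len(params$n_known)],
      novel_mirnas = matures[params$n_known + seq_len(params$n_novel)],
      families = families,
      precursors = precursors,
      ncrna = ncrna,
      genes = genes,
      transcripts = transcripts,
      target_sites = target_sites,
      truth_expr = truth_expr), class = "ReferenceBundle")
    validate_bundle(bundle)
    bundle
  })
}

# construction-time checks of the ReferenceBundle invariants
validate_bundle <- function(bundle) {
  pr <- bundle$precursors
  all_mat <- c(bundle$mature_mirnas, bundle$novel_mirnas)
  for (i in seq_len(nrow(pr))) {
    hits <- vapply(pr$sequence, function(s) grepl(pr$mature[i], s, fixed = TRUE), NA)
    if (sum(hits) != 1) stop("mature ", pr$name[i],
                             " does not occur in exactly one precursor")
    # precursor sequence recoverable from the genome at its locus
    g <- substr(bundle$genome, pr$start[i] + 1L, pr$end[i])
    if (pr$strand[i] == "-") g <- revcomp(g)
    if (g != pr$sequence[i]) stop("precursor ", pr$name[i],
                                  " not recoverable from genome locus")
  }
  ex <- bundle$genes[bundle$genes$type == "exon"]
  intr <- bundle$genes[bundle$genes$type == "intron"]
  for (g in unique(bundle$genes$gene_id)) {
    ov <- GenomicRanges::countOverlaps(ex[ex$gene_id == g],
                                       intr[intr$gene_id == g])
    if (any(ov > 0)) stop("exons of ", g, " overlap its introns")
  }
  if (max(GenomicRanges::end(bundle$genes)) > nchar(bundle$genome)) {
    stop("gene models exceed genome bounds")
  }
  # planted target sites must pass the six-rule filter by construction
  for (i in seq_len(nrow(bundle$target_sites))) {
    ts <- bundle$target_sites[i, ]
    mat <- all_mat[[ts$mirna]]
    win <- substr(bundle$transcripts[[ts$transcript]], ts$start + 1L, ts$end)
    aln <- duplex_align(mat, win)
    ok <- nrow(aln) > 0 && any(aln$start == 0 &
      apply_rules(aln[aln$start == 0, ][1, ])$all_pass_1_5)
    if (!ok) stop("planted target site for ", ts$mirna, " fails the rule filter")
  }
  invisible(bundle)
}

# sample a read insert as a random substring of one of `refs`
sample_fragments <- function(refs, n, len_range = c(18L, 30L), len_prob = NULL) {
  if (n == 0) {
    return(list(frag = character(0), ref = integer(0), start = integer(0)))
  }
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE, prob = len_prob)
  ref_i <- sample.int(length(refs), n, replace = TRUE)
  rl <- nchar(refs)[ref_i]
  lens <- pmin(lens, rl)
  starts <- 1L + floor(runif(n) * (rl - lens + 1L))
  frag <- substr(rep(refs[ref_i], 1), starts, starts + lens - 1L)
  list(frag = frag, ref = ref_i, start = starts)
}

#' Simulate one raw small RNA library
#'
#' Draws \code{n_reads_per_library} reads for one condition. Per-miRNA
#' counts are independent gamma-Poisson (negative binomial) draws around
#' means set by the reference base weights, with the planted log2 effects
#' applied to the \code{"protoplasts"} condition; the rest of the library
#' (defects, ncRNA contamination, degradation fragments) fills the
#' remaining reads at the configured relative fractions, so planting an
#' effect never distorts the other species. Reads are insert + 3' adapter,
#' padded to the read length; defective reads are constructed so that each
#' lands in its intended ledger category under the package's own cleaning
#' rules (verified by rejection sampling against those rules).
#'
#' @param bundle a \code{\link{generate_reference}} bundle.
#' @param params the same \code{\link{sim_params}} object.
#' @param condition \code{"calli"} or \code{"protoplasts"}.
#' @return An object of class \code{SimulatedLibrary}: list with
#'   \code{reads}, \code{qualities} (character vectors), \code{condition},
#'   and \code{truth} (category counts, per-miRNA realized counts, per-class
#'   ncRNA counts, and degradation read origins).
#' @export
simulate_library <- function(bundle, params, condition = c("calli", "protoplasts")) {
  stopifnot(inherits(bundle, "ReferenceBundle"), inherits(params, "SimParams"))
  condition <- match.arg(condition)
  if (params$n_reads_per_library <= 0) stop("n_reads_per_library must be > 0")
  seed_off <- if (condition == "calli") 1L else 2L

  with_seed(params$seed * 31L + seed_off, {
    n <- params$n_reads_per_library
    rl <- params$read_length
    a3 <- params$adapter3
    cats <- c(low_quality = params$frac_low_quality,
              no_3adapter = params$frac_no_3adapter,
              insert_null = params$frac_insert_null,
              contaminant_5adapter = params$frac_5adapter_contaminant,
              shorter_than_18 = params$frac_short,
              poly_a = params$frac_polya,
              ncrna = params$frac_ncrna,
              degradation = params$frac_degradation)

    # --- per-miRNA counts: independent gamma-Poisson (negative binomial)
    # draws, so a planted fold effect changes that miRNA's reads without
    # compositionally distorting the rest of the library; base weights are
    # scaled so the calli miRNA mass matches the configured remainder
    # one scale factor shared by both conditions (computed from whichever
    # condition carries more miRNA mass), so planted fold changes are exact
    # and the miRNA mass can never outgrow the library
    te <- bundle$truth_expr
    w_calli <- sum(te$base_weight)
    w_proto <- sum(te$base_weight * 2^te$log2_effect)
    s <- (1 - sum(cats)) * n / max(w_calli, w_proto)
    lam <- te$base_weight * s
    if (condition == "protoplasts") lam <- lam * 2^te$log2_effect
    disp <- params$expression_dispersion
    g <- if (disp > 0) rgamma(nrow(te), shape = 1 / disp, scale = disp)
         else rep(1, nrow(te))
    mir_counts <- stats::rpois(nrow(te), lam * g)
    n_mirna <- sum(mir_counts)
    if (n_mirna >= n) stop("miRNA draws exceed the library size")
    mirna_counts <- data.frame(mirna = te$mirna, known = te$known,
                               count = mir_counts, stringsAsFactors = FALSE)

    # remaining reads split across the defect/contaminant/degradation
    # categories at their relative fractions
    counts <- drop(rmultinom(1, n - n_mirna, cats / sum(cats)))
    names(counts) <- names(cats)
    counts <- c(counts, mirna = n_mirna)

    pad <- function(ins) {
      r <- paste0(ins, a3)
      short <- nchar(r) < rl
      if (any(short)) {
        r[short] <- vapply(r[short], function(x)
          paste0(x, paste(rep("A", rl - nchar(x)), collapse = "")), "")
      }
      substr(r, 1, rl)
    }

    # genome-sense mature sequences (reads come off the transcribed strand,
    # which is the precursor sequence itself)
    mir_reads <- pad(rep(bundle$precursors$mature, mir_counts))

    # degradation: random genome fragments, 24 nt most abundant as in real
    # plant sRNA length profiles
    len_prob <- c(2, 2, 3, 4, 5, 8, 14, 6, 4, 3, 2, 2, 2)  # lengths 18..30
    deg <- sample_fragments(bundle$genome, counts[["degradation"]],
                            len_prob = len_prob / sum(len_prob))
    deg_strand <- sample(c("+", "-"), counts[["degradation"]], replace = TRUE)
    deg_ins <- ifelse(deg_strand == "+", deg$frag, revcomp(deg$frag))
    deg_start <- deg$start
    # degradation inserts must land in the clean bucket with their own
    # identity: no accidental 5' adapter contamination or poly-A calls, and
    # no exact coincidence with a planted mature (fragments can sample the
    # precursor arms, which live in the genome)
    bad_insert <- function(ins)
      cpp_contains_pattern(ins, substr(params$adapter5, 1, 10), 1L) |
        polya_fraction(ins) >= 0.8 |
        ins %in% bundle$precursors$mature
    redo <- bad_insert(deg_ins)
    for (it in 1:20) {
      if (!any(redo)) break
      k <- sum(redo)
      d2 <- sample_fragments(bundle$genome, k, len_prob = len_prob / sum(len_prob))
      s2 <- sample(c("+", "-"), k, replace = TRUE)
      deg_ins[redo] <- ifelse(s2 == "+", d2$frag, revcomp(d2$frag))
      deg_start[redo] <- d2$start; deg_strand[redo] <- s2
      redo <- bad_insert(deg_ins)
    }
    deg_reads <- pad(deg_ins)
    deg_origin <- data.frame(start = deg_start - 1L,
                             width = nchar(deg_ins),
                             strand = deg_strand, stringsAsFactors = FALSE)

    # ncRNA contamination: fragments of the ncRNA reference sets
    all_nc <- unlist(bundle$ncrna)
    nc_class <- rep(names(bundle$ncrna), vapply(bundle$ncrna, length, 0L))
    nc <- sample_fragments(all_nc, counts[["ncrna"]])
    nc_ins <- nc$frag
    nc_ref <- nc$ref
    redo <- bad_insert(nc_ins)
    for (it in 1:20) {
      if (!any(redo)) break
      n2 <- sample_fragments(all_nc, sum(redo))
      nc_ins[redo] <- n2$frag; nc_ref[redo] <- n2$ref
      redo <- bad_insert(nc_ins)
    }
    nc_reads <- pad(nc_ins)
    ncrna_class_counts <- table(factor(nc_class[nc_ref], levels = names(bundle$ncrna)))

    # defect categories, constructed to match the cleaning rules exactly
    mk_no3ad <- function(k) {
      out <- rand_dna(k, rl)
      for (it in 1:50) {
        bad <- cpp_find_adapter(out, a3, 6L, 1L) >= 0
        if (!any(bad)) break
        out[bad] <- rand_dna(sum(bad), rl)
      }
      out
    }
    no3ad_reads <- mk_no3ad(counts[["no_3adapter"]])
    null_reads <- pad(rep("", counts[["insert_null"]]))
    contam_reads <- pad(paste0(substr(params$adapter5, 1, 12),
                               rand_dna(counts[["contaminant_5adapter"]], 8)))
    mk_short <- function(k) {
      if (k == 0) return(character(0))
      f <- sample_fragments(bundle$genome, k, len_range = c(10L, 17L))$frag
      for (it in 1:20) {
        bad <- cpp_contains_pattern(f, substr(params$adapter5, 1, 10), 1L)
        if (!any(bad)) break
        f[bad] <- sample_fragments(bundle$genome, sum(bad),
                                   len_range = c(10L, 17L))$frag
      }
      pad(f)
    }
    short_reads <- mk_short(counts[["shorter_than_18"]])
    polya_reads <- pad(vapply(sample(20:24, counts[["poly_a"]], replace = TRUE),
                              function(l) paste(rep("A", l), collapse = ""), ""))
    # low-quality reads: a clean-looking insert with one N planted
    lowq_reads <- pad(sample_fragments(bundle$genome, counts[["low_quality"]],
                                       len_range = c(18L, 30L))$frag)
    if (counts[["low_quality"]] > 0) {
      npos <- sample.int(rl, counts[["low_quality"]], replace = TRUE)
      substr(lowq_reads, npos, npos) <- "N"
    }

    reads <- c(mir_reads, deg_reads, nc_reads, no3ad_reads, null_reads,
               contam_reads, short_reads, polya_reads, lowq_reads)
    ord <- sample.int(length(reads))
    reads <- reads[ord]
    qualities <- strrep("I", rl)[rep(1, length(reads))]

    structure(list(
      reads = reads,
      qualities = qualities,
      condition = condition,
      truth = list(category_counts = counts,
                   mirna_counts = mirna_counts,
                   ncrna_class_counts = as.integer(ncrna_class_counts),
                   ncrna_classes = names(bundle$ncrna),
                   degradation_origin = deg_origin)),
      class = "SimulatedLibrary")
  })
}

polya_fraction <- function(x) {
  n <- nchar(x)
  a <- nchar(gsub("[^Aa]", "", x))
  ifelse(n == 0, 0, a / n)
}

#' Write a reference bundle and simulated libraries to disk
#'
#' Writes the standard file set: \code{genome.fa}, \code{mature.fa},
#' \code{ncrna_<class>.fa}, \code{transcripts.fa}, \code{genes.gff} (GFF3,
#' 1-based closed intervals), \code{reads_<condition>.fastq} (Phred33) and
#' \code{truth.tsv}.
#'
#' @param bundle a \code{ReferenceBundle}.
#' @param outdir output directory (created if needed).
#' @param libraries optional named list of \code{SimulatedLibrary} objects.
#' @return Invisibly, the vector of written paths.
#' @export
write_reference_bundle <- function(bundle, outdir, libraries = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wfa <- function(seqs, file) {
    p <- file.path(outdir, file)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), p)
    p
  }
  paths <- c(paths, wfa(c(chr1 = bundle$genome), "genome.fa"))
  paths <- c(paths, wfa(bundle$mature_mirnas, "mature.fa"))
  for (cl in names(bundle$ncrna)) {
    paths <- c(paths, wfa(bundle$ncrna[[cl]], sprintf("ncrna_%s.fa", tolower(cl))))
  }
  paths <- c(paths, wfa(bundle$transcripts, "transcripts.fa"))
  gff <- file.path(outdir, "genes.gff")
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    rtracklayer::export(bundle$genes, gff, format = "gff3")
  } else {
    df <- as.data.frame(bundle$genes)
    lines <- sprintf("chr1\tprotomir\t%s\t%d\t%d\t.\t%s\t.\tID=%s_%d;Parent=%s",
                     df$type, df$start, df$end, df$strand, df$type,
                     seq_len(nrow(df)), df$gene_id)
    writeLines(c("##gff-version 3", lines), gff)
  }
  paths <- c(paths, gff)
  tp <- file.path(outdir, "truth.tsv")
  write.table(bundle$truth_expr, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, tp)
  for (cond in names(libraries)) {
    lib <- libraries[[cond]]
    fq <- file.path(outdir, sprintf("reads_%s.fastq", cond))
    write_fastq(lib$reads, lib$qualities, fq)
    paths <- c(paths, fq)
  }
  invisible(paths)
}

write_fastq <- function(reads, qualities, path) {
  ids <- sprintf("@read%d", seq_along(reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ids, reads, "+", qualities, sep = "\n"), con)
  invisible(path)
}
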