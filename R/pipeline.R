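#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default. The
#' effective configuration of a run is archived as YAML alongside the
#' outputs, so any run is reproducible from its output directory.
#'
#' @param outdir output directory.
#' @param sim a \code{\link{sim_params}} object (the synthetic study
#'   design; also carries the seed).
#' @param min_len,max_len insert length window (nt).
#' @param engine folding engine for hairpin discovery.
#' @param min_reads,max_hits,flank novel miRNA discovery parameters.
#' @param fc_cut,p_cut DEM thresholds (log2 units; inclusive p cut).
#' @param tpm_floor low-expression TPM floor.
#' @param target_max_score,mfe_ratio_min target-filter thresholds.
#' @param normalize_by \code{"clean"} (total clean reads) or
#'   \code{"mirna"} (total miRNA-matched reads) library-size convention.
#' @return A list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(outdir = tempfile("protomir_run_"),
                            sim = sim_params(),
                            min_len = 18, max_len = 30,
                            engine = "auto",
                            min_reads = 5, max_hits = 25, flank = 150,
                            fc_cut = 1, p_cut = 0.01, tpm_floor = 0.01,
                            target_max_score = 4, mfe_ratio_min = 0.75,
                            normalize_by = c("clean", "mirna")) {
  structure(list(outdir = outdir, sim = sim, min_len = min_len,
                 max_len = max_len, engine = engine, min_reads = min_reads,
                 max_hits = max_hits, flank = flank, fc_cut = fc_cut,
                 p_cut = p_cut, tpm_floor = tpm_floor,
                 target_max_score = target_max_score,
                 mfe_ratio_min = mfe_ratio_min,
                 normalize_by = match.arg(normalize_by)),
            class = "PipelineConfig")
}

#' Run the full small RNA pipeline on simulated libraries
#'
#' Executes the stages in order: simulate (reference bundle and the callus
#' and protoplast libraries) -> clean (ledger per library) -> annotate ->
#' known miRNA quantification -> novel miRNA discovery -> differential
#' expression -> target prediction of the differentially expressed miRNAs.
#' Per-stage tables are written as TSV under \code{config$outdir}, together
#' with the effective configuration (\code{config.yaml}).
#'
#' @param config a \code{\link{pipeline_config}} object.
#' @param write write stage outputs to \code{config$outdir}.
#' @return A run summary list: \code{bundle}, \code{ledgers},
#'   \code{profiles}, \code{annotations}, \code{known}, \code{novel},
#'   \code{dems}, \code{targets}, \code{length_dist}.
#' @export
run_pipeline <- function(config = pipeline_config(), write = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  conds <- c("calli", "protoplasts")

  bundle <- generate_reference(config$sim)
  libs <- lapply(setNames(conds, conds), function(cond)
    simulate_library(bundle, config$sim, cond))

  cleaned <- lapply(libs, function(lib)
    clean_reads(lib, adapter3 = config$sim$adapter3,
                adapter5 = config$sim$adapter5,
                min_len = config$min_len, max_len = config$max_len))
  profiles <- lapply(cleaned, `[[`, "profile")
  ledgers <- lapply(cleaned, `[[`, "ledger")

  annotations <- lapply(profiles, classify, refs = bundle,
                        max_hits = config$max_hits)

  known <- identify_known_mirnas(profiles, bundle$mature_mirnas)

  novel <- predict_novel_mirnas(annotations, bundle$genome,
                                engine = config$engine,
                                min_reads = config$min_reads,
                                max_hits = config$max_hits,
                                flank = config$flank)
  # attach per-library counts for the novel catalogue
  for (cond in conds) {
    ix <- match(novel$mature, names(profiles[[cond]]$seq_counts))
    novel[[paste0("count_", cond)]] <-
      ifelse(is.na(ix), 0L, unname(profiles[[cond]]$seq_counts)[ix])
  }

  if (config$normalize_by == "clean") {
    N1 <- profiles$calli$total_clean
    N2 <- profiles$protoplasts$total_clean
  } else {
    N1 <- sum(known$count_calli, novel$count_calli)
    N2 <- sum(known$count_protoplasts, novel$count_protoplasts)
  }
  catalog <- rbind(
    known[, c("name", "count_calli", "count_protoplasts")],
    if (nrow(novel) > 0)
      novel[, c("name", "count_calli", "count_protoplasts")])
  dems <- call_dems(catalog, N1 = N1, N2 = N2, fc_cut = config$fc_cut,
                    p_cut = config$p_cut, floor = config$tpm_floor)

  # targets of the differentially expressed miRNAs only, as in a two-library
  # response study
  dem_names <- dems$name[dems$status != "unchanged"]
  mir_seqs <- c(setNames(known$mature, known$name),
                if (nrow(novel) > 0) setNames(novel$mature, novel$name))
  dem_seqs <- mir_seqs[names(mir_seqs) %in% dem_names]
  targets <- if (length(dem_seqs) > 0) {
    predict_targets(dem_seqs, bundle$transcripts,
                    max_score = config$target_max_score,
                    mfe_ratio_min = config$mfe_ratio_min)
  } else {
    structure(data.frame(mirna = character(), transcript = character(),
                         start = integer(), end = integer(),
                         score = numeric(), classes = character(),
                         mfe_ratio = numeric(), stringsAsFactors = FALSE),
              no_target = character(0))
  }

  summary <- list(bundle = bundle, ledgers = ledgers, profiles = profiles,
                  annotations = annotations, known = known, novel = novel,
                  dems = dems, targets = targets,
                  length_dist = lapply(profiles, length_distribution))

  if (write) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) write.table(x, file.path(config$outdir, f),
                                     sep = "\t", quote = FALSE,
                                     row.names = FALSE)
    wt(ledger_table(calli = ledgers$calli, protoplasts = ledgers$protoplasts),
       "ledger.tsv")
    for (cond in conds) {
      wt(annotations[[cond]]$summary, sprintf("annotation_%s.tsv", cond))
      wt(summary$length_dist[[cond]], sprintf("length_dist_%s.tsv", cond))
      write_profile_fasta(profiles[[cond]],
                          file.path(config$outdir,
                                    sprintf("clean_%s.fa", cond)))
    }
    wt(known, "known_mirnas.tsv")
    wt(novel, "novel_mirnas.tsv")
    write_dem_table(dems, file.path(config$outdir, "dem.tsv"))
    wt(targets, "targets.tsv")
    cfg <- config
    cfg$sim <- unclass(cfg$sim)
    yaml::write_yaml(unclass(cfg), file.path(config$outdir, "config.yaml"))
  }
  invisible(summary)
}
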