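#' TPM normalisation with a low-expression floor
#'
#' \code{TPM = 1e6 * count / library_total}; results below the floor
#' (including zero counts) are replaced by the floor so that fold changes
#' stay finite for miRNAs absent from one library.
#'
#' @param count non-negative read count(s).
#' @param library_total positive library size (total clean reads by
#'   default; total miRNA-mapped reads is an equally valid convention).
#' @param floor minimum reported TPM (default 0.01).
#' @return Numeric TPM value(s).
#' @examples
#' normalize_tpm(55, 1e7)   # 5.5
#' normalize_tpm(0, 1e7)    # 0.01
#' @export
normalize_tpm <- function(count, library_total, floor = 0.01) {
  if (any(library_total <= 0)) stop("library_total must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  pmax(1e6 * count / library_total, floor)
}

#' Log2 fold change between two TPM values
#'
#' \code{log2(tpm_protoplasts / tpm_calli)}; both inputs must be positive
#' (guaranteed by the TPM floor).
#'
#' @param tpm_protoplasts,tpm_calli positive normalised expression values.
#' @return The log2 ratio (full precision; round to 2 decimals for reports).
#' @export
log2_fold_change <- function(tpm_protoplasts, tpm_calli) {
  stopifnot(all(tpm_protoplasts > 0), all(tpm_calli > 0))
  log2(tpm_protoplasts / tpm_calli)
}

#' Exact conditional count test for two unreplicated libraries
#'
#' Tests whether a count \code{y} in library 2 is compatible with a count
#' \code{x} in library 1, given library sizes \code{N1} and \code{N2}
#' (Audic-Claverie-type statistic). The conditional distribution of
#' \code{y} given \code{x} is
#' \deqn{P(y\mid x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' which is negative binomial with size \code{x+1} and success probability
#' \code{N1/(N1+N2)}; tail sums are evaluated through
#' \code{\link[stats]{pnbinom}} (log-space internally, no factorial
#' overflow). The two-sided p-value doubles the smaller tail (point mass
#' included in both tails) and caps at 1.
#'
#' @param x,y non-negative integer counts (vectorised).
#' @param N1,N2 positive library sizes.
#' @return p-value(s) in \code{[0, 1]}.
#' @export
exact_count_pvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library sizes must be > 0")
  if (any(x != floor(x)) || any(y != floor(y))) stop("counts must be integers")
  p1 <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = p1)
  upper <- ifelse(y == 0, 1,
                  pnbinom(y - 1, size = x + 1, prob = p1, lower.tail = FALSE))
  pmin(1, 2 * pmin(lower, upper))
}

#' Up/down/unchanged status from fold change and p-value
#'
#' Up-regulated: \code{fc > fc_cut} and \code{p <= p_cut}; down-regulated:
#' \code{fc < -fc_cut} and \code{p <= p_cut}; otherwise unchanged. The fold
#' change cut is strict, the p cut inclusive.
#'
#' @param fc log2 fold change(s).
#' @param p p-value(s).
#' @param fc_cut,p_cut thresholds (defaults 1 and 0.01).
#' @return Character vector in \code{c("up", "down", "unchanged")}.
#' @export
dem_status <- function(fc, p, fc_cut = 1, p_cut = 0.01) {
  ifelse(fc > fc_cut & p <= p_cut, "up",
         ifelse(fc < -fc_cut & p <= p_cut, "down", "unchanged"))
}

#' Call differentially expressed miRNAs between two libraries
#'
#' For each catalogue entry, normalises the two counts to TPM (with the
#' low-expression floor), computes the log2 fold change
#' (protoplasts over calli), the exact conditional count p-value, and the
#' up/down/unchanged status. When the catalogue already carries TPM columns
#' and p-values (e.g. a published table), set \code{use_tpm = TRUE} to
#' classify from those directly, bypassing counts.
#'
#' @param catalog data.frame with columns \code{name} plus either
#'   \code{count_calli}/\code{count_protoplasts} or (with
#'   \code{use_tpm = TRUE}) \code{tpm_calli}/\code{tpm_protoplasts} and
#'   optionally \code{p}.
#' @param N1,N2 library sizes for calli and protoplasts (ignored when
#'   \code{use_tpm = TRUE}).
#' @param fc_cut,p_cut call thresholds.
#' @param floor TPM floor.
#' @param use_tpm classify from supplied TPM (and p) columns.
#' @param sort order the result as a report: up-regulated block then
#'   down-regulated block (each by ascending fold change), unchanged last.
#' @return A data.frame with columns \code{name}, \code{x}, \code{y},
#'   \code{tpm_calli}, \code{tpm_protoplasts}, \code{fc} (log2), \code{p}
#'   and \code{status}.
#' @export
call_dems <- function(catalog, N1 = NULL, N2 = NULL, fc_cut = 1,
                      p_cut = 0.01, floor = 0.01, use_tpm = FALSE,
                      sort = TRUE) {
  if (use_tpm) {
    tc <- catalog$tpm_calli
    tp <- catalog$tpm_protoplasts
    x <- catalog$count_calli %||% rep(NA_integer_, nrow(catalog))
    y <- catalog$count_protoplasts %||% rep(NA_integer_, nrow(catalog))
    p <- catalog$p %||% rep(0, nrow(catalog))
  } else {
    if (is.null(N1) || is.null(N2)) stop("N1 and N2 are required")
    if (any(catalog$count_calli > N1) || any(catalog$count_protoplasts > N2)) {
      stop("catalog counts exceed the library totals")
    }
    x <- catalog$count_calli
    y <- catalog$count_protoplasts
    tc <- normalize_tpm(x, N1, floor)
    tp <- normalize_tpm(y, N2, floor)
    p <- exact_count_pvalue(x, y, N1, N2)
  }
  fc <- log2_fold_change(tp, tc)
  out <- data.frame(name = catalog$name, x = x, y = y,
                    tpm_calli = tc, tpm_protoplasts = tp,
                    fc = fc, p = p,
                    status = dem_status(fc, p, fc_cut, p_cut),
                    stringsAsFactors = FALSE)
  if (sort) {
    blk <- match(out$status, c("up", "down", "unchanged"))
    out <- out[order(blk, out$fc), ]
    rownames(out) <- NULL
  }
  out
}

#' Write a DEM report table
#'
#' TPM and fold change rounded to 2 decimals, p-values in scientific
#' notation.
#'
#' @param dems result of \code{\link{call_dems}}.
#' @param path output TSV path.
#' @export
write_dem_table <- function(dems, path) {
  rep <- data.frame(
    miRNA = dems$name,
    tpm_calli = sprintf("%.2f", dems$tpm_calli),
    tpm_protoplasts = sprintf("%.2f", dems$tpm_protoplasts),
    log2_fold_change = sprintf("%.2f", dems$fc),
    p_value = ifelse(dems$p == 0, "0", sprintf("%.2E", dems$p)),
    status = dems$status, stringsAsFactors = FALSE)
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
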