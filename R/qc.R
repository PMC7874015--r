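#' Per-marker quality-control statistics
#'
#' @param panel A [genotype_panel()].
#' @return Data frame with one row per marker: `marker_id`, `call_rate`
#'   (fraction of non-missing calls over all individuals), `p_B` (B-allele
#'   frequency among non-missing calls, NA if all calls missing) and `maf`
#'   (`min(p_B, 1 - p_B)`).
#' @export
marker_qc <- function(panel) {
  d <- panel$dosages
  n_obs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0] <- NA_real_
  data.frame(marker_id = panel$markers$marker_id,
             call_rate = n_obs / nrow(d),
             p_B = p,
             maf = pmin(p, 1 - p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-individual quality-control statistics
#'
#' @param panel A [genotype_panel()].
#' @return Data frame with one row per individual: `id`, `missingness`
#'   (fraction of missing calls) and `heterozygosity` (fraction of
#'   non-missing calls with dosage 1; NA if every call is missing).
#' @export
individual_qc <- function(panel) {
  d <- panel$dosages
  n_obs <- rowSums(!is.na(d))
  het <- rowSums(d == 1L, na.rm = TRUE) / n_obs
  het[n_obs == 0] <- NA_real_
  data.frame(id = rownames(d),
             missingness = 1 - n_obs / ncol(d),
             heterozygosity = het,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' B-allele frequencies
#'
#' @param panel A [genotype_panel()].
#' @return Named numeric vector of per-marker B-allele frequencies computed
#'   over non-missing calls; markers with no calls are NA and listed in the
#'   `no_calls` attribute.
#' @export
allele_frequencies <- function(panel) {
  qc <- marker_qc(panel)
  p <- stats::setNames(qc$p_B, qc$marker_id)
  attr(p, "no_calls") <- qc$marker_id[is.na(qc$p_B)]
  p
}

#' Filter markers on missingness and minor-allele frequency
#'
#' Markers whose missingness exceeds `max_missing` or whose MAF falls below
#' `min_maf` are removed, the standard array-QC step for this kind of panel.
#'
#' @param panel A [genotype_panel()].
#' @param max_missing Maximum tolerated per-marker missingness (default 1%).
#' @param min_maf Minimum minor-allele frequency (default 5%).
#' @return List of class `qc_filter` with `panel` (the retained markers) and
#'   `report` (per-marker QC values, `removed` flag and `reason`).
#' @export
filter_markers <- function(panel, max_missing = 0.01, min_maf = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  qc <- marker_qc(panel)
  miss <- 1 - qc$call_rate
  fail_miss <- miss > max_missing
  fail_maf <- is.na(qc$maf) | qc$maf < min_maf
  reason <- rep(NA_character_, nrow(qc))
  reason[fail_maf] <- "maf"
  reason[fail_miss] <- "missingness"
  reason[fail_miss & fail_maf] <- "missingness+maf"
  removed <- fail_miss | fail_maf
  if (all(removed)) warning("filter_markers removed every marker")
  out <- list(panel = panel[, !removed],
              report = cbind(qc, missingness = miss, removed = removed,
                             reason = reason))
  class(out) <- "qc_filter"
  out
}

#' Filter individuals on missingness and heterozygosity
#'
#' Two presets mirror common practice on germplasm panels: `"qc"` removes
#' individuals with more than 5% missing calls; `"parentage"` is stricter
#' (1% missingness) and additionally removes individuals whose
#' heterozygosity falls outside \[0.25, 0.45\], a guard against residual
#' duplicates of inbred material and against low-quality DNA before
#' relatedness estimation.
#'
#' @param panel A [genotype_panel()].
#' @param preset `"qc"`, `"parentage"`, or `"custom"`.
#' @param max_missing Maximum individual missingness (overrides the preset).
#' @param het_range Length-2 numeric `c(low, high)` heterozygosity bounds, or
#'   NULL for no bound.
#' @return List of class `qc_filter` with `panel` and `report` (per-individual
#'   QC values, `removed` flag and `reason`).
#' @export
filter_individuals <- function(panel, preset = c("qc", "parentage", "custom"),
                               max_missing = NULL, het_range = NULL) {
  preset <- match.arg(preset)
  if (preset == "qc") {
    if (is.null(max_missing)) max_missing <- 0.05
  } else if (preset == "parentage") {
    if (is.null(max_missing)) max_missing <- 0.01
    if (is.null(het_range)) het_range <- c(0.25, 0.45)
  } else if (is.null(max_missing)) {
    stop("preset 'custom' requires max_missing")
  }
  qc <- individual_qc(panel)
  fail_miss <- qc$missingness > max_missing
  fail_het <- rep(FALSE, nrow(qc))
  if (!is.null(het_range))
    fail_het <- is.na(qc$heterozygosity) |
      qc$heterozygosity < het_range[1] | qc$heterozygosity > het_range[2]
  reason <- rep(NA_character_, nrow(qc))
  reason[fail_het] <- "heterozygosity"
  reason[fail_miss] <- "missingness"
  reason[fail_miss & fail_het] <- "missingness+heterozygosity"
  removed <- fail_miss | fail_het
  out <- list(panel = panel[!removed, ],
              report = cbind(qc, removed = removed, reason = reason))
  class(out) <- "qc_filter"
  out
}

#' @export
print.qc_filter <- function(x, ...) {
  cat("qc_filter:", sum(x$report$removed), "of", nrow(x$report),
      "entities removed\n")
  tab <- table(x$report$reason[x$report$removed])
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  invisible(x)
}

#' Prune markers in high linkage disequilibrium
#'
#' Sliding-window pruning on composite LD: r-squared is the squared Pearson
#' correlation of dosage vectors over pairwise-complete individuals (the
#' appropriate measure for unphased array data). Within each window, when a
#' kept pair exceeds `r2_max` the later marker (by position) is dropped.
#' Windows never span chromosomes, and the result is deterministic for a
#' fixed input.
#'
#' @param panel A [genotype_panel()] whose markers are sorted by
#'   (chromosome, position); unsorted input is an error.
#' @param r2_max Squared-correlation threshold above which the later marker
#'   of a pair is dropped (default 0.8).
#' @param window Window width in markers (default 50).
#' @param step Window advance in markers (default 5).
#' @return The pruned `genotype_panel`, with dropped marker ids in the
#'   `pruned` attribute.
#' @export
ld_prune <- function(panel, r2_max = 0.8, window = 50L, step = 5L) {
  mk <- panel$markers
  ord <- order(mk$chrom, mk$pos)
  if (!identical(ord, seq_len(nrow(mk))))
    stop("markers must be sorted by (chromosome, position) before ld_prune")
  keep <- rep(TRUE, nrow(mk))
  for (chr in unique(mk$chrom)) {
    idx <- which(mk$chrom == chr)
    n <- length(idx)
    starts <- seq(1L, max(1L, n - 1L), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1L, n)]
      w <- win[keep[win]]
      if (length(w) < 2) next
      cc <- suppressWarnings(
        stats::cor(panel$dosages[, w, drop = FALSE],
                   use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      for (a in seq_len(length(w) - 1L)) {
        if (!keep[w[a]]) next
        hits <- which(r2[a, ] > r2_max)
        hits <- hits[hits > a]
        if (length(hits)) keep[w[hits]] <- FALSE
      }
    }
  }
  out <- panel[, keep]
  attr(out, "pruned") <- mk$marker_id[!keep]
  out
}
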