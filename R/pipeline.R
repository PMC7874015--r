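#' Pipeline configuration
#'
#' All thresholds of the analysis in one serializable object. Defaults are
#' the field-standard cutoffs for array-based germplasm parentage: marker
#' QC at 1% missingness / 5% MAF, individual QC at 5% (relaxed) and 1%
#' plus heterozygosity in \[0.25, 0.45\] (parentage), 0.12% identity
#' mismatch, LD pruning at r-squared 0.8, PO at k0 < 0.03, FS at k2 > 0.3,
#' trio acceptance at 0.2% Mendelian-error rate, and the obligate-allele
#' scan rule (z >= 4, excess >= 0.15, at least 100 informative markers,
#' 2 accepted candidates to fix a direction).
#'
#' @param seed Integer seed funnelling all randomness in the run.
#' @param simulate Logical: generate the standard scenario (TRUE) or read
#'   `input_path`.
#' @param input_path,input_format Input panel when `simulate` is FALSE.
#' @param n_markers,error_rate,missing_rate Scenario knobs (see
#'   [standard_scenario()]).
#' @param ... Named threshold overrides (see Details in the source; any of
#'   `marker_max_missing`, `marker_min_maf`, `ind_max_missing`,
#'   `parentage_max_missing`, `parentage_het_low`, `parentage_het_high`,
#'   `identity_threshold`, `min_compared`, `ld_r2_max`, `ld_window`,
#'   `ld_step`, `k0_max`, `k2_min`, `trio_max_error_rate`, `sd_n_min`,
#'   `sd_z_min`, `sd_excess_min`, `sd_m_min`, `phi_min`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, simulate = TRUE, input_path = NULL,
                            input_format = "auto", n_markers = 10000L,
                            error_rate = 1e-4, missing_rate = 0.005, ...) {
  cfg <- list(seed = as.integer(seed), simulate = simulate,
              input_path = input_path, input_format = input_format,
              n_markers = as.integer(n_markers), error_rate = error_rate,
              missing_rate = missing_rate,
              marker_max_missing = 0.01, marker_min_maf = 0.05,
              ind_max_missing = 0.05,
              parentage_max_missing = 0.01,
              parentage_het_low = 0.25, parentage_het_high = 0.45,
              identity_threshold = 0.12, min_compared = 500L,
              ld_r2_max = 0.8, ld_window = 50L, ld_step = 5L,
              k0_max = 0.03, k2_min = 0.3, trio_max_error_rate = 0.002,
              sd_n_min = 100L, sd_z_min = 4, sd_excess_min = 0.15,
              sd_m_min = 2L, phi_min = 0.13)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param cfg A [pipeline_config()].
#' @param path YAML file.
#' @return `read_config` returns a `pipeline_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Serialize / restore a ground-truth pedigree
#' @param truth A [pedigree_truth()].
#' @param path TSV file (`id`, `kind`, `parent1`, `parent2`, `hidden`).
#' @return `read_truth` returns a `pedigree_truth`.
#' @export
write_truth <- function(truth, path) {
  rows <- data.frame(id = truth$founders, kind = "founder",
                     parent1 = NA_character_, parent2 = NA_character_,
                     hidden = truth$founders %in% truth$hidden,
                     stringsAsFactors = FALSE)
  if (!is.null(truth$events) && nrow(truth$events))
    rows <- rbind(rows, truth$events[c("id", "kind", "parent1", "parent2", "hidden")])
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  fd <- tab[tab$kind == "founder", , drop = FALSE]
  ev <- tab[tab$kind != "founder", , drop = FALSE]
  pedigree_truth(fd$id, if (nrow(ev)) ev else NULL,
                 hidden_founders = fd$id[fd$hidden])
}

.stage_file <- function(outdir, name) file.path(outdir, name)

#' Run one pipeline stage
#'
#' Stages communicate through files in `outdir`, so any stage can be rerun
#' in isolation once its predecessors have written their artifacts:
#' `simulate` (or input ingestion), `qc`, `dedupe`, `relate`, `pedigree`,
#' `report`.
#'
#' @param stage Stage name.
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
run_stage <- function(stage = c("simulate", "qc", "dedupe", "relate",
                                "pedigree", "report"),
                      cfg, outdir) {
  stage <- match.arg(stage)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) .stage_file(outdir, name)
  written <- character(0)
  emit <- function(obj, name) {
    utils::write.table(obj, f(name), sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, name)
  }
  if (stage == "simulate") {
    if (isTRUE(cfg$simulate)) {
      sc <- standard_scenario(cfg$seed, n_markers = cfg$n_markers,
                              error_rate = cfg$error_rate,
                              missing_rate = cfg$missing_rate)
      write_panel(sc$panel, f("panel.tsv"), format = "dosage")
      write_truth(sc$truth, f("truth.tsv"))
      emit(sc$names, "names.tsv")
      written <- c(written, "panel.tsv", "truth.tsv")
    } else {
      panel <- read_panel(cfg$input_path, cfg$input_format)
      write_panel(panel, f("panel.tsv"), format = "dosage")
      written <- c(written, "panel.tsv")
    }
  } else if (stage == "qc") {
    panel <- read_panel(f("panel.tsv"), "dosage")
    fm <- filter_markers(panel, cfg$marker_max_missing, cfg$marker_min_maf)
    fi <- filter_individuals(fm$panel, "custom", max_missing = cfg$ind_max_missing)
    emit(fm$report, "marker_qc_report.tsv")
    emit(fi$report, "individual_qc_report.tsv")
    write_panel(fi$panel, f("qc_panel.tsv"), format = "dosage")
    written <- c(written, "qc_panel.tsv")
  } else if (stage == "dedupe") {
    panel <- read_panel(f("qc_panel.tsv"), "dosage")
    mm <- pairwise_mismatch(panel, min_compared = cfg$min_compared)
    iqc <- individual_qc(panel)
    cl <- cluster_identicals(mm, threshold = cfg$identity_threshold,
                             missingness = stats::setNames(iqc$missingness, iqc$id))
    emit(cl, "clusters.tsv")
    if (file.exists(f("names.tsv"))) {
      nm <- utils::read.delim(f("names.tsv"), stringsAsFactors = FALSE)
      ct <- name_crosstab(cl, nm)
      emit(ct$synonyms, "synonyms.tsv")
      emit(ct$homonyms, "homonyms.tsv")
      emit(ct$table, "name_clusters.tsv")
    }
    dd <- dedupe(panel, cl)
    emit(attr(dd, "dedupe_map"), "dedupe_map.tsv")
    write_panel(dd, f("dedup_panel.tsv"), format = "dosage")
    written <- c(written, "dedup_panel.tsv")
  } else if (stage == "relate") {
    panel <- read_panel(f("dedup_panel.tsv"), "dosage")
    fi <- filter_individuals(panel, "custom",
                             max_missing = cfg$parentage_max_missing,
                             het_range = c(cfg$parentage_het_low,
                                           cfg$parentage_het_high))
    emit(fi$report, "parentage_individual_report.tsv")
    write_panel(fi$panel, f("parentage_panel.tsv"), format = "dosage")
    pruned <- ld_prune(fi$panel, r2_max = cfg$ld_r2_max,
                       window = cfg$ld_window, step = cfg$ld_step)
    freqs <- allele_frequencies(pruned)
    ibd <- pairwise_ibd(pruned, freqs)
    emit(ibd, "ibd.tsv")
    written <- c(written, "parentage_panel.tsv")
  } else if (stage == "pedigree") {
    panel <- read_panel(f("parentage_panel.tsv"), "dosage")
    ibd <- utils::read.delim(f("ibd.tsv"), stringsAsFactors = FALSE)
    duos <- find_po_duos(ibd, panel, k0_max = cfg$k0_max)
    emit(data.frame(k0 = attr(duos, "k0_values")), "k0_values.tsv")
    trios <- find_trios(panel, duos, max_error_rate = cfg$trio_max_error_rate)
    emit(trios, "trios.tsv")
    fs <- find_fullsibs(ibd, duos, k2_min = cfg$k2_min)
    emit(fs, "fullsibs.tsv")
    freqs <- allele_frequencies(panel)
    sd_res <- sd_scan_duos(panel, duos, trios, freqs = freqs,
                           n_min = cfg$sd_n_min, z_min = cfg$sd_z_min,
                           excess_min = cfg$sd_excess_min)
    emit(sd_res, "sd_scan.tsv")
    duos <- infer_directions(duos, trios, fs, sd_res, m_min = cfg$sd_m_min)
    emit(duos, "po_duos.tsv")
    nodes <- if (file.exists(f("names.tsv")))
      utils::read.delim(f("names.tsv"), stringsAsFactors = FALSE) else NULL
    net <- pedigree_network(duos, fs, trios, nodes = nodes)
    export_network(net, f("network.tsv"), "edge_tsv")
    export_network(net, f("network.graphml"), "graphml")
    export_network(net, f("network.dot"), "dot")
    written <- c(written, "network.tsv", "network.graphml", "network.dot")
  } else if (stage == "report") {
    written <- c(written, .pipeline_report(cfg, outdir))
  }
  invisible(written)
}

#' Run the full pipeline
#'
#' simulate (or ingest) -> qc -> dedupe -> relate -> pedigree -> report,
#' with per-stage artifacts and a manifest in `outdir`. A stage failure
#' aborts with the stage name; artifacts of completed stages are preserved.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, the machine-readable summary (see [pipeline_report()]).
#' @export
run_pipeline <- function(cfg, outdir) {
  stages <- c("simulate", "qc", "dedupe", "relate", "pedigree", "report")
  manifest <- list(config = unclass(cfg), stages = list())
  for (s in stages) {
    res <- tryCatch(run_stage(s, cfg, outdir),
                    error = function(e) stop("pipeline stage '", s, "' failed: ",
                                             conditionMessage(e), call. = FALSE))
    manifest$stages[[s]] <- res
  }
  jsonlite::write_json(manifest, .stage_file(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(jsonlite::read_json(.stage_file(outdir, "summary.json")))
}

# Build summary.json and report.md from the stage TSVs alone, so every
# reported number is recomputable from the artifacts.
.pipeline_report <- function(cfg, outdir) {
  f <- function(name) .stage_file(outdir, name)
  rd <- function(name) if (file.exists(f(name)))
    utils::read.delim(f(name), stringsAsFactors = FALSE) else NULL
  qc_panel <- read_panel(f("qc_panel.tsv"), "dosage")
  clusters <- rd("clusters.tsv")
  duos <- rd("po_duos.tsv")
  trios <- rd("trios.tsv")
  fs <- rd("fullsibs.tsv")
  sd_res <- rd("sd_scan.tsv")
  iqc <- rd("individual_qc_report.tsv")
  n_ind <- nrow(qc_panel$dosages)
  n_clusters <- if (!is.null(clusters)) nrow(clusters) else n_ind
  acc_trios <- if (!is.null(trios) && nrow(trios)) sum(trios$accepted) else 0L
  summary <- list(
    n_individuals_postqc = n_ind,
    n_markers_postqc = ncol(qc_panel$dosages),
    mean_heterozygosity = if (!is.null(iqc))
      mean(iqc$heterozygosity[!iqc$removed], na.rm = TRUE) else NA,
    n_identity_clusters = n_clusters,
    duplicate_fraction = (n_ind - n_clusters) / n_ind,
    n_po_duos = if (!is.null(duos)) nrow(duos) else 0L,
    n_trios_tested = if (!is.null(trios)) nrow(trios) else 0L,
    n_trios_accepted = acc_trios,
    n_fullsib_edges = if (!is.null(fs)) nrow(fs) else 0L,
    n_sd_accepted = if (!is.null(sd_res) && nrow(sd_res)) sum(sd_res$accepted) else 0L,
    n_po_directed = if (!is.null(duos) && nrow(duos)) sum(!is.na(duos$parent)) else 0L,
    n_po_undirected = if (!is.null(duos) && nrow(duos)) sum(is.na(duos$parent)) else 0L)
  if (file.exists(f("truth.tsv")) && !is.null(clusters)) {
    truth <- read_truth(f("truth.tsv"))
    memb <- integer(0)
    for (i in seq_len(nrow(clusters))) {
      m <- strsplit(clusters$members[i], ",")[[1]]
      memb[m] <- clusters$cluster[i]
    }
    attr(clusters, "membership") <- memb
    parentage_ids <- rownames(read_panel(f("parentage_panel.tsv"),
                                         "dosage")$dosages)
    sc <- score_recovery(truth, clusters = clusters,
                         po_edges = duos, trios = trios,
                         analysis_ids = parentage_ids)
    summary$recovery <- lapply(unclass(sc), function(s)
      list(precision = s$precision, recall = s$recall,
           n_true = s$n_true, n_called = s$n_called))
  }
  jsonlite::write_json(summary, f("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  md <- c("# Parentage pipeline report", "",
          sprintf("- individuals after QC: %d", summary$n_individuals_postqc),
          sprintf("- markers after QC: %d", summary$n_markers_postqc),
          sprintf("- mean heterozygosity: %.1f%%",
                  100 * summary$mean_heterozygosity),
          sprintf("- identity clusters (unique genotypes): %d",
                  summary$n_identity_clusters),
          sprintf("- duplicate fraction: %.1f%%",
                  100 * summary$duplicate_fraction),
          sprintf("- PO duos (k0 < %.3g): %d", cfg$k0_max, summary$n_po_duos),
          sprintf("- trios accepted / tested: %d / %d",
                  summary$n_trios_accepted, summary$n_trios_tested),
          sprintf("- full-sib edges (k2 > %.2g): %d", cfg$k2_min,
                  summary$n_fullsib_edges),
          sprintf("- accepted second-degree scan hits: %d", summary$n_sd_accepted),
          sprintf("- PO directions resolved / unresolved: %d / %d",
                  summary$n_po_directed, summary$n_po_undirected))
  writeLines(md, f("report.md"))
  c("summary.json", "report.md")
}

#' Regenerate the run report
#'
#' Rebuilds `summary.json` and `report.md` from the stage artifacts in
#' `outdir`; idempotent.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Directory holding the stage artifacts.
#' @return The summary list, invisibly.
#' @export
pipeline_report <- function(cfg, outdir) {
  .pipeline_report(cfg, outdir)
  invisible(jsonlite::read_json(.stage_file(outdir, "summary.json")))
}
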