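# Shared standard-scenario analyses, memoized across test files so the
# end-to-end seeds are simulated and analysed once per session.

.gk_cache <- new.env(parent = emptyenv())

scenario_analysis <- function(seed, error_rate = 1e-4, missing_rate = 0.005) {
  key <- paste("sa", seed, error_rate, missing_rate, sep = "_")
  if (!is.null(.gk_cache[[key]])) return(.gk_cache[[key]])
  sc <- standard_scenario(seed, error_rate = error_rate,
                          missing_rate = missing_rate)
  fm <- filter_markers(sc$panel)
  fi <- filter_individuals(fm$panel, "qc")
  mm <- pairwise_mismatch(fi$panel)
  iqc <- individual_qc(fi$panel)
  cl <- cluster_identicals(mm, missingness = stats::setNames(iqc$missingness,
                                                             iqc$id))
  dd <- dedupe(fi$panel, cl)
  pf <- filter_individuals(dd, "parentage")$panel
  pruned <- ld_prune(pf)
  ibd <- pairwise_ibd(pruned)
  duos <- find_po_duos(ibd, pf)
  trios <- find_trios(pf, duos)
  fs <- find_fullsibs(ibd, duos)
  freqs <- allele_frequencies(pf)
  sdres <- sd_scan_duos(pf, duos, trios, freqs = freqs)
  dirs <- infer_directions(duos, trios, fs, sdres)
  res <- list(sc = sc, truth = sc$truth, qc_panel = fi$panel, mm = mm,
              clusters = cl, dedup = dd, pf = pf, ibd = ibd, duos = duos,
              trios = trios, fs = fs, freqs = freqs, sdres = sdres,
              dirs = dirs)
  .gk_cache[[key]] <- res
  res
}

clone_src <- function(truth, ids)
  vapply(ids, function(x) {
    while (x %in% names(truth$clones)) x <- truth$clones[[x]]
    x
  }, character(1))

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Trio-less duos of an analysis, each oriented by simulator truth.
true_directed_duos <- function(a) {
  acc <- a$trios[a$trios$accepted, , drop = FALSE]
  expl <- c(pair_key(acc$offspring, acc$parent1),
            pair_key(acc$offspring, acc$parent2))
  todo <- a$duos[!(pair_key(a$duos$id1, a$duos$id2) %in% expl), , drop = FALSE]
  if (!nrow(todo)) return(todo)
  par <- character(nrow(todo))
  for (i in seq_len(nrow(todo))) {
    s1 <- clone_src(a$truth, todo$id1[i]); s2 <- clone_src(a$truth, todo$id2[i])
    p2 <- a$truth$parents[[s2]] %||% character(0)
    par[i] <- if (s1 %in% p2) todo$id1[i] else todo$id2[i]
  }
  todo$true_parent <- par
  todo$true_child <- ifelse(par == todo$id1, todo$id2, todo$id1)
  todo
}
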