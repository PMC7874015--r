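#' Pairwise mismatch between individuals
#'
#' The duplicate-detection statistic: for every pair of individuals, the
#' percentage of pairwise-complete markers at which the two dosages differ.
#' Germplasm panels show a sharply bimodal mismatch distribution — clonal
#' copies of one variety differ only by genotyping error (well under 1%),
#' while distinct varieties, even close relatives, differ at 10% of markers
#' or more.
#'
#' @param panel A [genotype_panel()] with at least two individuals.
#' @param min_compared Pairs with fewer pairwise-complete markers than this
#'   floor are flagged unreliable (mismatch set to NA). Default 500.
#' @return Object of class `mismatch_matrix`: list with `mismatch`
#'   (symmetric percentage matrix, diagonal 0, NA where unreliable) and
#'   `n_compared` (pairwise-complete marker counts).
#' @export
pairwise_mismatch <- function(panel, min_compared = 500L) {
  d <- panel$dosages
  if (nrow(d) < 2) stop("pairwise_mismatch needs at least two individuals")
  V <- !is.na(d)
  storage.mode(V) <- "double"
  n_comp <- tcrossprod(V)
  # agreements: count markers where both observed and equal
  eq <- matrix(0, nrow(d), nrow(d))
  for (g in 0:2) {
    A <- (!is.na(d)) & d == g
    storage.mode(A) <- "double"
    eq <- eq + tcrossprod(A)
  }
  mm <- 100 * (n_comp - eq) / n_comp
  mm[n_comp == 0] <- NA_real_
  unreliable <- n_comp < min_compared
  diag(unreliable) <- FALSE
  mm[unreliable] <- NA_real_
  diag(mm) <- 0
  dimnames(mm) <- dimnames(n_comp) <- list(rownames(d), rownames(d))
  structure(list(mismatch = mm, n_compared = n_comp,
                 min_compared = min_compared),
            class = "mismatch_matrix")
}

#' @export
print.mismatch_matrix <- function(x, ...) {
  v <- x$mismatch[upper.tri(x$mismatch)]
  cat("mismatch_matrix:", nrow(x$mismatch), "individuals;",
      sum(is.na(v)), "unreliable pair(s)\n")
  if (any(!is.na(v)))
    cat(sprintf("  range %.3f%% - %.1f%%\n", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  invisible(x)
}

#' Cluster identical genotypes
#'
#' Single-linkage grouping at a strict mismatch threshold: two individuals
#' belong to the same cluster when connected by a chain of pairs each below
#' the threshold. At a near-zero threshold the linkage choice is immaterial
#' and the result is order-independent. Unreliable pairs (NA mismatch) never
#' link.
#'
#' @param mm A [pairwise_mismatch()] result.
#' @param threshold Identity threshold in percent; pairs with mismatch
#'   strictly below it are considered the same genotype. Default 0.12.
#' @param missingness Optional named vector of per-individual missingness
#'   used to pick each cluster's representative (least missing wins, ties by
#'   input order). Defaults to equal missingness.
#' @return Data frame with one row per cluster: `cluster` id, `members`
#'   (comma-separated), `n`, `representative`, `max_internal_mismatch`.
#'   Attribute `membership` maps each individual to its cluster.
#' @export
cluster_identicals <- function(mm, threshold = 0.12, missingness = NULL) {
  stopifnot(threshold > 0)
  ids <- rownames(mm$mismatch)
  adj <- !is.na(mm$mismatch) & mm$mismatch < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  if (is.null(missingness)) missingness <- stats::setNames(rep(0, length(ids)), ids)
  rows <- lapply(sort(unique(comp)), function(k) {
    members <- ids[comp == k]
    rep_id <- members[order(missingness[members],
                            match(members, ids))][1]
    internal <- if (length(members) > 1)
      max(mm$mismatch[members, members], na.rm = TRUE) else 0
    data.frame(cluster = k, members = paste(members, collapse = ","),
               n = length(members), representative = rep_id,
               max_internal_mismatch = internal, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "membership") <- comp
  out
}

#' Cross-tabulate genotype clusters against accession names
#'
#' Flags candidate synonyms (one genotype cluster carrying several distinct
#' names) and candidate homonyms (one name spread over several clusters).
#' Curation of the flags — true synonym versus misnaming — is a human
#' decision and is left as an empty `curation` column.
#'
#' @param clusters Result of [cluster_identicals()].
#' @param names_table Data frame with columns `id` and `name`; every
#'   clustered individual must appear at least once.
#' @return List with data frames `synonyms` (cluster, names), `homonyms`
#'   (name, clusters) and `table` (the full id/name/cluster mapping with an
#'   empty `curation` column).
#' @export
name_crosstab <- function(clusters, names_table) {
  membership <- attr(clusters, "membership")
  if (is.null(membership)) stop("clusters must come from cluster_identicals()")
  if (!all(names(membership) %in% names_table$id))
    stop("names_table lacks name(s) for: ",
         paste(utils::head(setdiff(names(membership), names_table$id), 5),
               collapse = ", "))
  tab <- names_table[names_table$id %in% names(membership), , drop = FALSE]
  tab$cluster <- membership[tab$id]
  tab$curation <- ""
  syn <- do.call(rbind, lapply(split(tab, tab$cluster), function(s) {
    nms <- unique(s$name)
    if (length(nms) < 2) return(NULL)
    data.frame(cluster = s$cluster[1], names = paste(sort(nms), collapse = " | "),
               n_names = length(nms), stringsAsFactors = FALSE)
  }))
  hom <- do.call(rbind, lapply(split(tab, tab$name), function(s) {
    cl <- unique(s$cluster)
    if (length(cl) < 2) return(NULL)
    data.frame(name = s$name[1], clusters = paste(sort(cl), collapse = ","),
               n_clusters = length(cl), stringsAsFactors = FALSE)
  }))
  empty_syn <- data.frame(cluster = integer(0), names = character(0),
                          n_names = integer(0))
  empty_hom <- data.frame(name = character(0), clusters = character(0),
                          n_clusters = integer(0))
  list(synonyms = if (is.null(syn)) empty_syn else syn,
       homonyms = if (is.null(hom)) empty_hom else hom,
       table = tab[order(tab$cluster), ])
}

#' Reduce a panel to one representative per genotype cluster
#'
#' @param panel The [genotype_panel()] the clusters were computed from.
#' @param clusters Result of [cluster_identicals()].
#' @return The deduplicated `genotype_panel`; attribute `dedupe_map` is a
#'   data frame mapping every individual to its retained representative.
#' @export
dedupe <- function(panel, clusters) {
  membership <- attr(clusters, "membership")
  if (!all(names(membership) %in% rownames(panel$dosages)))
    stop("clusters refer to individuals absent from the panel")
  reps <- clusters$representative
  keep <- rownames(panel$dosages)[rownames(panel$dosages) %in% reps]
  out <- panel[keep, ]
  attr(out, "true_freqs") <- attr(panel, "true_freqs")
  map <- data.frame(id = names(membership),
                    representative = clusters$representative[
                      match(membership, clusters$cluster)],
                    stringsAsFactors = FALSE)
  attr(out, "dedupe_map") <- map
  out
}
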