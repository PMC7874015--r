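#' Score recovered relationships against simulator truth
#'
#' Precision and recall of clone clustering, PO-duo detection and trio
#' detection against a [pedigree_truth()]. Individuals are mapped through
#' the clone map before comparison, so a call involving a retained clone
#' copy counts as a call on its source variety. PO truth includes
#' parent-offspring pairs arising from selfings.
#'
#' @param truth A [pedigree_truth()].
#' @param clusters Result of [cluster_identicals()] (or NULL to skip).
#' @param cluster_ids Individuals over which clustering ran.
#' @param po_edges PO edge data frame (or NULL to skip).
#' @param trios Trio table from [find_trios()] (or NULL to skip).
#' @param analysis_ids Individuals present in the relatedness analysis
#'   (post-dedupe, post-filters); truth is restricted to them.
#' @return List of class `recovery_score` with elements `clones`, `po`,
#'   `trios`, each a list `precision`, `recall`, `n_true`, `n_called`.
#' @export
score_recovery <- function(truth, clusters = NULL, cluster_ids = NULL,
                           po_edges = NULL, trios = NULL, analysis_ids = NULL) {
  src <- function(id) vapply(id, function(x) .clone_source(truth, x), character(1))
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pr <- function(called, true) {
    list(precision = if (length(called)) mean(called %in% true) else NA_real_,
         recall = if (length(true)) mean(true %in% called) else NA_real_,
         n_true = length(true), n_called = length(called))
  }
  out <- list()
  if (!is.null(clusters)) {
    if (is.null(cluster_ids)) cluster_ids <- names(attr(clusters, "membership"))
    rel <- true_relationships(truth, cluster_ids)
    true_pairs <- pair_key(rel$id1, rel$id2)[rel$relation == "CLONE"]
    memb <- attr(clusters, "membership")
    called <- character(0)
    for (k in unique(memb)) {
      m <- names(memb)[memb == k]
      if (length(m) > 1) {
        cmb <- utils::combn(sort(m), 2)
        called <- c(called, pair_key(cmb[1, ], cmb[2, ]))
      }
    }
    out$clones <- pr(called, true_pairs)
  }
  if (!is.null(po_edges)) {
    if (is.null(analysis_ids)) stop("analysis_ids required to score PO edges")
    srcs <- src(analysis_ids)
    rel <- true_relationships(truth, srcs)
    true_pairs <- pair_key(rel$id1, rel$id2)[rel$relation %in% c("PO", "SELF")]
    called <- if (nrow(po_edges))
      unique(pair_key(src(po_edges$id1), src(po_edges$id2))) else character(0)
    out$po <- pr(called, true_pairs)
  }
  if (!is.null(trios)) {
    if (is.null(analysis_ids)) stop("analysis_ids required to score trios")
    srcs <- src(analysis_ids)
    true_trios <- character(0)
    for (id in srcs) {
      pp <- truth$parents[[id]]
      if (is.null(pp) || pp[1] == pp[2]) next
      if (all(pp %in% srcs))
        true_trios <- c(true_trios, paste(id, pair_key(pp[1], pp[2])))
    }
    acc <- trios[trios$accepted, , drop = FALSE]
    called <- if (nrow(acc))
      unique(paste(src(acc$offspring),
                   pair_key(src(acc$parent1), src(acc$parent2)))) else character(0)
    out$trios <- pr(called, unique(true_trios))
  }
  class(out) <- "recovery_score"
  out
}

#' @export
print.recovery_score <- function(x, ...) {
  for (nm in names(x)) {
    s <- x[[nm]]
    cat(sprintf("%-7s precision %.3f recall %.3f (%d true, %d called)\n",
                nm, s$precision, s$recall, s$n_true, s$n_called))
  }
  invisible(x)
}

#' True second-degree relatives through the missing parent of a duo
#'
#' For a directed duo (genotyped parent, offspring) whose other parent is
#' not genotyped, lists the genotyped individuals that descend from or
#' flank the missing parent's lineage — the individuals the obligate-allele
#' scan is expected to flag: other children of the missing parent, the
#' missing parent's parents (the offspring's grandparents) and the missing
#' parent's full sibs (avuncular).
#'
#' Full sibs of the offspring (sharing the genotyped parent as well) are
#' excluded: at the scan's informative markers their allele from the shared
#' genotyped parent is never the obligate allele, so their carrier excess is
#' roughly half that of a true half sib and they are not second-degree
#' relatives in the first place.
#'
#' @param truth A [pedigree_truth()].
#' @param parent,offspring The focal duo (true direction).
#' @param ids Genotyped individuals available as scan candidates.
#' @return Character vector of ids (clone copies map to their source).
#' @export
missing_parent_relatives <- function(truth, parent, offspring, ids) {
  pp <- truth$parents[[.clone_source(truth, offspring)]]
  if (is.null(pp)) stop(offspring, " has no recorded parents")
  mp <- setdiff(pp, .clone_source(truth, parent))
  if (length(mp) != 1) stop("missing parent not unique for this duo")
  P <- truth$parents
  kids <- names(P)[vapply(P, function(q)
    mp %in% q && !.clone_source(truth, parent) %in% q, logical(1))]
  kids <- setdiff(kids, .clone_source(truth, offspring))
  gps <- P[[mp]]
  fs <- if (!is.null(P[[mp]]))
    names(P)[vapply(P, function(q) all(sort(q) == sort(P[[mp]])), logical(1))]
  else character(0)
  fs <- setdiff(fs, mp)
  rel <- unique(c(kids, gps, fs))
  ids[vapply(ids, function(x) .clone_source(truth, x), character(1)) %in% rel]
}
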