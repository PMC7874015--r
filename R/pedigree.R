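#' Detect parent-offspring duos
#'
#' Pairs whose estimated k0 falls below the threshold are called PO duos.
#' On real germplasm panels the k0 distribution is sharply bimodal with an
#' empty gap around 0.03 separating true first-degree pairs from everything
#' else; the threshold is a fixed default and the full k0 vector is returned
#' so the gap can be inspected. Each emitted edge is annotated with its duo
#' Mendelian-error count as confirmation (a true PO pair shows essentially
#' none).
#'
#' @param ibd Data frame from [pairwise_ibd()], computed on the LD-pruned,
#'   parentage-filtered, deduplicated panel.
#' @param panel Optional [genotype_panel()] on the full (unpruned) marker
#'   set used for the Mendelian-error confirmation counts; omit to skip.
#' @param k0_max PO threshold on k0 (default 0.03).
#' @return Data frame of PO edges: `id1`, `id2`, `relation` = "PO", the IBD
#'   columns, `duo_errors`, `duo_error_rate`. Attribute `k0_values` carries
#'   all pairwise k0 for histogram inspection.
#' @export
find_po_duos <- function(ibd, panel = NULL, k0_max = 0.03) {
  hit <- ibd$k0 < k0_max
  edges <- ibd[hit, , drop = FALSE]
  edges$relation <- rep("PO", nrow(edges))
  edges$duo_errors <- rep(NA_integer_, nrow(edges))
  edges$duo_error_rate <- rep(NA_real_, nrow(edges))
  if (!is.null(panel) && nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      duo <- mendel_errors_duo(panel, edges$id1[i], edges$id2[i])
      edges$duo_errors[i] <- duo$mendelian_errors
      edges$duo_error_rate[i] <- duo$error_rate
    }
  }
  rownames(edges) <- NULL
  attr(edges, "k0_values") <- ibd$k0
  edges
}

#' Detect trios among the identified duos
#'
#' For every individual with at least two PO partners, each unordered pair
#' of partners is tested as its parents by counting trio Mendelian errors on
#' the full marker set. True trios show error rates near the genotyping
#' error rate; false trios (e.g. a true parent swapped for its full sib) are
#' one to two orders of magnitude above, so a rate threshold separates them
#' cleanly.
#'
#' @param panel [genotype_panel()] on the full marker set.
#' @param duos PO edge data frame from [find_po_duos()].
#' @param max_error_rate Acceptance threshold on the trio error rate
#'   (default 0.002, i.e. 0.2% of tested markers — between the observed
#'   true-trio and false-trio regimes and expressed as a rate so it
#'   transfers across panel sizes).
#' @return Data frame of all tested trios: `offspring`, `parent1`,
#'   `parent2`, `errors`, `n_valid`, `error_rate`, `accepted`.
#' @export
find_trios <- function(panel, duos, max_error_rate = 0.002) {
  partners <- function(id)
    sort(unique(c(duos$id2[duos$id1 == id], duos$id1[duos$id2 == id])))
  offs <- sort(unique(c(duos$id1, duos$id2)))
  rows <- list()
  for (o in offs) {
    pp <- partners(o)
    if (length(pp) < 2) next
    cmb <- utils::combn(pp, 2)
    for (j in seq_len(ncol(cmb))) {
      tr <- mendel_errors_trio(panel, o, cmb[1, j], cmb[2, j])
      rows[[length(rows) + 1L]] <-
        data.frame(offspring = o, parent1 = cmb[1, j], parent2 = cmb[2, j],
                   errors = tr$mendelian_errors, n_valid = tr$n_valid,
                   error_rate = tr$error_rate,
                   accepted = !is.na(tr$error_rate) &&
                     tr$error_rate <= max_error_rate,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(offspring = character(0), parent1 = character(0),
                      parent2 = character(0), errors = integer(0),
                      n_valid = integer(0), error_rate = numeric(0),
                      accepted = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect well-supported full-sib pairs
#'
#' Non-PO pairs with k2 above a conservative threshold are flagged FS. The
#' expected k2 of full sibs is 0.25, and there is no clean gap between full
#' sibs and second-degree pairs in k2; a high threshold therefore trades
#' recall for precision, keeping only strongly supported full-sib calls.
#'
#' @param ibd Data frame from [pairwise_ibd()].
#' @param po_edges PO edges from [find_po_duos()] (these pairs are excluded).
#' @param k2_min FS threshold on k2 (default 0.3).
#' @return Data frame of FS edges with the IBD columns.
#' @export
find_fullsibs <- function(ibd, po_edges = NULL, k2_min = 0.3) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  is_po <- if (is.null(po_edges) || !nrow(po_edges)) rep(FALSE, nrow(ibd))
           else key(ibd$id1, ibd$id2) %in% key(po_edges$id1, po_edges$id2)
  edges <- ibd[!is_po & ibd$k2 > k2_min, , drop = FALSE]
  if (nrow(edges)) edges$relation <- "FS"
  else edges$relation <- character(0)
  rownames(edges) <- NULL
  edges
}

#' Obligate-allele scan for second-degree relatives of a missing parent
#'
#' Given an accepted PO duo and an assumed direction, the informative
#' markers are those where the assumed parent is homozygous and the
#' offspring heterozygous: the offspring allele the parent lacks (the
#' obligate allele) must have come from the other — possibly non-genotyped —
#' parent. Relatives of that missing parent carry the obligate allele far
#' more often than Hardy-Weinberg carrier frequencies predict, so each
#' candidate's observed carrier fraction `f_obs` is compared with its
#' expectation `f_exp` and standardized to a z score. Both homozygous parent
#' classes are used by default (the argument is symmetric in the two
#' alleles); `literal_aa_only = TRUE` restricts to parent-AA/offspring-AB
#' markers.
#'
#' @param panel Deduplicated [genotype_panel()] (full marker set).
#' @param parent,offspring The focal duo, with `parent` as assumed parent.
#' @param candidates Individuals to test (default: everyone else).
#' @param freqs Per-marker B-allele frequencies for carrier expectations.
#' @param n_min Minimum informative markers for a reported candidate
#'   (default 100).
#' @param z_min,excess_min Acceptance rule: z >= `z_min` (default 4) and
#'   `f_obs - f_exp` >= `excess_min` (default 0.15). The two-sided guard
#'   rejects both small-n flukes and large-n trivial excesses.
#' @param literal_aa_only Use only the parent-AA homozygote class.
#' @return Data frame of class `sd_scan`: `parent_assumed`, `offspring`,
#'   `candidate`, `n_informative`, `f_obs`, `f_exp`, `z`, `accepted`.
#' @export
sd_scan <- function(panel, parent, offspring,
                    candidates = setdiff(rownames(panel$dosages), c(parent, offspring)),
                    freqs = allele_frequencies(panel),
                    n_min = 100L, z_min = 4, excess_min = 0.15,
                    literal_aa_only = FALSE) {
  d <- panel$dosages
  if (!all(c(parent, offspring) %in% rownames(d)))
    stop("duo member(s) not in panel")
  pd <- d[parent, ]; od <- d[offspring, ]
  p <- freqs[colnames(d)]
  inf_B <- !is.na(pd) & !is.na(od) & pd == 0L & od == 1L   # obligate allele = B
  inf_A <- !is.na(pd) & !is.na(od) & pd == 2L & od == 1L   # obligate allele = A
  if (literal_aa_only) inf_A[] <- FALSE
  use <- (inf_B | inf_A) & !is.na(p)
  # per-marker HWE carrier expectation for the obligate allele
  carrier_exp <- ifelse(inf_B, 1 - (1 - p)^2, 1 - p^2)
  rows <- lapply(candidates, function(cand) {
    cd <- d[cand, ]
    ok <- use & !is.na(cd)
    n <- sum(ok)
    if (n == 0)
      return(data.frame(parent_assumed = parent, offspring = offspring,
                        candidate = cand, n_informative = 0L, f_obs = NA_real_,
                        f_exp = NA_real_, z = NA_real_, accepted = FALSE,
                        stringsAsFactors = FALSE))
    carries <- ifelse(inf_B[ok], cd[ok] >= 1L, cd[ok] <= 1L)
    f_obs <- mean(carries)
    f_exp <- mean(carrier_exp[ok])
    z <- (f_obs - f_exp) / sqrt(f_exp * (1 - f_exp) / n)
    data.frame(parent_assumed = parent, offspring = offspring, candidate = cand,
               n_informative = n, f_obs = f_obs, f_exp = f_exp, z = z,
               accepted = n >= n_min & z >= z_min & (f_obs - f_exp) >= excess_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sd_scan", class(out))
  out
}

#' Run the obligate-allele scan over all trio-less duos, both directions
#'
#' The direction of a PO pair is generally unknown, so for every accepted
#' duo that is not already explained by an accepted trio the scan is run
#' twice, once per direction. The direction that accumulates accepted
#' second-degree candidates is evidence for which member is the parent.
#'
#' @param panel Deduplicated [genotype_panel()].
#' @param duos PO edges from [find_po_duos()].
#' @param trios Trio table from [find_trios()] (accepted rows explain their
#'   two parental duos).
#' @param ... Passed to [sd_scan()].
#' @return Combined `sd_scan` data frame over duos and directions.
#' @export
sd_scan_duos <- function(panel, duos, trios = NULL, ...) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  explained <- character(0)
  if (!is.null(trios) && nrow(trios)) {
    acc <- trios[trios$accepted, , drop = FALSE]
    explained <- c(key(acc$offspring, acc$parent1), key(acc$offspring, acc$parent2))
  }
  todo <- duos[!(key(duos$id1, duos$id2) %in% explained), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(todo))) {
    out[[length(out) + 1L]] <- sd_scan(panel, todo$id1[i], todo$id2[i], ...)
    out[[length(out) + 1L]] <- sd_scan(panel, todo$id2[i], todo$id1[i], ...)
  }
  if (!length(out))
    return(data.frame(parent_assumed = character(0), offspring = character(0),
                      candidate = character(0), n_informative = integer(0),
                      f_obs = numeric(0), f_exp = numeric(0), z = numeric(0),
                      accepted = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Test a candidate grandparent pair of a missing parent
#'
#' Over the informative markers of a directed duo (assumed parent
#' homozygous, offspring heterozygous), the obligate allele descends from
#' the missing parent, hence from one of the missing parent's own parents.
#' A marker where neither candidate grandparent carries the obligate allele
#' is an incompatibility; a true grandparent pair shows none in the absence
#' of genotyping error.
#'
#' @param panel Deduplicated [genotype_panel()].
#' @param parent,offspring The focal duo (assumed direction).
#' @param g1,g2 Candidate grandparent pair (parents of the missing parent).
#' @return List of class `grandparent_test`: `incompatibilities`,
#'   `n_informative`, `rate`.
#' @export
test_grandparents <- function(panel, parent, offspring, g1, g2) {
  d <- panel$dosages
  ids <- c(parent, offspring, g1, g2)
  if (!all(ids %in% rownames(d)))
    stop("individual(s) not in panel: ",
         paste(setdiff(ids, rownames(d)), collapse = ", "))
  pd <- d[parent, ]; od <- d[offspring, ]
  g1d <- d[g1, ]; g2d <- d[g2, ]
  inf_B <- !is.na(pd) & !is.na(od) & pd == 0L & od == 1L
  inf_A <- !is.na(pd) & !is.na(od) & pd == 2L & od == 1L
  ok <- (inf_B | inf_A) & !is.na(g1d) & !is.na(g2d)
  n <- sum(ok)
  carries <- function(gd) ifelse(inf_B[ok], gd[ok] >= 1L, gd[ok] <= 1L)
  incomp <- sum(!carries(g1d) & !carries(g2d))
  structure(list(parent = parent, offspring = offspring, g1 = g1, g2 = g2,
                 incompatibilities = incomp, n_informative = n,
                 rate = if (n > 0) incomp / n else NA_real_),
            class = "grandparent_test")
}

#' @export
print.grandparent_test <- function(x, ...) {
  cat(sprintf("grandparent test (%s, %s) for duo %s -> %s: %d/%d incompatible (%.2f%%)\n",
              x$g1, x$g2, x$parent, x$offspring, x$incompatibilities,
              x$n_informative, 100 * x$rate))
  invisible(x)
}

#' Empirical background for the grandparent test
#'
#' The incompatibility rate of random candidate pairs provides the
#' acceptance background: a true grandparent pair sits far below it.
#'
#' @inheritParams test_grandparents
#' @param n_perm Number of random candidate pairs (default 100).
#' @param seed Integer seed.
#' @param exclude Individuals never drawn as candidates (besides the duo).
#' @return Numeric vector of permuted incompatibility rates.
#' @export
grandparent_background <- function(panel, parent, offspring, n_perm = 100L,
                                   seed, exclude = character(0)) {
  if (missing(seed)) stop("grandparent_background requires a seed")
  set.seed(seed)
  pool <- setdiff(rownames(panel$dosages), c(parent, offspring, exclude))
  if (length(pool) < 2) stop("not enough individuals for a permutation background")
  vapply(seq_len(n_perm), function(i) {
    gg <- sample(pool, 2)
    test_grandparents(panel, parent, offspring, gg[1], gg[2])$rate
  }, numeric(1))
}

#' Infer parent-offspring directions
#'
#' Applies three rules in priority order to the undirected PO edges:
#' (1) an accepted trio directs both of its parental edges toward the
#' offspring; (2) if A has a full sib C and C is PO with none of A's PO
#' partners, A is the parent in all its still-unresolved edges (an
#' individual cannot have a full sib among its own offspring's partners
#' unless its parents are present); (3) for a still-undirected duo, the
#' direction whose obligate-allele scan accepted at least `m_min`
#' second-degree candidates is adopted. In rule 3, accepted candidates that
#' are themselves detected PO partners of the scan's offspring are not
#' counted: they are first-degree relatives whose obligate-allele excess
#' reflects descent from the offspring itself, not independent evidence
#' about the missing parent's lineage (an offspring of two non-genotyped
#' parents would otherwise pull its own children in as spurious support for
#' the inverted direction). Contradictory evidence leaves the edge
#' undirected and logs a conflict; edges with no evidence stay undirected
#' and flagged.
#'
#' @param duos PO edges from [find_po_duos()].
#' @param trios Trio table from [find_trios()].
#' @param fs_edges FS edges from [find_fullsibs()].
#' @param sd_results Scan table from [sd_scan_duos()].
#' @param m_min Minimum accepted second-degree candidates for rule 3
#'   (default 2).
#' @return The duo data frame with added columns `parent`, `child`,
#'   `direction_evidence` ("trio", "fullsib", "sd" or NA). Attribute
#'   `conflicts` lists edges with contradictory evidence.
#' @export
infer_directions <- function(duos, trios = NULL, fs_edges = NULL,
                             sd_results = NULL, m_min = 2L) {
  n <- nrow(duos)
  duos$parent <- rep(NA_character_, n)
  duos$child <- rep(NA_character_, n)
  duos$direction_evidence <- rep(NA_character_, n)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ekey <- key(duos$id1, duos$id2)
  conflicts <- character(0)
  set_dir <- function(i, parent, evidence) {
    if (!is.na(duos$parent[i]) && duos$parent[i] != parent) {
      conflicts <<- c(conflicts, ekey[i])
      duos$parent[i] <<- NA_character_
      duos$child[i] <<- NA_character_
      duos$direction_evidence[i] <<- NA_character_
      return(invisible(NULL))
    }
    duos$parent[i] <<- parent
    duos$child[i] <<- setdiff(c(duos$id1[i], duos$id2[i]), parent)
    duos$direction_evidence[i] <<- evidence
  }
  # rule 1: trios
  if (!is.null(trios) && nrow(trios)) {
    for (r in which(trios$accepted)) {
      for (par in c(trios$parent1[r], trios$parent2[r])) {
        i <- which(ekey == key(trios$offspring[r], par))
        if (length(i) == 1) set_dir(i, par, "trio")
      }
    }
  }
  partners <- function(id)
    unique(c(duos$id2[duos$id1 == id], duos$id1[duos$id2 == id]))
  # rule 2: a full sib outside A's PO neighbourhood marks A as parent
  if (!is.null(fs_edges) && nrow(fs_edges)) {
    for (r in seq_len(nrow(fs_edges))) {
      for (a in c(fs_edges$id1[r], fs_edges$id2[r])) {
        cc <- setdiff(c(fs_edges$id1[r], fs_edges$id2[r]), a)
        if (length(intersect(partners(cc), partners(a))) > 0) next
        for (i in which((duos$id1 == a | duos$id2 == a) & is.na(duos$parent)))
          set_dir(i, a, "fullsib")
      }
    }
  }
  # rule 3: direction with >= m_min accepted second-degree candidates
  if (!is.null(sd_results) && nrow(sd_results)) {
    acc <- sd_results[sd_results$accepted, , drop = FALSE]
    # first-degree partners of the offspring are not second-degree evidence
    n_acc <- function(par, off)
      sum(acc$parent_assumed == par & acc$offspring == off &
            !acc$candidate %in% partners(off))
    for (i in which(is.na(duos$parent) & !(ekey %in% conflicts))) {
      a <- duos$id1[i]; b <- duos$id2[i]
      na_ <- n_acc(a, b); nb <- n_acc(b, a)
      if (na_ >= m_min && nb < m_min) set_dir(i, a, "sd")
      else if (nb >= m_min && na_ < m_min) set_dir(i, b, "sd")
      else if (na_ >= m_min && nb >= m_min) conflicts <- c(conflicts, ekey[i])
    }
  }
  attr(duos, "conflicts") <- unique(conflicts)
  duos
}

#' Close relatives not yet classified
#'
#' Ranks, for one individual, all others whose estimated kinship exceeds a
#' floor, excluding partners already classified as PO, FS or merged clones —
#' the pool where unresolved second-degree and more complex relationships
#' hide.
#'
#' @param ibd Data frame from [pairwise_ibd()].
#' @param individual Focal individual name.
#' @param phi_min Kinship floor (default 0.13, just above the second-degree
#'   expectation of 0.125).
#' @param exclude_edges Data frame(s) of already-classified edges (PO, FS)
#'   whose pairs are dropped.
#' @return Data frame `id`, `kinship`, `k0`, `k1`, `k2` ranked by kinship,
#'   labelled `unclassified close relative`.
#' @export
kinship_neighbors <- function(ibd, individual, phi_min = 0.13,
                              exclude_edges = NULL) {
  sel <- ibd$id1 == individual | ibd$id2 == individual
  tab <- ibd[sel, , drop = FALSE]
  tab$id <- ifelse(tab$id1 == individual, tab$id2, tab$id1)
  if (!is.null(exclude_edges) && nrow(exclude_edges)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    tab <- tab[!(key(tab$id1, tab$id2) %in%
                   key(exclude_edges$id1, exclude_edges$id2)), , drop = FALSE]
  }
  tab <- tab[tab$kinship > phi_min, , drop = FALSE]
  tab <- tab[order(-tab$kinship), c("id", "kinship", "k0", "k1", "k2")]
  tab$label <- if (nrow(tab)) "unclassified close relative" else character(0)
  rownames(tab) <- NULL
  tab
}
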