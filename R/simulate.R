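#' Pedigree event helpers
#'
#' Build the event list of a simulated pedigree. Events are applied in order;
#' every parent (or clone source) must have been defined earlier (founders
#' count as defined from the start).
#'
#' @param id Name of the new individual.
#' @param parent1,parent2 Parent names for a cross.
#' @param parent Parent name for a selfing.
#' @param source Source individual for a clone.
#' @param hidden Logical; hidden individuals are simulated but removed from
#'   the released panel (they model non-genotyped ancestors).
#' @return One-row data frame describing the event.
#' @name pedigree_events
NULL

#' @rdname pedigree_events
#' @export
ped_cross <- function(id, parent1, parent2, hidden = FALSE)
  data.frame(id = id, kind = "cross", parent1 = parent1, parent2 = parent2,
             hidden = hidden, stringsAsFactors = FALSE)

#' @rdname pedigree_events
#' @export
ped_self <- function(id, parent, hidden = FALSE)
  data.frame(id = id, kind = "self", parent1 = parent, parent2 = parent,
             hidden = hidden, stringsAsFactors = FALSE)

#' @rdname pedigree_events
#' @export
ped_clone <- function(id, source, hidden = FALSE)
  data.frame(id = id, kind = "clone", parent1 = source, parent2 = NA_character_,
             hidden = hidden, stringsAsFactors = FALSE)

#' Assemble a ground-truth pedigree
#'
#' @param founders Character vector of founder names.
#' @param events Data frame of events from [ped_cross()], [ped_self()],
#'   [ped_clone()] (rbind them), applied in row order.
#' @param hidden_founders Founders that are simulated but not released
#'   (non-genotyped ancestors).
#' @return An object of class `pedigree_truth`: parent map, clone map,
#'   founder set and hidden set, with a relationship oracle available through
#'   [relationship()].
#' @export
pedigree_truth <- function(founders, events = NULL, hidden_founders = character(0)) {
  if (anyDuplicated(founders)) stop("duplicate founder names")
  parents <- list()
  clones <- character(0)
  hidden <- hidden_founders
  defined <- founders
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (ev$id %in% defined) stop("individual defined twice: ", ev$id)
      if (ev$kind == "clone") {
        if (!ev$parent1 %in% defined) stop("clone source undefined: ", ev$parent1)
        clones[ev$id] <- ev$parent1
      } else {
        if (!all(c(ev$parent1, ev$parent2) %in% defined))
          stop("parent undefined for ", ev$id)
        parents[[ev$id]] <- c(ev$parent1, ev$parent2)
      }
      if (isTRUE(ev$hidden)) hidden <- c(hidden, ev$id)
      defined <- c(defined, ev$id)
    }
  }
  structure(list(founders = founders, parents = parents, clones = clones,
                 hidden = hidden, events = events,
                 individuals = defined),
            class = "pedigree_truth")
}

#' @export
print.pedigree_truth <- function(x, ...) {
  cat("pedigree_truth:", length(x$individuals), "individuals (",
      length(x$founders), "founders,", length(x$parents), "derived,",
      length(x$clones), "clones;", length(x$hidden), "hidden )\n")
  invisible(x)
}

# Follow clone chains back to the clonal source.
.clone_source <- function(truth, id) {
  while (id %in% names(truth$clones)) id <- truth$clones[[id]]
  id
}

#' True relationship of a pair
#'
#' The simulator's oracle. Clones are mapped to their source before
#' classification. Returned labels: `CLONE`, `PO` (parent-offspring),
#' `SELF` (parent vs its selfed offspring), `FS` (full sibs), `HS` (half
#' sibs), `GP` (grandparent-grandchild), `AV` (avuncular: full sib of a
#' parent), `UNREL`.
#'
#' @param truth A [pedigree_truth()].
#' @param a,b Individual names.
#' @return A single character label.
#' @export
relationship <- function(truth, a, b) {
  sa <- .clone_source(truth, a)
  sb <- .clone_source(truth, b)
  if (sa == sb) return("CLONE")
  P <- truth$parents
  pa <- P[[sa]]
  pb <- P[[sb]]
  if (!is.null(pb) && sa %in% pb)
    return(if (pb[1] == pb[2]) "SELF" else "PO")
  if (!is.null(pa) && sb %in% pa)
    return(if (pa[1] == pa[2]) "SELF" else "PO")
  if (!is.null(pa) && !is.null(pb)) {
    if (all(sort(pa) == sort(pb))) return("FS")
    if (length(intersect(pa, pb)) >= 1) return("HS")
  }
  gp_of <- function(x, y) {
    py <- P[[y]]
    if (is.null(py)) return(FALSE)
    any(vapply(unique(py), function(p) x %in% P[[p]], logical(1)))
  }
  if (gp_of(sa, sb) || gp_of(sb, sa)) return("GP")
  is_fs <- function(x, y) {
    px <- P[[x]]; py <- P[[y]]
    !is.null(px) && !is.null(py) && x != y && all(sort(px) == sort(py))
  }
  av_of <- function(x, y) {
    py <- P[[y]]
    if (is.null(py)) return(FALSE)
    any(vapply(unique(py), function(p) is_fs(x, p), logical(1)))
  }
  if (av_of(sa, sb) || av_of(sb, sa)) return("AV")
  "UNREL"
}

#' All pairwise true relationships
#'
#' @param truth A [pedigree_truth()].
#' @param ids Individuals to consider (default: all non-hidden).
#' @return Data frame `id1`, `id2` (id1 < id2), `relation`.
#' @export
true_relationships <- function(truth, ids = setdiff(truth$individuals, truth$hidden)) {
  if (length(ids) < 2) return(data.frame(id1 = character(0), id2 = character(0),
                                         relation = character(0)))
  cmb <- utils::combn(sort(ids), 2)
  data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
             relation = vapply(seq_len(ncol(cmb)),
                               function(i) relationship(truth, cmb[1, i], cmb[2, i]),
                               character(1)),
             stringsAsFactors = FALSE)
}

#' Simulate founder genotypes under Hardy-Weinberg equilibrium
#'
#' Per marker, a minor-allele frequency is drawn from `maf_sampler` and
#' assigned at random to the A or B allele; founder dosages are then
#' independent Binomial(2, p_B) draws. Markers are laid out in order along
#' `n_chrom` chromosomes.
#'
#' @param founders Character vector of founder names.
#' @param n_markers Number of markers.
#' @param maf_sampler Function of `n` returning minor-allele frequencies in
#'   (0, 0.5]. The default, Uniform(0.05, 0.4), gives a mean expected
#'   heterozygosity E\[2pq\] of about 0.33, the typical value for outbred
#'   grapevine material on this kind of array.
#' @param seed Integer seed (mandatory: every simulated fixture must be
#'   reproducible).
#' @param n_chrom Number of chromosomes to spread markers over (default 19,
#'   the grapevine karyotype).
#' @return A [genotype_panel()] of the founders. The true B-allele
#'   frequencies are kept in the `true_freqs` attribute.
#' @export
simulate_founders <- function(founders, n_markers,
                              maf_sampler = function(n) stats::runif(n, 0.05, 0.4),
                              seed, n_chrom = 19L) {
  if (missing(seed)) stop("simulate_founders requires a seed")
  set.seed(seed)
  m <- as.integer(n_markers)
  maf <- maf_sampler(m)
  if (any(maf <= 0 | maf > 0.5)) stop("maf_sampler must return values in (0, 0.5]")
  p <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)
  n <- length(founders)
  d <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n,
              dimnames = list(founders, sprintf("snp%05d", seq_len(m))))
  chrom <- sprintf("chr%02d", sort(rep(seq_len(n_chrom), length.out = m)))
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1000L
  alle <- t(vapply(seq_len(m), function(i) sample(c("A", "C", "G", "T"), 2),
                   character(2)))
  panel <- genotype_panel(d, data.frame(marker_id = colnames(d), chrom = chrom,
                                        pos = pos, allele_A = alle[, 1],
                                        allele_B = alle[, 2],
                                        stringsAsFactors = FALSE))
  attr(panel, "true_freqs") <- stats::setNames(p, colnames(d))
  panel
}

#' Gene-drop genotypes through a pedigree
#'
#' Mendelian transmission at unlinked loci: each child receives,
#' independently per marker, one allele from each parent (a B allele with
#' probability dosage/2); a selfing draws both gametes from the same parent;
#' clones copy dosages exactly. Applied before any genotyping error, so at
#' this stage true trios are Mendelian-consistent at every marker by
#' construction.
#'
#' @param panel Founder [genotype_panel()] from [simulate_founders()].
#' @param truth A [pedigree_truth()] whose founders match the panel rows.
#' @param seed Integer seed.
#' @return A `genotype_panel` containing founders and all derived
#'   individuals (hidden ones included; drop them with panel subsetting).
#' @export
gene_drop <- function(panel, truth, seed) {
  if (missing(seed)) stop("gene_drop requires a seed")
  if (!all(truth$founders %in% rownames(panel$dosages)))
    stop("panel lacks founder(s): ",
         paste(setdiff(truth$founders, rownames(panel$dosages)), collapse = ", "))
  set.seed(seed)
  m <- ncol(panel$dosages)
  all_ids <- truth$individuals
  d <- matrix(NA_integer_, nrow = length(all_ids), ncol = m,
              dimnames = list(all_ids, colnames(panel$dosages)))
  d[truth$founders, ] <- panel$dosages[truth$founders, , drop = FALSE]
  ev <- truth$events
  if (!is.null(ev) && nrow(ev)) {
    gamete <- function(parent_dos) {
      g <- stats::rbinom(m, 1L, parent_dos / 2)
      g[is.na(parent_dos)] <- NA_integer_
      g
    }
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, ]
      d[e$id, ] <- if (e$kind == "clone") d[e$parent1, ]
                   else gamete(d[e$parent1, ]) + gamete(d[e$parent2, ])
    }
  }
  out <- genotype_panel(d, panel$markers)
  attr(out, "true_freqs") <- attr(panel, "true_freqs")
  out
}

#' Add genotyping error and missingness
#'
#' Symmetric dosage-replacement error: each non-missing call is replaced,
#' with probability `error_rate`, by one of the other two dosage values
#' (uniformly); afterwards each call is set to missing with probability
#' `missing_rate`. Two clone copies corrupted independently at rate e are
#' expected to mismatch at about 2e(1-e) of markers, which is how the
#' default scenario error rate is calibrated against the sub-0.12%
#' clone-mismatch ceiling seen on real arrays.
#'
#' @param panel A [genotype_panel()].
#' @param error_rate Per-call replacement probability in \[0, 1).
#' @param missing_rate Per-call missingness probability in \[0, 1).
#' @param seed Integer seed.
#' @return The corrupted `genotype_panel`.
#' @export
corrupt_panel <- function(panel, error_rate, missing_rate, seed) {
  stopifnot(error_rate >= 0, error_rate < 1, missing_rate >= 0, missing_rate <= 1)
  if (missing(seed)) stop("corrupt_panel requires a seed")
  set.seed(seed)
  d <- panel$dosages
  if (error_rate > 0) {
    hit <- which(!is.na(d) & stats::runif(length(d)) < error_rate)
    if (length(hit)) {
      shift <- sample(1:2, length(hit), replace = TRUE)
      d[hit] <- (d[hit] + shift) %% 3L
    }
  }
  if (missing_rate > 0)
    d[stats::runif(length(d)) < missing_rate] <- NA_integer_
  out <- genotype_panel(d, panel$markers)
  attr(out, "true_freqs") <- attr(panel, "true_freqs")
  out
}

#' The standard validation scenario
#'
#' A packaged multi-generation pedigree emulating the statistical structure
#' of an 18K-array germplasm panel after QC: about 6,600 retained markers,
#' 40 genotyped founders, trios, full sibs, a selfing, clones, two
#' half-sibships through non-genotyped parents (with their genotyped
#' grandparent pairs and an avuncular relative each), a founder full-sib
#' pair whose parents are not genotyped, and unrelated singletons. Ground
#' truth is returned alongside, plus an accession-name table containing one
#' synonym pair and one homonym pair for the identity stage.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_markers Markers simulated before QC (default 10000, chosen so
#'   that roughly 6,600 survive the default marker filters at the default
#'   missingness).
#' @param error_rate Per-call genotyping error (default 1e-4, back-calculated
#'   so clone pairs stay below the 0.12% identity threshold and true trios
#'   show at most a handful of Mendelian errors at this marker count).
#' @param missing_rate Per-call missingness (default 0.005).
#' @param keep_hidden Keep non-genotyped ancestors in the released panel
#'   (useful to verify the obligate-allele scan against the true missing
#'   parent).
#' @return List with `panel` (corrupted, hidden individuals dropped unless
#'   `keep_hidden`), `truth` (a [pedigree_truth()]) and `names` (data frame
#'   `id`, `name`).
#' @export
standard_scenario <- function(seed, n_markers = 10000L, error_rate = 1e-4,
                              missing_rate = 0.005, keep_hidden = FALSE) {
  founders <- sprintf("F%02d", 1:40)
  hidden_founders <- sprintf("HF%d", 1:4)
  ev <- rbind(
    # half-sibship 1: hidden parent M1 = F08 x F09, with avuncular A1
    ped_cross("M1", "F08", "F09", hidden = TRUE),
    ped_cross("A1", "F08", "F09"),
    # half-sibship 2: hidden parent M2 = F30 x F31, with avuncular A2
    ped_cross("M2", "F30", "F31", hidden = TRUE),
    ped_cross("A2", "F30", "F31"),
    # founder-level full-sib pair with non-genotyped parents (direction rule 2)
    ped_cross("P1", "HF1", "HF2"),
    ped_cross("P2", "HF1", "HF2"),
    ped_cross("W1", "P1", "HF3"),
    ped_cross("W2", "P1", "HF4"),
    ped_cross("W3", "P1", "HF3"),
    # trio families among genotyped founders
    ped_cross("T1", "F01", "F02"),
    ped_cross("T2", "F01", "F02"),
    ped_cross("T3", "F03", "F04"),
    ped_cross("T4", "F03", "F04"),
    ped_cross("T5", "F05", "F06"),
    ped_self("S1", "F07"),
    ped_cross("U1", "F14", "F15"),
    ped_cross("U2", "F16", "F17"),
    ped_cross("U3", "F18", "F19"),
    ped_cross("U4", "F20", "F21"),
    ped_cross("U5", "F22", "F23"),
    ped_cross("U6", "F24", "F25"),
    # half-sib children of the hidden parents
    ped_cross("H1", "M1", "F10"),
    ped_cross("H2", "M1", "F11"),
    ped_cross("H3", "M1", "F12"),
    ped_cross("K1", "M2", "F32"),
    ped_cross("K2", "M2", "F33"),
    # third generation
    ped_cross("G1", "T1", "T3"),
    ped_cross("G2", "T1", "T3"),
    ped_cross("G3", "T5", "U1"),
    # clones
    ped_clone("CL1", "F01"),
    ped_clone("CL2", "T1"),
    ped_clone("CL3", "U5"),
    ped_clone("CL4", "H1"))
  truth <- pedigree_truth(c(founders, hidden_founders), ev,
                          hidden_founders = hidden_founders)
  fpanel <- simulate_founders(c(founders, hidden_founders), n_markers,
                              seed = seed)
  full <- gene_drop(fpanel, truth, seed = seed + 1L)
  full <- corrupt_panel(full, error_rate, missing_rate, seed = seed + 2L)
  panel <- if (keep_hidden) full else full[setdiff(rownames(full$dosages), truth$hidden), ]
  attr(panel, "true_freqs") <- attr(full, "true_freqs")
  ids <- rownames(panel$dosages)
  nm <- paste0("Var_", ids)
  names(nm) <- ids
  nm["CL1"] <- "AliasOfF01"      # synonym: same genotype, different name
  nm["CL3"] <- "AliasOfU5"       # synonym
  nm["CL2"] <- nm["T1"]          # plain duplicate under the same name
  nm["CL4"] <- nm["H1"]
  nm[c("F26", "F27")] <- "SharedName"  # homonym: one name on two genotypes
  list(panel = panel, truth = truth,
       names = data.frame(id = ids, name = unname(nm[ids]),
                          stringsAsFactors = FALSE))
}
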