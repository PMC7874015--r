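#' Identity-by-state counts for a pair
#'
#' IBS per marker is the number of alleles the two genotypes share by state:
#' for dosages d1, d2 this is 2 - |d1 - d2| (opposite homozygotes share
#' none). Markers missing in either individual are excluded.
#'
#' @param panel A [genotype_panel()].
#' @param id1,id2 Individual names.
#' @param markers Optional marker-id subset.
#' @return List of class `ibs_counts`: `N0`, `N1`, `N2`, `n_valid`, and a
#'   logical `valid` vector over the (subset) markers.
#' @export
ibs_counts <- function(panel, id1, id2, markers = NULL) {
  d <- panel$dosages
  if (!all(c(id1, id2) %in% rownames(d)))
    stop("individual(s) not in panel: ",
         paste(setdiff(c(id1, id2), rownames(d)), collapse = ", "))
  j <- if (is.null(markers)) seq_len(ncol(d)) else match(markers, colnames(d))
  x <- d[id1, j]; y <- d[id2, j]
  valid <- !is.na(x) & !is.na(y)
  ibs <- 2L - abs(x[valid] - y[valid])
  out <- list(N0 = sum(ibs == 0L), N1 = sum(ibs == 1L), N2 = sum(ibs == 2L),
              n_valid = sum(valid), valid = valid)
  if (out$n_valid == 0) warning("no pairwise-complete markers for ", id1, "/", id2)
  class(out) <- "ibs_counts"
  out
}

# Per-marker conditional IBS probabilities given IBD state, as functions of
# the B-allele frequency p (q = 1 - p):
#   P(IBS0|IBD0) = 2 p^2 q^2
#   P(IBS1|IBD0) = 4 p^3 q + 4 p q^3
#   P(IBS2|IBD0) = p^4 + q^4 + 4 p^2 q^2
#   P(IBS1|IBD1) = 2 p q          P(IBS2|IBD1) = 1 - 2 p q
#   P(IBS2|IBD2) = 1
.ibs_given_ibd <- function(p) {
  q <- 1 - p
  list(e00 = 2 * p^2 * q^2,
       e10 = 4 * p^3 * q + 4 * p * q^3,
       e20 = p^4 + q^4 + 4 * p^2 * q^2,
       e11 = 2 * p * q,
       e21 = 1 - 2 * p * q)
}

#' Expected IBS counts given IBD state
#'
#' Sums, over the supplied markers, of the per-marker conditional
#' probabilities P(IBS = i | IBD = z) under Hardy-Weinberg genotype
#' frequencies — the frequency-dependent expectations that the method of
#' moments inverts. Monomorphic markers (p of 0 or 1) carry no information
#' and are excluded with their count recorded.
#'
#' @param freqs Numeric vector of per-marker B-allele frequencies.
#' @return Object of class `expected_ibs`: list with `E` (3x3 matrix, rows
#'   IBS 0-2, columns IBD 0-2, each entry a sum over the retained markers),
#'   `n_valid` (number of retained markers) and `n_monomorphic`.
#' @export
expected_ibs <- function(freqs) {
  p <- freqs[!is.na(freqs)]
  mono <- p <= 0 | p >= 1
  p <- p[!mono]
  if (length(p) == 0) stop("no polymorphic markers; expectations undefined")
  e <- .ibs_given_ibd(p)
  n <- length(p)
  E <- matrix(c(sum(e$e00), sum(e$e10), sum(e$e20),
                0,          sum(e$e11), sum(e$e21),
                0,          0,          n),
              nrow = 3, dimnames = list(paste0("IBS", 0:2), paste0("IBD", 0:2)))
  structure(list(E = E, n_valid = n, n_monomorphic = sum(mono)),
            class = "expected_ibs")
}

# Core method-of-moments inversion; all arguments scalar (or equal-length).
# Raw solutions are unbiased but unconstrained; reported values are truncated
# to [0, 1] and renormalized onto the simplex (which introduces the usual
# boundary bias for pairs whose true k lies on the simplex edge).
.mom_k <- function(N0, N1, N2, n, E00, E10, E20, E11, E21) {
  k0r <- N0 / E00
  k1r <- (N1 - k0r * E10) / E11
  k2r <- (N2 - k0r * E20 - k1r * E21) / n
  k0 <- pmin(pmax(k0r, 0), 1)
  k1 <- pmin(pmax(k1r, 0), 1)
  k2 <- pmin(pmax(k2r, 0), 1)
  s <- k0 + k1 + k2
  list(k0 = k0 / s, k1 = k1 / s, k2 = k2 / s,
       k0_raw = k0r, k1_raw = k1r, k2_raw = k2r)
}

#' Method-of-moments IBD coefficients
#'
#' Inverts observed IBS counts against their frequency-dependent
#' expectations to estimate the probabilities (k0, k1, k2) that a pair
#' shares 0, 1 or 2 alleles identical by descent:
#' k0 = N0 / E\[IBS0|IBD0\], then k1 and k2 by sequential subtraction.
#' Raw solutions are truncated to \[0, 1\] and renormalized to the simplex,
#' and kinship is phi = k1/4 + k2/2; the unconstrained solutions are kept as
#' `k0_raw`, `k1_raw`, `k2_raw` (they are the unbiased moment estimates —
#' the truncated values are biased toward the interior for pairs whose true
#' coefficients lie on the simplex boundary, noticeably so on panels of a
#' few thousand markers). Counts and expectations must refer to the same
#' marker set.
#'
#' @param counts An [ibs_counts()] result (computed on polymorphic markers).
#' @param expected An [expected_ibs()] result over the same markers.
#' @return List of class `ibd_estimate`: `k0`, `k1`, `k2`, `kinship`,
#'   `n_valid`.
#' @export
mom_ibd <- function(counts, expected) {
  if (counts$n_valid == 0) stop("no valid markers; IBD undefined")
  if (counts$n_valid != expected$n_valid)
    stop("counts (", counts$n_valid, ") and expectations (", expected$n_valid,
         ") cover different marker sets")
  E <- expected$E
  if (E["IBS0", "IBD0"] <= 0) stop("E[IBS0|IBD0] is zero; markers uninformative")
  k <- .mom_k(counts$N0, counts$N1, counts$N2, counts$n_valid,
              E["IBS0", "IBD0"], E["IBS1", "IBD0"], E["IBS2", "IBD0"],
              E["IBS1", "IBD1"], E["IBS2", "IBD1"])
  structure(list(k0 = k$k0, k1 = k$k1, k2 = k$k2,
                 kinship = k$k1 / 4 + k$k2 / 2, n_valid = counts$n_valid,
                 k0_raw = k$k0_raw, k1_raw = k$k1_raw, k2_raw = k$k2_raw),
            class = "ibd_estimate")
}

#' @export
print.ibd_estimate <- function(x, ...) {
  cat(sprintf("ibd_estimate: k0 = %.3f, k1 = %.3f, k2 = %.3f (kinship %.3f, %d markers)\n",
              x$k0, x$k1, x$k2, x$kinship, x$n_valid))
  invisible(x)
}

#' IBD estimate for one pair
#'
#' Convenience wrapper restricting to markers that are polymorphic (at the
#' supplied frequencies) and non-missing in both individuals, then running
#' [ibs_counts()], [expected_ibs()] and [mom_ibd()].
#'
#' @param panel A [genotype_panel()].
#' @param id1,id2 Individual names.
#' @param freqs Per-marker B-allele frequencies (default: estimated from
#'   `panel`; on panels containing clones estimate them after [dedupe()]).
#' @return An `ibd_estimate`.
#' @export
pair_ibd <- function(panel, id1, id2, freqs = allele_frequencies(panel)) {
  freqs <- freqs[colnames(panel$dosages)]
  poly <- !is.na(freqs) & freqs > 0 & freqs < 1
  cnt <- ibs_counts(panel, id1, id2, markers = colnames(panel$dosages)[poly])
  mom_ibd(cnt, expected_ibs(freqs[poly][cnt$valid]))
}

#' IBD estimates for all pairs
#'
#' Vectorized method-of-moments over every unordered pair of individuals,
#' with per-pair expectations summed over exactly the markers that pair has
#' complete (and that are polymorphic at the supplied frequencies).
#'
#' @inheritParams pair_ibd
#' @return Data frame with one row per pair: `id1`, `id2`, `n_valid`, `N0`,
#'   `N1`, `N2`, `k0`, `k1`, `k2`, `kinship`.
#' @export
pairwise_ibd <- function(panel, freqs = allele_frequencies(panel)) {
  d <- panel$dosages
  n <- nrow(d)
  if (n < 2) stop("pairwise_ibd needs at least two individuals")
  freqs <- freqs[colnames(d)]
  poly <- !is.na(freqs) & freqs > 0 & freqs < 1
  d <- d[, poly, drop = FALSE]
  p <- freqs[poly]
  A <- lapply(0:2, function(g) {
    M <- (!is.na(d)) & d == g
    storage.mode(M) <- "double"
    M
  })
  V <- A[[1]] + A[[2]] + A[[3]]
  N2 <- tcrossprod(A[[1]]) + tcrossprod(A[[2]]) + tcrossprod(A[[3]])
  N0 <- tcrossprod(A[[1]], A[[3]]) + tcrossprod(A[[3]], A[[1]])
  nv <- tcrossprod(V)
  N1 <- nv - N0 - N2
  e <- .ibs_given_ibd(p)
  psum <- function(w) tcrossprod(V, sweep(V, 2, w, `*`))
  E00 <- psum(e$e00); E10 <- psum(e$e10); E20 <- psum(e$e20)
  E11 <- psum(e$e11); E21 <- psum(e$e21)
  ut <- which(upper.tri(nv), arr.ind = TRUE)
  k <- .mom_k(N0[ut], N1[ut], N2[ut], nv[ut],
              E00[ut], E10[ut], E20[ut], E11[ut], E21[ut])
  ids <- rownames(d)
  data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
             n_valid = nv[ut], N0 = N0[ut], N1 = N1[ut], N2 = N2[ut],
             k0 = k$k0, k1 = k$k1, k2 = k$k2,
             kinship = k$k1 / 4 + k$k2 / 2,
             stringsAsFactors = FALSE)
}

#' Mendelian errors for a putative parent-offspring duo
#'
#' A duo Mendelian error is a marker at which the two individuals are
#' opposite homozygotes — impossible for a true parent-offspring pair, which
#' shares one allele at every locus.
#'
#' @param panel A [genotype_panel()].
#' @param id1,id2 Individual names.
#' @param markers Optional marker-id subset.
#' @return List of class `duo_result`: `id1`, `id2`, `mendelian_errors`,
#'   `n_valid`, `error_rate`.
#' @export
mendel_errors_duo <- function(panel, id1, id2, markers = NULL) {
  cnt <- ibs_counts(panel, id1, id2, markers = markers)
  structure(list(id1 = id1, id2 = id2, mendelian_errors = cnt$N0,
                 n_valid = cnt$n_valid,
                 error_rate = if (cnt$n_valid > 0) cnt$N0 / cnt$n_valid else NA_real_),
            class = "duo_result")
}

# Opposite-homozygote counts for all pairs at once (full marker set).
.pairwise_duo_errors <- function(panel) {
  d <- panel$dosages
  H0 <- (!is.na(d)) & d == 0L
  H2 <- (!is.na(d)) & d == 2L
  storage.mode(H0) <- "double"; storage.mode(H2) <- "double"
  tcrossprod(H0, H2) + tcrossprod(H2, H0)
}

#' Mendelian errors for a putative trio
#'
#' Over markers where offspring and both candidate parents are all called, a
#' trio error is a marker at which no choice of one allele from each parent
#' can produce the offspring genotype: a homozygous offspring needs that
#' allele from both parents, a heterozygous offspring needs one parent able
#' to donate A and the other able to donate B.
#'
#' @param panel A [genotype_panel()].
#' @param offspring,parent1,parent2 Three distinct individual names.
#' @return List of class `trio_result`: the three ids, `mendelian_errors`,
#'   `n_valid`, `error_rate`.
#' @export
mendel_errors_trio <- function(panel, offspring, parent1, parent2) {
  ids <- c(offspring, parent1, parent2)
  if (length(unique(ids)) != 3) stop("trio requires three distinct individuals")
  d <- panel$dosages
  if (!all(ids %in% rownames(d)))
    stop("individual(s) not in panel: ",
         paste(setdiff(ids, rownames(d)), collapse = ", "))
  o <- d[offspring, ]; a <- d[parent1, ]; b <- d[parent2, ]
  valid <- !is.na(o) & !is.na(a) & !is.na(b)
  o <- o[valid]; a <- a[valid]; b <- b[valid]
  # donate_A: parent can transmit A (dosage <= 1); donate_B: dosage >= 1
  err <- (o == 0L & (a == 2L | b == 2L)) |
         (o == 2L & (a == 0L | b == 0L)) |
         (o == 1L & ((a == 0L & b == 0L) | (a == 2L & b == 2L)))
  n <- sum(valid)
  structure(list(offspring = offspring, parent1 = parent1, parent2 = parent2,
                 mendelian_errors = sum(err), n_valid = n,
                 error_rate = if (n > 0) sum(err) / n else NA_real_),
            class = "trio_result")
}

#' @export
print.duo_result <- function(x, ...) {
  cat(sprintf("duo %s / %s: %d Mendelian error(s) over %d markers (%.3f%%)\n",
              x$id1, x$id2, x$mendelian_errors, x$n_valid, 100 * x$error_rate))
  invisible(x)
}

#' @export
print.trio_result <- function(x, ...) {
  cat(sprintf("trio %s = %s x %s: %d Mendelian error(s) over %d markers (%.3f%%)\n",
              x$offspring, x$parent1, x$parent2, x$mendelian_errors,
              x$n_valid, 100 * x$error_rate))
  invisible(x)
}
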