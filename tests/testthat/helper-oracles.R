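# Independent oracles used to validate the analytical machinery.
# These deliberately avoid the package's closed forms and vectorized paths:
# expectations come from exhaustive enumeration, IBD proportions from an
# allele-tracking gene-dropper.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive enumeration of E[IBS state | IBD state] per marker.
# Genotypes are enumerated as ordered allele pairs so no HWE closed form is
# reused from the implementation.
oracle_expected_ibs <- function(p_vec) {
  E <- matrix(0, 3, 3, dimnames = list(paste0("IBS", 0:2), paste0("IBD", 0:2)))
  for (p in p_vec) {
    q <- 1 - p
    pa <- c(A = q, B = p)  # allele sampling probabilities
    ibs_of <- function(d1, d2) 2 - abs(d1 - d2)
    # IBD0: two independent ordered genotypes
    for (a1 in names(pa)) for (a2 in names(pa))
      for (b1 in names(pa)) for (b2 in names(pa)) {
        d1 <- sum(c(a1, a2) == "B"); d2 <- sum(c(b1, b2) == "B")
        w <- pa[a1] * pa[a2] * pa[b1] * pa[b2]
        E[ibs_of(d1, d2) + 1, 1] <- E[ibs_of(d1, d2) + 1, 1] + w
      }
    # IBD1: one shared allele X, one free allele per individual
    for (x in names(pa)) for (y1 in names(pa)) for (y2 in names(pa)) {
      d1 <- sum(c(x, y1) == "B"); d2 <- sum(c(x, y2) == "B")
      w <- pa[x] * pa[y1] * pa[y2]
      E[ibs_of(d1, d2) + 1, 2] <- E[ibs_of(d1, d2) + 1, 2] + w
    }
    # IBD2: identical genotype
    E[3, 3] <- E[3, 3] + 1
  }
  E
}

# Naive scalar method-of-moments, written independently of .mom_k.
oracle_mom <- function(N0, N1, N2, n, E) {
  k0 <- N0 / E["IBS0", "IBD0"]
  k1 <- (N1 - k0 * E["IBS1", "IBD0"]) / E["IBS1", "IBD1"]
  k2 <- (N2 - k0 * E["IBS2", "IBD0"] - k1 * E["IBS2", "IBD1"]) / n
  k <- c(k0, k1, k2)
  k[k < 0] <- 0; k[k > 1] <- 1
  k <- k / sum(k)
  list(k0 = k[1], k1 = k[2], k2 = k[3], kinship = k[2] / 4 + k[3] / 2)
}

# Allele-tracking gene drop for a nuclear family: returns, per marker, the
# two children's genotypes plus the true count of alleles shared IBD.
# Founder allele copies carry unique labels so IBD is exact, not inferred.
oracle_fullsib_drop <- function(n_markers, p, seed) {
  set.seed(seed)
  draw_founder <- function(tag) {
    alleles <- ifelse(stats::runif(2 * n_markers) < p, "B", "A")
    matrix(paste0(alleles, ":", tag, ":", rep(1:2, each = n_markers)),
           ncol = 2)
  }
  f1 <- draw_founder("f1"); f2 <- draw_founder("f2")
  gamete <- function(f) f[cbind(seq_len(n_markers),
                                sample(1:2, n_markers, replace = TRUE))]
  c1 <- cbind(gamete(f1), gamete(f2))
  c2 <- cbind(gamete(f1), gamete(f2))
  allele_state <- function(m) substr(m, 1, 1)
  dosage <- function(m) rowSums(allele_state(m) == "B")
  ibd <- (c1[, 1] == c2[, 1]) + (c1[, 2] == c2[, 2])
  list(d1 = dosage(c1), d2 = dosage(c2), ibd = ibd)
}

# A small random panel with missing calls for oracle-equivalence checks.
random_small_panel <- function(n_ind, n_mark, seed) {
  set.seed(seed)
  p <- stats::runif(n_mark, 0.1, 0.9)
  d <- matrix(stats::rbinom(n_ind * n_mark, 2L, rep(p, each = n_ind)),
              nrow = n_ind)
  d[stats::runif(length(d)) < 0.05] <- NA_integer_
  rownames(d) <- sprintf("i%02d", seq_len(n_ind))
  colnames(d) <- sprintf("m%03d", seq_len(n_mark))
  genotype_panel(d, data.frame(marker_id = colnames(d), chrom = "chr01",
                               pos = seq_len(n_mark) * 100L,
                               allele_A = "A", allele_B = "C",
                               stringsAsFactors = FALSE))
}
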