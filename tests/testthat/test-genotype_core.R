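make_panel <- function() {
  d <- rbind(s1 = c(0L, 1L, 2L, NA, 1L, 0L),
             s2 = c(2L, 1L, 0L, 2L, NA, 0L),
             s3 = c(1L, NA, 1L, 1L, 1L, 2L))
  colnames(d) <- sprintf("m%d", 1:6)
  genotype_panel(d, data.frame(marker_id = colnames(d), chrom = "chr01",
                               pos = 1:6 * 50L, allele_A = "A",
                               allele_B = c("C", "G", "T", "C", "G", "T"),
                               stringsAsFactors = FALSE))
}

test_that("panel construction validates values, names and alleles", {
  p <- make_panel()
  expect_s3_class(p, "genotype_panel")
  expect_identical(dim(p), c(3L, 6L))
  bad <- p$dosages; bad[1, 1] <- 3L
  expect_error(genotype_panel(bad, p$markers), "outside")
  dup <- p$dosages; rownames(dup)[2] <- "s1"
  expect_error(genotype_panel(dup, p$markers), "duplicate individual")
  mk <- p$markers; mk$allele_B[1] <- "A"
  expect_error(genotype_panel(p$dosages, mk), "allele_A equals allele_B")
})

test_that("VCF round trip reproduces dosages, orders and metadata", {
  p <- make_panel()
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_panel(p, tmp)
  p2 <- read_panel(tmp)
  expect_identical(p2$dosages, p$dosages)
  expect_identical(p2$markers, p$markers)
})

test_that("VCF reader honours GT semantics and skips non-biallelic-SNP rows", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "chr01\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr01\t200\tv2\tA\tG\t.\tPASS\t.\tGT\t1/1\t./.",
    "chr01\t250\tv3\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/0",
    "chr01\t300\tv4\tAT\tG\t.\tPASS\t.\tGT\t0/0\t0/0",
    "chr01\t400\tv5\tA\tG\t.\tPASS\t.\tGT\t0|1\t./0"), tmp)
  expect_message(p <- read_panel(tmp), "skipped 2")
  expect_identical(colnames(p$dosages), c("v1", "v2", "v5"))
  expect_identical(unname(p$dosages["a", ]), c(0L, 2L, 1L))
  # missing, and the half call, are NA
  expect_identical(unname(p$dosages["b", ]), c(1L, NA_integer_, NA_integer_))
})

test_that("dosage-table round trip is exact and NA maps to missing", {
  p <- make_panel()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_panel(p, tmp, format = "dosage")
  expect_true(file.exists(paste0(tmp, ".markers.tsv")))
  p2 <- read_panel(tmp, format = "dosage")
  expect_identical(p2$dosages, p$dosages)
  expect_identical(p2$markers, p$markers)
})

test_that("merge reconciles swapped allele labels by flipping dosages", {
  p1 <- make_panel()
  p2 <- make_panel()
  rownames(p2$dosages) <- c("t1", "t2", "t3")
  # swap labels of marker m3 in panel 2 and flip its dosages accordingly
  p2$markers$allele_A[3] <- p1$markers$allele_B[3]
  p2$markers$allele_B[3] <- p1$markers$allele_A[3]
  p2$dosages[, 3] <- 2L - p2$dosages[, 3]
  m <- merge_panels(list(p1, p2))
  expect_identical(m$dosages["t1", ], p1$dosages["s1", ])
  expect_identical(m$markers, p1$markers)
})

test_that("merge drops irreconcilable markers and suffixes name clashes", {
  p1 <- make_panel()
  p2 <- make_panel()
  p2$markers$allele_B[2] <- "A"   # neither match nor swap vs (A, G)
  p2$markers$allele_A[2] <- "T"
  m <- merge_panels(list(p1, p2))
  expect_false("m2" %in% m$markers$marker_id)
  expect_setequal(attr(m, "merge_log")$dropped_markers, "m2")
  expect_setequal(rownames(m$dosages),
                  c("s1", "s2", "s3", "s1.2", "s2.2", "s3.2"))
  expect_identical(m$dosages["s1.2", "m1"], p1$dosages["s1", "m1"])
})

test_that("merging panels with disjoint markers is an error", {
  p1 <- make_panel()
  p2 <- make_panel()
  p2$markers$marker_id <- paste0("x", p2$markers$marker_id)
  colnames(p2$dosages) <- p2$markers$marker_id
  expect_error(merge_panels(list(p1, p2)), "empty intersection")
})

test_that("marker filters remove by missingness and MAF with reasons", {
  set.seed(5)
  n <- 200
  d <- matrix(1L, nrow = n, ncol = 3,
              dimnames = list(sprintf("i%03d", 1:n), c("ok", "miss", "rare")))
  d[, "ok"] <- rbinom(n, 2, 0.5)
  d[, "miss"] <- rbinom(n, 2, 0.5)
  d[sample(n, 4), "miss"] <- NA          # 2% missing > 1%
  d[, "rare"] <- rbinom(n, 2, 0.03)      # MAF ~3% < 5%
  p <- genotype_panel(d, data.frame(marker_id = colnames(d), chrom = "chr01",
                                    pos = 1:3 * 10L, allele_A = "A",
                                    allele_B = "G"))
  fm <- filter_markers(p)
  expect_identical(fm$panel$markers$marker_id, "ok")
  rep <- fm$report
  expect_identical(rep$reason[rep$marker_id == "miss"], "missingness")
  expect_identical(rep$reason[rep$marker_id == "rare"], "maf")
})

test_that("individual filters implement the qc and parentage presets", {
  m <- 400
  d <- rbind(clean = rbinom(m, 2, 0.5),
             holey = rbinom(m, 2, 0.5),
             inbred = rep(c(0L, 2L), m / 2))
  d["holey", seq_len(0.06 * m)] <- NA   # 6% missing
  # make 'clean' a typical outbred profile: H ~ 0.5 here, inside [0.25, 0.45]?
  d["clean", ] <- rep(c(0L, 1L, 1L, 2L), m / 4)  # H = 0.5 -> outside parentage
  d["clean", seq(2, m, by = 4)] <- 0L            # H = 0.25 exactly
  colnames(d) <- sprintf("m%03d", seq_len(m))
  p <- genotype_panel(d, data.frame(marker_id = colnames(d), chrom = "chr01",
                                    pos = seq_len(m) * 10L, allele_A = "A",
                                    allele_B = "G"))
  qc <- filter_individuals(p, "qc")
  expect_false("holey" %in% rownames(qc$panel$dosages))
  expect_true(all(c("clean", "inbred") %in% rownames(qc$panel$dosages)))
  par <- filter_individuals(p, "parentage")
  # inbred H = 0 < 0.25 removed; clean H = 0.25 kept (bounds inclusive)
  expect_false("inbred" %in% rownames(par$panel$dosages))
  expect_true("clean" %in% rownames(par$panel$dosages))
  expect_identical(par$report$reason[par$report$id == "holey"],
                   "missingness+heterozygosity")
})

test_that("allele frequencies ignore missing calls and flag empty markers", {
  d <- rbind(a = c(0L, 2L, 1L, NA), b = c(1L, 2L, NA, NA), c = c(2L, 2L, NA, NA))
  colnames(d) <- sprintf("m%d", 1:4)
  p <- genotype_panel(d, data.frame(marker_id = colnames(d), chrom = "chr01",
                                    pos = 1:4 * 10L, allele_A = "A",
                                    allele_B = "G"))
  f <- allele_frequencies(p)
  expect_equal(unname(f[1:3]), c(0.5, 1, 0.5))
  expect_true(is.na(f[4]))
  expect_identical(attr(f, "no_calls"), "m4")
})

test_that("marker and individual filtering decisions are per-entity", {
  set.seed(41)
  p <- scenario_analysis(1)$sc$panel
  sub_m <- p[, sample(colnames(p$dosages), 300)]
  whole <- filter_markers(p)$panel$markers$marker_id
  part <- filter_markers(sub_m)$panel$markers$marker_id
  expect_setequal(part, intersect(whole, colnames(sub_m$dosages)))
  ids <- rownames(p$dosages)[1:20]
  whole_i <- rownames(filter_individuals(p, "qc")$panel$dosages)
  part_i <- rownames(filter_individuals(p[ids, ], "qc")$panel$dosages)
  expect_setequal(part_i, intersect(whole_i, ids))
})

test_that("LD pruning drops later members of correlated pairs only", {
  set.seed(11)
  n <- 400
  x <- rbinom(n, 2, 0.4)
  y <- x; flip <- sample(n, 12); y[flip] <- rbinom(12, 2, 0.4)  # r2 ~ 0.9
  z <- rbinom(n, 2, 0.4)                                        # independent
  d <- cbind(m1 = x, m2 = x, m3 = y, m4 = z)
  rownames(d) <- sprintf("i%03d", 1:n)
  p <- genotype_panel(d, data.frame(marker_id = colnames(d), chrom = "chr01",
                                    pos = 1:4 * 1000L, allele_A = "A",
                                    allele_B = "G"))
  r2_m3 <- cor(x, y)^2
  expect_gt(r2_m3, 0.8)
  pr <- ld_prune(p)
  kept <- pr$markers$marker_id
  expect_identical(kept, c("m1", "m4"))        # duplicate and 0.9-pair pruned
  expect_setequal(attr(pr, "pruned"), c("m2", "m3"))
})

test_that("independent simulated markers survive pruning", {
  f <- simulate_founders(sprintf("F%03d", 1:500), 60, seed = 21)
  pr <- ld_prune(f)
  expect_identical(ncol(pr$dosages), 60L)
})

test_that("flipping allele labels twice is the identity", {
  flip <- function(p) {
    p$dosages <- 2L - p$dosages
    tmp <- p$markers$allele_A
    p$markers$allele_A <- p$markers$allele_B
    p$markers$allele_B <- tmp
    genotype_panel(p$dosages, p$markers)
  }
  p <- make_panel()
  expect_identical(flip(flip(p)), p)
})
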