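fake_ibd <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(id1 = r[[1]], id2 = r[[2]], n_valid = 5000, N0 = 0, N1 = 0,
               N2 = 0, k0 = as.numeric(r[[3]]), k1 = as.numeric(r[[4]]),
               k2 = as.numeric(r[[5]]),
               kinship = as.numeric(r[[4]]) / 4 + as.numeric(r[[5]]) / 2,
               stringsAsFactors = FALSE)))
}

test_that("PO duos are called below the k0 threshold and annotated", {
  ibd <- fake_ibd(list("a", "b", 0.004, 0.99, 0.006),
                  list("a", "c", 0.029, 0.95, 0.021),
                  list("b", "c", 0.25, 0.5, 0.25),
                  list("a", "d", 0.98, 0.02, 0))
  duos <- find_po_duos(ibd)
  expect_setequal(pair_key(duos$id1, duos$id2), c("a b", "a c"))
  expect_identical(unique(duos$relation), "PO")
  expect_length(attr(duos, "k0_values"), 4L)
  expect_identical(nrow(find_po_duos(ibd, k0_max = 0)), 0L)
})

test_that("standard-scenario duos and trios are recovered exactly", {
  a <- scenario_analysis(1)
  sc <- score_recovery(a$truth, po_edges = a$duos, trios = a$trios,
                       analysis_ids = rownames(a$pf$dosages))
  expect_identical(sc$po$precision, 1)
  expect_identical(sc$po$recall, 1)
  expect_identical(sc$trios$precision, 1)
  expect_identical(sc$trios$recall, 1)
  # every accepted duo is confirmed by a near-zero Mendelian error rate
  expect_true(all(a$duos$duo_error_rate < 0.001))
})

test_that("a parent swapped for its full sib explodes the trio error count", {
  a <- scenario_analysis(1)
  good <- mendel_errors_trio(a$pf, "G1", "T1", "T3")
  bad <- mendel_errors_trio(a$pf, "G1", "T2", "T3")  # T2 is T1's full sib
  expect_lte(good$error_rate, 0.002)
  expect_gt(bad$error_rate, 0.02)   # an order of magnitude over the threshold
  # no inversion: the accepted trio has the smallest error count for G1
  g1 <- a$trios[a$trios$offspring == "G1", ]
  expect_true(all(g1$errors[g1$accepted] <= g1$errors[!g1$accepted]))
})

test_that("full-sib calling excludes PO pairs and applies k2 strictly", {
  ibd <- fake_ibd(list("v", "w", 0.23, 0.42, 0.35),   # FS-like signature
                  list("v", "x", 0.01, 0.97, 0.02),   # PO with high k2 noise
                  list("w", "x", 0.5, 0.5, 0),
                  list("v", "y", 0.6, 0.3, 0.1))
  po <- find_po_duos(ibd)
  fs <- find_fullsibs(ibd, po)
  expect_identical(fs$id1, "v")
  expect_identical(fs$id2, "w")
  expect_identical(fs$relation, "FS")
  # the same pair below the conservative bar is not called
  expect_identical(nrow(find_fullsibs(ibd, po, k2_min = 0.4)), 0L)
})

test_that("obligate-allele scan separates lineage members from everyone else", {
  a <- scenario_analysis(1)
  scan <- sd_scan(a$pf, "F10", "H1", freqs = a$freqs)
  rels <- missing_parent_relatives(a$truth, "F10", "H1",
                                   rownames(a$pf$dosages))
  expect_setequal(rels, c("F08", "F09", "A1", "H2", "H3"))
  expect_true(all(scan$accepted[scan$candidate %in% rels]))
  other <- scan[!scan$candidate %in% rels, ]
  expect_false(any(other$accepted))
  expect_true(all(abs(other$z) < 4, na.rm = TRUE))
  # informative count must clear the configured floor
  expect_true(all(scan$n_informative >= 100))
})

test_that("the literal single-homozygote-class variant halves the markers", {
  a <- scenario_analysis(1)
  both <- sd_scan(a$pf, "F10", "H1", candidates = "H2", freqs = a$freqs)
  aa <- sd_scan(a$pf, "F10", "H1", candidates = "H2", freqs = a$freqs,
                literal_aa_only = TRUE)
  expect_lt(aa$n_informative, both$n_informative)
  expect_gt(aa$n_informative, 0.25 * both$n_informative)
})

test_that("the scan driver covers both directions of trio-less duos only", {
  a <- scenario_analysis(1)
  covered <- unique(pair_key(a$sdres$parent_assumed, a$sdres$offspring))
  acc <- a$trios[a$trios$accepted, ]
  explained <- c(pair_key(acc$offspring, acc$parent1),
                 pair_key(acc$offspring, acc$parent2))
  expect_length(intersect(covered, explained), 0L)
  # both directions present for each scanned duo
  dirs <- paste(a$sdres$parent_assumed, a$sdres$offspring)
  for (k in covered) {
    ids <- strsplit(k, " ")[[1]]
    expect_true(all(c(paste(ids[1], ids[2]), paste(ids[2], ids[1])) %in% dirs))
  }
})

test_that("grandparent incompatibilities rank true pair < mixed < unrelated", {
  sc0 <- .gk_cache$gp_clean %||% standard_scenario(9, error_rate = 0,
                                                   missing_rate = 0)
  .gk_cache$gp_clean <- sc0
  true_pair <- test_grandparents(sc0$panel, "F10", "H1", "F08", "F09")
  mixed <- test_grandparents(sc0$panel, "F10", "H1", "F08", "F20")
  unrel <- test_grandparents(sc0$panel, "F10", "H1", "F20", "F21")
  expect_identical(true_pair$incompatibilities, 0L)
  expect_gt(mixed$rate, 0.02)
  expect_gt(unrel$rate, mixed$rate)
})

test_that("trio membership directs both parental edges", {
  duos <- fake_ibd(list("P1", "O", 0.01, 0.99, 0),
                   list("P2", "O", 0.01, 0.99, 0))
  duos$relation <- "PO"
  trios <- data.frame(offspring = "O", parent1 = "P1", parent2 = "P2",
                      errors = 0L, n_valid = 5000L, error_rate = 0,
                      accepted = TRUE, stringsAsFactors = FALSE)
  res <- infer_directions(duos, trios)
  expect_identical(res$parent, c("P1", "P2"))
  expect_identical(res$child, c("O", "O"))
  expect_identical(unique(res$direction_evidence), "trio")
})

test_that("a detached full sib marks its sibling as parent of all its duos", {
  duos <- fake_ibd(list("A", "c1", 0.01, 0.99, 0),
                   list("A", "c2", 0.02, 0.97, 0.01),
                   list("A", "c3", 0.01, 0.98, 0.01))
  duos$relation <- "PO"
  fs <- fake_ibd(list("A", "S", 0.25, 0.5, 0.25))
  fs$relation <- "FS"
  res <- infer_directions(duos, fs_edges = fs)
  expect_identical(res$parent, rep("A", 3))
  expect_identical(unique(res$direction_evidence), "fullsib")
  # but not when the sib shares a PO partner with A (A could be the child)
  duos2 <- rbind(duos, {
    e <- fake_ibd(list("S", "c1", 0.01, 0.99, 0)); e$relation <- "PO"; e
  })
  res2 <- infer_directions(duos2, fs_edges = fs)
  expect_true(all(is.na(res2$parent)))
})

test_that("second-degree evidence directs a duo, first-degree does not count", {
  duos <- fake_ibd(list("P", "O", 0.01, 0.99, 0),
                   list("O", "D", 0.01, 0.99, 0),   # D is O's child
                   list("P", "E", 0.01, 0.99, 0))   # E is P's child
  duos$relation <- "PO"
  sd_tab <- data.frame(
    parent_assumed = c("P", "P", "O", "O"),
    offspring = c("O", "O", "P", "P"),
    candidate = c("x1", "x2", "y1", "E"),
    n_informative = 1000L, f_obs = 0.8, f_exp = 0.55, z = 10,
    accepted = TRUE, stringsAsFactors = FALSE)
  res <- infer_directions(duos, sd_results = sd_tab)
  i <- which(pair_key(res$id1, res$id2) == pair_key("P", "O"))
  # P-direction has 2 independent candidates; O-direction has y1 plus E,
  # but E is a detected PO partner of the scanned offspring P and is
  # discounted as first-degree -> the P-as-parent direction wins
  expect_identical(res$parent[i], "P")
  expect_identical(res$direction_evidence[i], "sd")
})

test_that("conflicting or absent evidence leaves edges undirected", {
  duos <- fake_ibd(list("a", "b", 0.01, 0.99, 0))
  duos$relation <- "PO"
  expect_true(is.na(infer_directions(duos)$parent))
  sd_tab <- data.frame(
    parent_assumed = c("a", "a", "b", "b"), offspring = c("b", "b", "a", "a"),
    candidate = c("u1", "u2", "w1", "w2"), n_informative = 1000L,
    f_obs = 0.8, f_exp = 0.55, z = 10, accepted = TRUE,
    stringsAsFactors = FALSE)
  res <- infer_directions(duos, sd_results = sd_tab)
  expect_true(is.na(res$parent))
  expect_identical(attr(res, "conflicts"), "a b")
})

test_that("direction inference is sound against simulator truth", {
  a <- scenario_analysis(1)
  for (i in which(!is.na(a$dirs$parent))) {
    child_src <- clone_src(a$truth, a$dirs$child[i])
    expect_true(clone_src(a$truth, a$dirs$parent[i]) %in%
                  a$truth$parents[[child_src]])
  }
})

test_that("kinship neighbours rank unclassified relatives above the floor", {
  ibd <- fake_ibd(list("f", "po", 0.01, 0.99, 0),     # phi ~ 0.25
                  list("f", "gp", 0.47, 0.53, 0),     # phi ~ 0.13-0.14
                  list("f", "un", 0.99, 0.01, 0),     # phi ~ 0
                  list("po", "gp", 0.5, 0.5, 0))
  po <- find_po_duos(ibd)
  nb <- kinship_neighbors(ibd, "f", exclude_edges = po)
  expect_identical(nb$id, "gp")
  expect_identical(nb$label, "unclassified close relative")
  expect_false("po" %in% nb$id)
  expect_false("un" %in% nb$id)
})

test_that("network exports round-trip and carry trio structure", {
  a <- scenario_analysis(1)
  net <- pedigree_network(a$dirs, a$fs, a$trios,
                          nodes = data.frame(id = rownames(a$pf$dosages),
                                             name = rownames(a$pf$dosages)))
  expect_s3_class(net, "pedigree_network")
  # trios appear as two directed edges sharing a trio id
  tid <- net$edges$trio_id[!is.na(net$edges$trio_id)]
  expect_true(all(table(tid) == 2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "edge_tsv")
  back <- read_network(tsv)
  expect_identical(nrow(back$edges), nrow(net$edges))
  expect_identical(back$edges$id1, net$edges$id1)
  expect_identical(back$edges$parent, net$edges$parent)
  expect_equal(back$edges$k0, net$edges$k0, tolerance = 1e-9)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  dot <- withr::local_tempfile(fileext = ".dot")
  export_network(net, dot, "dot")
  expect_gt(length(readLines(dot)), nrow(net$edges))
})

test_that("an empty network still exports valid documents", {
  net <- pedigree_network(fake_ibd(list("a", "b", 0.5, 0.5, 0))[0, ])
  expect_identical(nrow(net$edges), 0L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "edge_tsv")
  expect_identical(nrow(read_network(tsv)$edges), 0L)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  expect_silent(igraph::read_graph(gml, format = "graphml"))
})
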