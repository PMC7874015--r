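Package: grapekin
Title: SNP-Based Parentage and Pedigree Reconstruction for Clonal Germplasm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Kinship inference for diploid, biallelic SNP panels typical of
    clonally propagated germplasm collections (grapevine and similar crops).
    Provides genotype-panel input/output (VCF and a dosage-table dialect),
    marker and individual quality control, LD pruning, duplicate/clone
    detection by pairwise mismatch with synonym and homonym cross-tabulation,
    method-of-moments estimation of IBD coefficients (k0, k1, k2) and kinship,
    Mendelian-error tests for parent-offspring duos and trios, a conditional
    obligate-allele scan for second-degree relatives through a non-genotyped
    parent, grandparent-pair testing, parent-offspring direction inference,
    and pedigree-network assembly and export. A gene-dropping simulator with
    a known-truth pedigree oracle supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
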