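# grapekin

SNP-based kinship inference for clonally propagated germplasm collections.

Grapevine and similar crops are maintained as clones, exchanged under many
names, and descend from a surprisingly small set of recurring founder
varieties. Given a diploid, biallelic SNP panel (a few thousand markers from
a genotyping array), `grapekin` reconstructs the relationships hiding in a
collection:

* **duplicates, synonyms and homonyms** — pairwise mismatch clustering at a
  sub-0.12% identity threshold, with a name-by-genotype cross-tabulation;
* **parent–offspring (PO) duos** — method-of-moments IBD coefficients with
  Mendelian-error confirmation;
* **trios** — both parents of an offspring, accepted on a trio
  Mendelian-error rate;
* **full sibs** — a conservative k2 threshold;
* **second-degree relatives through a *non-genotyped* parent** — a
  conditional obligate-allele scan, plus a grandparent-pair test;
* **PO direction inference and a pedigree network** — exported as edge TSV,
  GraphML or DOT.

A gene-dropping simulator with a known-truth pedigree oracle
(`standard_scenario()`) makes the whole pipeline testable end to end.

## The statistics at the core

For a pair of individuals, let `N_i` be the number of markers at IBS state
`i` (sharing `i` alleles by state), and let the per-marker probabilities of
IBS given IBD be, with B-allele frequency `p`, `q = 1 − p`:

```
P(IBS0 | IBD0) = 2 p² q²
P(IBS1 | IBD0) = 4 p³ q + 4 p q³
P(IBS2 | IBD0) = p⁴ + q⁴ + 4 p² q²
P(IBS1 | IBD1) = 2 p q          P(IBS2 | IBD1) = 1 − 2 p q
P(IBS2 | IBD2) = 1
```

Summing these over markers gives expectations `E[i|z]`, and the
method-of-moments IBD coefficients are solved in cascade:

```
k0 = N0 / E[0|0]
k1 = (N1 − k0 · E[1|0]) / E[1|1]
k2 = (N2 − k0 · E[2|0] − k1 · E[2|1]) / n
```

truncated to `[0, 1]`, renormalized to `k0 + k1 + k2 = 1`, with kinship
`φ = k1/4 + k2/2`. PO pairs sit at `(k0, k1, k2) ≈ (0, 1, 0)`, full sibs at
`(¼, ½, ¼)`, second-degree relatives at `(½, ½, 0)`.

A **duo Mendelian error** is an opposite-homozygote marker (impossible for a
true PO pair); a **trio error** is a marker where no choice of one allele
per parent can produce the offspring. The **obligate-allele scan** uses
markers where a known parent is homozygous and the offspring heterozygous:
the offspring allele the parent lacks must come from the other — possibly
missing — parent, so relatives of that missing parent carry it far in excess
of the Hardy–Weinberg carrier frequency. The excess is standardized to a z
score and accepted at `z ≥ 4` with an absolute excess of at least 0.15 over
at least 100 informative markers.

## Worked example

```r
library(grapekin)
sc <- standard_scenario(seed = 1)     # panel + known-truth pedigree
sc$panel
#> genotype_panel: 71 individuals x 10000 markers
#>   missing calls: 0.50%
#>   chromosomes: 19

qc <- filter_individuals(filter_markers(sc$panel)$panel, "qc")$panel
mm <- pairwise_mismatch(qc)
mm
#> mismatch_matrix: 71 individuals; 0 unreliable pair(s)
#>   range 0.000% - 51.4%
```

The mismatch distribution is sharply bimodal: clone pairs differ at under
0.05% of markers (genotyping error only), all distinct varieties at 17% or
more, so clustering at the 0.12% threshold isolates exactly the duplicated
accessions. After deduplication and the stricter parentage QC:

```r
clusters  <- cluster_identicals(mm)
parentage <- filter_individuals(dedupe(qc, clusters), "parentage")$panel
ibd <- pairwise_ibd(ld_prune(parentage))
pair_ibd(parentage, "F01", "T1")
#> ibd_estimate: k0 = 0.000, k1 = 1.000, k2 = 0.000 (kinship 0.250, 6649 markers)

duos  <- find_po_duos(ibd, parentage)   # k0 < 0.03, error-confirmed
trios <- find_trios(parentage, duos)
head(trios[trios$accepted, c("offspring","parent1","parent2","errors","error_rate")], 3)
#>   offspring parent1 parent2 errors   error_rate
#> 1        A1     F08     F09      0 0.0000000000
#> 2        A2     F30     F31      1 0.0001503986
#> 7        G1      T1      T3      0 0.0000000000
```

`H1` is a child of founder `F10` and a *non-genotyped* parent. Scanning the
obligate alleles of the `F10 → H1` duo flags exactly the missing parent's
lineage — its other children (`H2`, `H3`), its parents (`F08`, `F09`) and
its full sib (`A1`) — and nobody else:

```r
scan <- sd_scan(parentage, "F10", "H1")
subset(scan, accepted, select = c(candidate, n_informative, f_obs, f_exp, z))
#>    candidate n_informative     f_obs     f_exp        z
#> 8        F08          1201 0.7876769 0.5738358 14.98582
#> 9        F09          1201 0.7735221 0.5738358 13.99386
#> 40        A1          1201 0.7926728 0.5738358 15.33592
#> 58        H2          1201 0.7943381 0.5738358 15.45263
#> 59        H3          1201 0.7685262 0.5738358 13.64375

test_grandparents(parentage, "F10", "H1", "F08", "F09")
#> grandparent test (F08, F09) for duo F10 -> H1: 0/1201 incompatible (0.00%)
```

`infer_directions()` then orients duos from trio membership, full-sib
evidence and the scan, and `pedigree_network()` / `export_network()` emit
the result. The same analysis runs as a staged, file-backed pipeline —
`run_pipeline(pipeline_config(seed = 1), "out/")` — or from the shell via
`inst/cli/grapekin.R` with subcommands `simulate`, `qc`, `dedupe`, `relate`,
`pedigree`, `report`, `run`.

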