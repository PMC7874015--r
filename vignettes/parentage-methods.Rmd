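---
title: "Methods: SNP parentage and pedigree reconstruction in clonal germplasm"
author: "grapekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP parentage and pedigree reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapekin)
```

## The problem

Germplasm collections of clonally propagated crops accumulate three kinds of
structure that confound each other: the *same* genotype under several names
(clones, synonyms), *different* genotypes under one name (homonyms), and a
dense web of first- and second-degree kinship radiating from a handful of
founder varieties — many of which were never genotyped, or no longer exist.
`grapekin` untangles these in stages, each stage consuming the previous
one's output: marker and individual QC, duplicate clustering, pairwise IBD
estimation, Mendelian duo/trio testing, a conditional scan for relatives of
non-genotyped parents, direction inference, and network assembly.

All methods assume diploid, biallelic SNPs; genotypes are stored as B-allele
dosages in $\{0, 1, 2, \mathrm{NA}\}$.

## Identity: mismatch clustering

The duplicate statistic is the percentage of pairwise-complete markers at
which two dosage vectors differ. Its distribution on array panels is
strongly bimodal: clone pairs differ only through genotyping error (well
below 1%), while even parent–offspring pairs differ at a large fraction of
markers (for a PO pair the per-marker mismatch probability is
$\mathbb{E}[2pq]$, about 33% under this panel's allele-frequency spectrum).
Individuals are grouped by single linkage at a strict `< 0.12%` threshold —
at a near-zero threshold the linkage rule is immaterial and the result is
order-independent. Pairs with fewer than 500 comparable markers are flagged
unreliable rather than linked. Each cluster is represented downstream by its
least-missing member; allele frequencies and all kinship statistics are
computed after deduplication so clone copies cannot bias them.

## Relatedness: method-of-moments IBD

For each pair we count markers at IBS 0/1/2 over pairwise-complete,
polymorphic markers and invert the frequency-dependent expectations
$E[\mathrm{IBS}=i \mid \mathrm{IBD}=z]$ (closed forms in
`?expected_ibs`) in cascade to obtain $(\hat k_0, \hat k_1, \hat k_2)$ and
kinship $\varphi = k_1/4 + k_2/2$. Two numerical choices matter:

* **Truncation then renormalization.** Raw moment solutions can leave
  $[0,1]$; reported values are clipped and renormalized so the simplex
  invariant $k_0+k_1+k_2=1$ holds exactly. The raw solutions are kept
  (`k0_raw` …) because they are the unbiased estimates: for pairs whose true
  coefficients lie on the simplex boundary (unrelated pairs, PO pairs),
  clipping biases the *mean* of the reported values toward the interior.
  At 2,000 markers the raw $\hat k_0$ of an unrelated pair has a standard
  deviation near 0.09, so the truncated mean falls around 0.93 rather than
  1.00. This is a property of the estimator itself, not of any
  implementation; calibration should be judged on the raw solutions.
* **No small-sample frequency correction.** Allele frequencies are taken
  from the full deduplicated panel; with hundreds of individuals the
  finite-sample correction terms are negligible (verified in the package's
  own calibration checks, where substituting the generator's true
  frequencies changes the means by under 0.002).

Markers monomorphic at the estimation frequencies are excluded from both
counts and expectations, with the exclusion count recorded.

IBD estimation runs on an LD-pruned marker set (sliding window of 50
markers, step 5, drop-the-later-marker at $r^2 > 0.8$, windows never
spanning chromosomes). $r^2$ is composite LD — the squared Pearson
correlation of dosage columns — appropriate for unphased array data. Window
and step are conventional values; the pruning rule is deterministic.
Mendelian error counting, by contrast, uses the full post-QC marker set:
errors are per-marker logical impossibilities and benefit from every marker.

## Parentage calls and their thresholds

* **PO duos: $k_0 < 0.03$** (`find_po_duos`). On panels of this type the
  $k_0$ distribution is bimodal with an empty gap: in the packaged scenario
  true first-degree pairs sit below 0.005 and all other pairs above 0.19.
  The threshold is a fixed default chosen inside the gap; the full $k_0$
  vector is returned so the gap can be inspected by eye, and no automated
  gap-finder is attempted. Every accepted duo is annotated with its
  opposite-homozygote count as confirmation.
* **Trios: error rate $\le$ 0.2%** (`find_trios`). For each individual with
  two or more PO partners, every partner pair is tested. The threshold is
  expressed as a *rate* rather than an absolute count so it transfers
  across panel sizes; it sits an order of magnitude above the true-trio
  regime (a handful of errors, i.e. $\sim$0.05% at the default error rate)
  and an order below the false-trio regime (a parent swapped for its full
  sib produces a 2–5% error rate; unrelated substitutes far more).
* **Full sibs: $k_2 > 0.3$** (`find_fullsibs`). Deliberately conservative:
  there is no clean $k_2$ gap between full sibs and second-degree pairs, so
  the threshold trades recall for precision. Note that with a few thousand
  quasi-independent markers the realized $\hat k_2$ of a true FS pair
  concentrates near 0.25 (spread roughly 0.02–0.03), so *most true full
  sibs fall below this bar* — calls that pass are individually trustworthy,
  and the package makes no recall promise at this threshold. Lower
  `k2_min` for exploratory work.

## The obligate-allele scan for missing parents

Given an accepted duo and an assumed direction, informative markers are
those where the assumed parent is homozygous and the offspring
heterozygous: the offspring's other allele (the *obligate allele*) came from
the other parent. For each candidate we compare the fraction of informative
markers at which it carries the obligate allele, $f_{obs}$, with the mean
Hardy–Weinberg carrier expectation $f_{exp}$, standardized as
$z = (f_{obs} - f_{exp}) / \sqrt{f_{exp}(1-f_{exp})/n}$.

Both homozygous parent classes are used by default — the argument is
symmetric in the two alleles and using both roughly triples the informative
marker count; a `literal_aa_only` switch restores the single-class variant.
A candidate is accepted when $z \ge 4$ **and** $f_{obs} - f_{exp} \ge 0.15$
**and** $n \ge 100$: the z floor rejects small-$n$ flukes, the absolute
excess floor rejects large-$n$ trivial excesses, and the marker floor
refuses to report on thin evidence. Under the packaged scenario a half sib
through the missing parent shows an excess near
$\tfrac12(1 - \bar f_{exp}) \approx 0.21$ ($z \approx 14$), grandparents
and avuncular relatives the same to first order, while unrelated candidates
stay within sampling noise — the two groups never overlap across the test
seeds. A *full* sib of the offspring (sharing the genotyped parent too) is
a deliberate exclusion from this logic: at informative markers its allele
from the shared parent is never obligate, halving its excess; it is a
first-degree relative and is detected as such by $k_2$, not by the scan.

The grandparent test reuses the informative markers: a candidate pair is
incompatible at a marker when *neither* member carries the obligate allele.
A true grandparent pair of the missing parent is incompatibility-free in
the absence of genotyping error; because no principled acceptance threshold
exists, `grandparent_background()` provides an empirical null from random
candidate pairs (background rates run 10–35% in the packaged scenario,
against 0–0.1% for the true pair).

## Direction inference

Three rules apply in strict priority order (`infer_directions`):

1. **Trio membership** directs both parental edges toward the offspring.
2. **Full-sib evidence**: if A has a full sib C, and C is PO with none of
   A's PO partners, then A is the parent in all its unresolved duos — were A
   the child, its sib would be PO with A's parents, which sit among A's
   partners.
3. **Scan evidence**: the direction whose scan accepted at least 2
   second-degree candidates is adopted. Accepted candidates that are
   themselves detected PO partners of the scanned offspring are *not*
   counted: they are first-degree relatives whose obligate-allele excess
   reflects descent from the offspring itself. Without this filter, a child
   of two non-genotyped parents attracts its own children as spurious
   support for the inverted direction — the one systematic misdirection
   mode we observed, and the reason the filter exists.

Contradictory evidence (both directions qualifying, or rules disagreeing)
leaves the edge undirected with a logged conflict. The design goal is
soundness, not completeness: the inference may abstain, but across the
packaged scenario's seeds it never directs an edge against the true
pedigree.

## The synthetic scenario: what it emulates, and what it does not

`standard_scenario()` generates a panel shaped like a post-QC genotyping
array study of a clonal crop collection: 10,000 simulated markers of which
about 6,600 survive the default QC (matching the scale of an 18K-array
panel after filters), 40 genotyped founders plus four hidden ones, and a
three-generation pedigree containing trios, full sibs, a selfing, four
clone copies, two half-sibships through non-genotyped parents (with their
genotyped grandparent pairs and an avuncular relative), a founder full-sib
pair with non-genotyped parents, and unrelated singletons. Accession names
include one synonym pair and one homonym pair to exercise the
cross-tabulation.

Calibration choices, fixed once from the statistical targets the panel is
meant to emulate:

* **Founder MAF sampler Uniform(0.05, 0.4)**, assigned to a random allele:
  gives mean expected heterozygosity $\mathbb{E}[2pq] \approx 0.33$, the
  typical value for outbred material on such arrays.
* **Per-call error rate $10^{-4}$** (symmetric dosage replacement).
  Back-calculated from two observables: two independently corrupted clone
  copies mismatch at $\approx 2\varepsilon$ of markers, which must stay
  safely below the 0.12% identity threshold at 6,600 markers
  (Poisson mean $\approx 1.3$, exceedance probability $\sim 10^{-4}$); and
  true trios must show at most a handful of Mendelian errors. An error rate
  of $5\times10^{-4}$, sometimes quoted for such arrays, already pushes a
  third of clone pairs over the 0.12% bar at this marker count — the
  identity threshold and the error rate are only jointly consistent in a
  narrow band, which is worth knowing when transferring the thresholds to
  a real panel.
* **Missingness 0.5% per call.** With ~70 genotyped individuals the 1%
  marker-missingness filter then removes any marker with a single missing
  call (~30% of markers), which is how 10,000 simulated markers land at
  ~6,600 — the filter's severity scales with panel size, exactly as it does
  on real data.
* **Unlinked markers.** Gene dropping is per-marker Bernoulli transmission;
  dosage-level transmission yields exactly the joint genotype distribution
  of allele-level Mendelian inheritance at unlinked loci (validated in the
  tests against an allele-tracking oracle). No LD and no linkage are
  simulated, so realized IBD proportions concentrate faster than on a real
  genome, where chromosome-scale linkage inflates the spread of realized
  kinship — real FS pairs show more $\hat k_2$ dispersion (occasionally
  above 0.3) than simulated ones.
* **Single frequency vector.** Founders share one allele-frequency
  spectrum; population structure, which inflates apparent relatedness
  between subpopulation members, is out of scope.

Consequently, passing the packaged checks demonstrates correctness of the
statistical machinery under the stated model — it does not demonstrate
robustness to LD, structure, array batch effects, or somatic mutations
within clonal lineages, none of which are simulated.

A note on selfings: a selfed offspring has expected heterozygosity
$\mathbb{E}[pq] \approx 0.16$, so the parentage heterozygosity filter
(0.25–0.45) removes it before IBD estimation — the same fate an inbred
accession meets on a real panel. The truth oracle labels such pairs `SELF`
and the scoring treats them as PO when they survive filtering.

## Problem sizes and runtimes

The test suite exercises: oracle equivalence on 10×50 panels (enumeration
vs closed forms, agreement to $10^{-12}$); estimator calibration on 50
pairs per relationship class at 2,000 markers; exact zero-error Mendelian
checks and closed-form duo-error expectations on the full scenario; and
the end-to-end recovery, scan-separation, direction-soundness and
grandparent checks on ten scenario seeds (~70 individuals × ~6,600 post-QC
markers each, a few seconds per seed). The complete suite runs in a few
minutes on one CPU; `scripts/acceptance.R` reruns the headline computation
in under ten seconds.

## Known limitations

* Second-degree classes (half-sib vs grandparent vs avuncular) are not
  distinguished from each other — all share expected kinship 1/8 and
  near-identical scan signatures; resolving them needs linked-segment
  methods, out of scope here.
* The full-sib threshold's low recall (above) is inherent to the
  conservative design; likelihood-based sibship reconstruction would trade
  scalability for power.
* Inbreeding violates the three-state IBD model's assumptions; heavily
  inbred material is filtered out rather than modelled (no nine-state
  condensed-identity extension).
* The truncated IBD coefficients are biased near the simplex boundary on
  small marker sets; use the raw solutions for calibration work.
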