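---
title: "Conservative clone calling from single-cell mtDNA heteroplasmy: models and choices"
author: "mtlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservative clone calling from single-cell mtDNA heteroplasmy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlineage)
```

## The problem

Somatic mitochondrial DNA (mtDNA) mutations accumulate in dividing cell
lineages and are recoverable per cell by mitochondria-retaining single-cell
ATAC protocols. Because a cell carries hundreds to thousands of mtDNA copies,
each variant is observed as a *heteroplasmy* — the fraction of the cell's
mitochondrial genomes carrying the alternate allele. Cells sharing a rare
somatic variant are, with high probability, clonal relatives. This gives
innate immune cells (monocytes, macrophages, dendritic cells, NK cells) an
endogenous lineage barcode that recombination-based approaches such as
TCR/BCR sequencing cannot provide.

Two realities make naive clone calling from these data unreliable:

* **Genetic drift.** Mitochondrial genomes partition stochastically at cell
  division, so heteroplasmy fluctuates within a lineage and can drift to
  zero; a cell genuinely belonging to a clone may show low or absent signal.
* **Ambient contamination.** In dissociated solid tissue, cell-free mtDNA
  from lysed cells is co-encapsulated with intact cells, planting low-level
  heteroplasmy of *other* lineages' variants in unrelated cells. Horizontal
  mitochondrial transfer can produce similar artifacts biologically.

The pipeline implemented here deliberately trades detection sensitivity for
assignment fidelity: it is designed so that the clones it reports are right,
at the cost of leaving most cells unassigned.

## The pipeline

The stage order is fixed: cell coverage filter → per-sample variant quality
metrics → donor-union validity → pseudobulk ceiling → blacklist →
binarization → prevalence filter → co-occurrence graph → component merge →
assignment. All stages are deterministic given inputs and parameters.

### Variant selection

Per sample, a variant passes quality control iff its **strand correlation**
exceeds 0.65 and its **variance–mean ratio** (VMR) exceeds 0.01 (strict
inequalities). Strand correlation is the Pearson correlation across cells
between forward- and reverse-strand alternate counts, restricted to cells
with nonzero coverage at the variant; true variants are supported
concordantly on both strands, while sequencing artifacts are typically
strand-biased. VMR is the variance of per-cell heteroplasmy divided by its
mean; clonal variants are overdispersed (a subset of cells at substantial
heteroplasmy), noise is not. Undefined metrics (fewer than two covered
cells, constant strand vectors, zero mean) fail the filter — the
conservative resolution.

Because donors contribute multiple samples (tumor, non-involved tissue,
blood) and per-sample filters are already conservative, validity is taken as
the **union across the donor's samples**: a variant passing anywhere in a
donor is usable everywhere in that donor.

Variants with **pseudobulk frequency above 1%** are excluded: such variants
are almost always early-developmental/zygotic and are carried by cells
across unrelated lineages, while drift makes them unreliable even within
their own lineage. Pseudobulk frequency is computed read-weighted — total
alternate reads over total reads across the donor's cells — which is the
standard pseudobulk construction; a per-cell-mean variant and per-sample
scoping are available as arguments since the aggregation is a genuine
free choice. The boundary is honored as printed: exactly 1% is retained.

The homopolymeric, highly polymorphic region at chrM **307–314** is
blacklisted (configurable as a list of inclusive intervals); variants there
generate spurious linkages. The interval is kept exactly as printed even
though the CCCTCCC motif itself spans seven bases; we do not guess which
endpoint was intended.

### Binarization and prevalence

The heteroplasmy matrix is binarized at a default threshold of **0.07**:
exact heteroplasmy levels are not trustworthy under drift and variable
coverage, so detection is reduced to presence/absence. A value *at* the
threshold counts as detected (values *below* the threshold are "not
detected"), and missing-coverage entries are zero — the result is a
*positive-unlabeled* matrix in which 0 conflates absent with unobserved.

Variants detected in **more than 20%** of the scope's cells (technical or
homoplasmic; the ceiling is `floor(0.20 * n)` with strict exceedance
removed) or in **fewer than 3 cells** are dropped. The denominator scope
defaults to the donor, matching the per-donor implementation of clone
calling; per-sample scoping is available (`prevalence_scope = "sample"`),
in which case exceeding the ceiling in any one sample removes the variant.

### Graph merge and assignment

Subclonal structure is intentionally collapsed: variants that frequently
co-occur in the same cells may mark nested subclones, but establishing true
hierarchy from these data is not robust. An undirected weighted graph is
built with variants as vertices and the Pearson correlation of their binary
call columns (the phi coefficient) as edge weights, edges below **0.5** are
removed (exactly 0.5 is kept), and each connected component becomes one
clone. Zero-variance columns — possible only transiently — yield no edges:
an undefined correlation cannot evidence co-occurrence.

A cell is assigned to a single-variant clone iff positive for the variant,
and to a multi-variant clone iff positive for **all** of its variants. A
cell matching two or more clones is **discarded** (`discarded_multi`): with
donor-scoped clones, multi-clone matches are fingerprints of ambient
contamination or doublets, and dropping them is the core of the
accuracy-over-sensitivity design. Clone identifiers are deterministic —
donor plus the lexicographically smallest member variant — so repeated runs
are byte-identical without any RNG.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_coverage` | 10 | minimum mean mtDNA coverage per cell (×); 100 is conventional for full-length scRNA genotypes |
| `strand_corr_min` | 0.65 | per-sample strand-concordance floor (strict) |
| `vmr_min` | 0.01 | per-sample overdispersion floor (strict) |
| `pseudobulk_max` | 0.01 | donor pseudobulk allele-frequency ceiling |
| `blacklist` | 307–314 | inclusive chrM intervals to mask |
| `threshold` | 0.07 | heteroplasmy detection cutoff |
| `max_prevalence` | 0.20 | per-scope call-prevalence ceiling |
| `min_variant_cells` | 3 | minimum positive cells per variant |
| `edge_min` | 0.5 | co-occurrence edge retention floor |

The defaults reproduce the published operating point out of the box; every
parameter is settable programmatically, per YAML config, and from the CLI.

## Downstream clonal statistics

**Clone sharing** between two disjoint cell groups A and B is the number of
cross-group cell pairs sharing a clone divided by all cross-group pairs
*within the same donor* (cross-donor pairs can never share a donor-scoped
clone and are excluded from the normalization). With per-clone counts
$X_{i1}, X_{i2}$ and per-donor totals $D_{j1}, D_{j2}$:

$$ s(A,B) \;=\; \frac{\sum_i X_{i1} X_{i2}}{\sum_j D_{j1} D_{j2}}. $$

**Cell-type composition association** tests each clone (≥ 5 cells) against
the pooled cell-type proportions with BH adjustment across clones. A
one-clone-versus-background composition comparison has no single canonical
rank-test construction, so the default is a Monte-Carlo exact multinomial
goodness-of-fit (p = probability of a table at most as probable as the
observed one under the background multinomial); a Kruskal-Wallis mode —
ranking the clone-membership indicator across cell types — is available via
`method = "kruskal"` for users who want the rank-test framing.

**Tissue enrichment** tests each clone (≥ 10 cells in tumor + non-involved
tissue) with a two-sided 2×2 Fisher exact test of (clone vs rest) ×
(tumor vs NILT), BH-adjusted; direction is read off the odds ratio.
Two-sided is the conservative default since sidedness is a free choice here.

**Clone-frequency correlations** between cell groups use a common clone
axis (clones ≥ 5 cells; zero counts included) with each clone's frequency
normalized by the group's assigned-cell total, reported both as Pearson's
ρ and Kendall's τ.

**Clone purity** (dominant-type fraction, clones ≥ 3 cells) is compared to
a null obtained by permuting cell-type labels *within samples*, which holds
per-sample composition and clone structure fixed; observed and permuted
purity distributions are compared by Kruskal-Wallis.
`expected_permuted_purity()` provides the closed-form expectation by
multinomial enumeration for small clones (e.g. 0.75 for a 3-cell clone on a
50/50 two-type background), used to validate the Monte-Carlo machinery.

**Cumulative clone-size curves** per cell group sort clone fractions in
decreasing order and accumulate them over normalized clone rank; the
trapezoid AUC (curve anchored at the largest fraction) is 1 when a single
clone holds the group and $(K^2+1)/(2K^2) \to 1/2$ for K even clones. Note
that normalized rank makes curves from different clone counts only
comparable in a majorization sense: merging two clones never decreases the
AUC when the merged curve is evaluated on the same clone axis (padding with
an empty clone), but the unpadded AUC can move either way.

**Lineage-bias clustering** builds clone × (subtype × tissue) proportion
profiles — proportions normalized within each tissue — for clones detected
in both tissue sites or holding ≥ 3 cells, and applies average-linkage
hierarchical clustering on Euclidean distance with the tree cut at k = 2.
No particular algorithm is canonical for this step; average linkage on
Euclidean distance is the simplest reproducible choice, and the linkage, k
and distance are recorded in the output. Clusters are named by the dominant
subtype of their centroid, optionally restricted to differentiated subtypes
so that shared monocyte content does not name every cluster. If all
profiles are identical the function returns a single cluster rather than an
arbitrary split.

## Benchmarking

Against ground-truth clonal labels (physically separated colonies, or
simulation truth), each truth clone is mapped to the **mode** of the called
clones among its assigned cells (ties broken by lexicographically smallest
clone id, recorded). **Accuracy** is the fraction of assigned, truth-labeled
cells matching their truth clone's mapped label; unassigned and discarded
cells are excluded from that denominator and instead drive the **assignment
rate** (assigned over all coverage-passing cells). Reporting the two numbers
separately is what makes the sensitivity–fidelity trade-off visible. The
adjusted Rand index over the same cells is reported alongside as a
mapping-free metric, guarding against degenerate modal mappings.
`threshold_sweep()` re-runs the whole pipeline across binarization cutoffs
(default 0.01–0.15) and reports the rate-maximizing threshold.

## The synthetic-data generator

`simulate_heteroplasmy()` generates donor-scoped clones marked by 1–3
founder variants with founder heteroplasmy drawn uniformly from a
configurable range. Per-cell heteroplasmy then evolves by **Wright-Fisher
drift**: iterated binomial resampling of variant copies among
`effective_mito_copies` genomes per division. This is the simplest
mechanism that reproduces the qualitative behavior of real lineages — the
expectation is preserved while the variance grows as
$h_0(1-h_0)\,(1-(1-1/N)^t)$, so cells drift toward loss or fixation.
Observed counts are drawn at each cell's coverage (negative-binomial across
cells, Poisson per site) and split binomially across strands, so the
strand-correlation and VMR filters see realistic inputs.

Noise layers, each independently switchable:

* **Ambient variants** — dedicated variants hitting a random fraction of all
  cells, across donors, at low heteroplasmy (default U(0.05, 0.25), chosen so
  that a 10% hit rate puts their read-weighted pseudobulk near 1.5%,
  above the 1% ceiling, while many per-cell values still straddle the 0.07
  detection threshold).
* **Cross-clone contamination** — a fraction of cells takes up the founder
  variant sets of two other clones of the same donor at very low
  heteroplasmy, U(0.01, 0.05), emulating the ambient soup of lysed-cell
  mtDNA. This layer is what gives threshold sweeps their characteristic
  shape: at a 0.01 cutoff the contaminants are detected, cells match
  multiple clones and are discarded, so the assignment rate falls below its
  interior maximum; at 0.07 the contaminants are invisible.
* **Zygotic variants** — donor-wide variants at high base heteroplasmy
  subject to the same drift; their pseudobulk frequency far exceeds 1%.
* **Doublets** — cells carrying the unioned founder variant sets of two
  clones at founder heteroplasmy, which the multi-clone discard rule must
  catch.

`simulate_celltype_labels()` adds cell-type and tissue labels with planted
per-clone multinomial biases, enabling power checks for the composition,
enrichment and lineage-bias statistics.

### Packaged fixtures

Fixtures ship as generation configs (`fixture_config()`), not data files.

* **easy** — 3 donors × 10 clones × 20 cells, founders U(0.25, 0.45), no
  drift, no ambient, no zygotic variants, seed 1. Every cell belongs to a
  clone, so informative variants necessarily exceed 1% of a fixture this
  small; the paired pipeline parameters therefore disable the pseudobulk
  ceiling, which has nothing to remove in a noise-free fixture. On this
  fixture the pipeline recovers every clone exactly (ARI 1, accuracy 1,
  assignment rate ≥ 0.99 — losses are pure binomial dropout at low
  coverage).
* **hard** — 3 donors × 8 clones × 25 cells plus 1800 background cells per
  donor, founders U(0.3, 0.5), Wright-Fisher drift with 100 effective
  copies over 20 divisions, 3 ambient variants at 10% hit rate, 2 zygotic
  variants, 15% cross-clone contamination, 10 doublets per donor, seed 1.
  The background cells keep founder pseudobulk below the 1% ceiling
  (≈ 25 × 0.4 / 2000 ≈ 0.5%), which stays at its default. Expected
  behavior, verified by the test suite: no ambient or zygotic variant in
  any clone definition, all doublets discarded, mode-mapped accuracy
  ≥ 0.85 at threshold 0.07, and an interior rate maximum in the threshold
  sweep. The sweep's argmax location is contamination-level- and
  seed-sensitive; only its qualitative shape is a stable property.

These problem sizes (600 and ~6000 cells) were chosen to exercise every
filter with comfortable statistical margins while keeping the whole suite
fast on a laptop.

### What the simulation does not capture

Per-cell coverage is uniform across the mitochondrial genome (no positional
coverage structure), sequencing error is absent (so false positives arise
only from simulated contamination, not miscalls), variants drift
independently (no linkage between founder variants on the same molecule),
and cell-type proportions are stationary. Passing on these fixtures
therefore demonstrates the correctness and conservatism of the machinery
under the modeled noise sources — not performance on any particular real
dataset, where mapping artifacts, index hopping and positional biases add
failure modes the quality filters can only partially absorb.

## Numerical choices and degenerate inputs

* Boundary conventions, fixed throughout: heteroplasmy ≥ threshold is
  positive; quality filters are strict (0.65 / 0.01 fail); prevalence uses
  strict exceedance of `floor(0.20 n)`; pseudobulk exactly 1% is retained;
  graph edges of exactly 0.5 are kept; blacklist endpoints are inclusive.
* Zero-coverage entries are distinguished from observed zeros in the
  heteroplasmy container, but both binarize to 0; the correlation graph
  treats missing-as-zero, which is flagged here because the alternative
  (pairwise-complete correlations) would make edge weights depend on
  coverage patterns in opaque ways.
* Donors with no retained variants yield an empty clone set with a warning,
  never an error; an all-cells-removed coverage filter likewise warns.
* Monte-Carlo p-values use the add-one estimator (1 + #{more extreme}) /
  (B + 1), which cannot return 0.
* All randomness in the simulator and permutation tests flows from a single
  mandatory seed; the clone caller itself uses none.

## Limitations

Subclonal hierarchy is deliberately not reconstructed; clones are flat
variant groups. Indels and multi-allelic sites are out of scope (SNV
catalogs only). The assignment rate is intentionally low — on noisy data
most cells are unassigned, and analyses downstream should treat assigned
cells as a high-precision, non-random subsample: assignment probability
depends on coverage and clone size, which can bias composition statistics
for very small clones. The Fisher-based enrichment tests condition on
margins and ignore donor as a stratum; with few donors, donor effects can
masquerade as tissue enrichment.
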