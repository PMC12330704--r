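# mtlineage

Clonal lineage tracing from single-cell mitochondrial DNA heteroplasmy.

Somatic mtDNA mutations accumulate within cell lineages and can be read out
per cell by mitochondria-retaining single-cell ATAC protocols, giving every
cell an endogenous clonal barcode. This is the only practical lineage mark
for innate immune cells (monocytes, macrophages, dendritic cells, NK cells),
which lack the somatic recombination that makes TCR/BCR-based clone tracking
possible for T and B cells. `mtlineage` is for researchers who have
cell-by-variant heteroplasmy matrices (mgatk-style output) from donors with
one or more samples — e.g. matched tumor, non-involved tissue and blood —
and who want clone assignments they can trust, plus the clone-level
statistics needed to study expansion, tissue enrichment and differentiation
bias.

## The method

Clone calling prioritizes assignment fidelity over sensitivity:

1. **Variant selection.** Per sample, keep variants with strand correlation
   > 0.65 and heteroplasmy variance–mean ratio > 0.01; take the union of
   passing variants across each donor's samples; drop variants with donor
   pseudobulk allele frequency > 1% (zygotic/homoplasmic) and variants in
   the chrM 307–314 homopolymer region.
2. **Binarization.** Call cell–variant pairs positive when heteroplasmy
   ≥ 0.07, producing a positive-unlabeled 0/1 matrix (exact heteroplasmy is
   unreliable under mitochondrial genetic drift and variable coverage).
3. **Prevalence filter.** Remove variants positive in > 20% of a donor's
   cells (artifact/homoplasmic linkage risk) or in < 3 cells.
4. **Clone definition.** Build a graph with variants as vertices, weighted
   by the Pearson correlation (phi) of their binary columns; drop edges
   < 0.5; each connected component is one clone (co-occurring variants —
   potential subclones — are collapsed).
5. **Assignment.** A cell joins a clone iff positive for *all* of the
   clone's variants; cells matching two or more clones are discarded as
   likely contamination or doublets.

Downstream statistics: donor-aware clone sharing between cell groups
(`sum_i X_i1 X_i2 / sum_j D_j1 D_j2` over same-donor cross pairs), per-clone
cell-type composition tests and Fisher tissue-enrichment tests (both
BH-adjusted), Pearson/Kendall clone-frequency correlations between cell
types, clone purity against within-sample permutation nulls, cumulative
clone-size curves with AUC summaries, and clustering of clone-level subtype
compositions into lineage-biased groups. A benchmark module scores calls
against ground-truth labels by modal mapping (accuracy, assignment rate,
ARI, threshold sweeps), and a seeded generator simulates clones with
Wright-Fisher heteroplasmy drift, ambient contamination, zygotic variants
and doublets.

## Worked example

Simulate the packaged noise-free fixture (3 donors × 10 clones × 20 cells,
founder heteroplasmy 0.25–0.45), run the pipeline, and score against truth:

```r
library(mtlineage)

fx  <- fixture_config("easy")
sim <- simulate_heteroplasmy(fx$sim)
res <- mt_pipeline(sim$counts, sim$annotation, fx$params)

res$clones$D1
#> clone_set donor D1: 10 clones; 200 assigned, 0 unassigned, 0 discarded_multi

head(res$clones$D1$clones, 2)
#> $`D1:10547G>A`
#> [1] "10547G>A" "13226T>C" "4783A>G"
#> $`D1:11049C>A`
#> [1] "11049C>A" "12212C>T" "6534C>A"

truth <- truth_labels(sim$truth$cells$cell_id, sim$truth$cells$clone)
acc   <- assignment_accuracy(res$clones, truth)
c(accuracy = acc$accuracy, ari = acc$ari, rate = assignment_rate(res$clones))
#> accuracy      ari     rate
#>    1.000    1.000    0.998
```

Each clone is a connected component of co-occurring variants (here the 2–3
founder variants planted per clone, correctly merged), every assigned cell
matches its true clone (accuracy and adjusted Rand index 1.0), and 99.8% of
cells were assignable — the remainder are binomial dropout at low coverage.
Clone sharing between tissue compartments of the same donors:

```r
at <- assignment_table(res$clones, sim$annotation)
clone_sharing_fraction(at,
                       at$cell_id[at$tissue == "tumor"],
                       at$cell_id[at$tissue == "NILT"])
#> [1] 0.0932876
```

i.e. 9.3% of same-donor tumor–NILT cell pairs share a clone — the expected
level when each donor's cells spread evenly over 10 clones (≈ 1/10).

A command-line wrapper with subcommands (`simulate`, `select-variants`,
`call`, `benchmark`, `share`, `enrich`, `correlate`, `purity`, `auc`,
`bias`) is installed at `system.file("cli", "mtlineage", package =
"mtlineage")`; it reads the same MTX/TSV layout and YAML configs and writes
tidy TSV results plus a JSON run manifest.

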