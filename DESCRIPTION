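Package: mtlineage
Title: Clonal Lineage Tracing from Single-Cell Mitochondrial DNA Heteroplasmy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conservative clone calling from single-cell mitochondrial DNA
    genotypes. Reads cell-by-variant heteroplasmy matrices with strand-resolved
    allele counts, applies variant-level quality filters (strand concordance,
    variance-mean ratio, pseudobulk frequency ceiling, donor-level union
    validity, blacklist regions), binarizes heteroplasmy into a
    positive-unlabeled call matrix, defines clones as connected components of a
    variant co-occurrence graph, and assigns cells to clones while discarding
    ambiguous multi-clone cells. Includes downstream clonal statistics
    (clone sharing across cell groups, cell-type and tissue enrichment tests,
    clone-frequency correlations, purity permutation tests, cumulative
    clone-size curves, lineage-bias clustering), a benchmarking module scoring
    assignments against ground-truth clonal labels, and a synthetic-data
    generator with Wright-Fisher heteroplasmy drift, ambient contamination and
    zygotic variants for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    mclust,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
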