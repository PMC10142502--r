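Package: ithtrace
Title: Linked Lineage Tracing and Single-Cell Analysis of Clonal Selection
    and Intra-Tumoral Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing tumor cell populations profiled with expressed
    DNA lineage tags alongside droplet single-cell RNA-seq. Implements the
    barcode-processing chain (flank-anchored tag extraction, cell-barcode
    filtering, UMI deduplication, Hamming-distance library matching, and
    per-cell clone assignment), a transcriptional workflow (QC filtering,
    log-normalization, gene-module and cell-cycle scoring, covariate
    regression, highly variable gene selection, PCA, shared-nearest-neighbor
    graph construction, and modularity clustering with silhouette-based
    selection of the cluster number), per-cell intra-tumoral heterogeneity
    scores with a kernel-density distribution-overlap statistic, clone-level
    analytics (clone-size distributions, unique-clone fractions, expanded
    clones, cluster-by-condition tables, clone-by-cluster contingency), a
    self-contained negative-binomial Wald test for differential expression,
    and hypergeometric gene-set enrichment. A ground-truthed synthetic-data
    generator emulates clone-structured negative-binomial counts under
    culture, permissive-colonization, and bottlenecked-colonization
    conditions, together with error-injected lineage-tag reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    cluster,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
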