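---
title: "Methods: linked lineage tracing and single-cell heterogeneity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linked lineage tracing and single-cell heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ithtrace)
```

# Scope and model

`ithtrace` analyzes experiments that couple an expressed DNA lineage tag
to droplet single-cell RNA-seq. Each founding cell receives one tag from a
high-diversity library; the tag is transcribed, captured by the 3'
chemistry, and inherited by all progeny, so a "clone" is the set of cells
sharing a tag. The analysis asks two linked questions: how strongly does a
colonization bottleneck skew the clone-size distribution (clonal
selection), and how much per-cell transcriptional heterogeneity survives
that selection (phenotypic diversity).

The package assumes UMI count data, tags of fixed length between known
constant flanks, substitution-dominated sequencing error (no indels in the
tag cassette), and at most one tag per cell (multiplicity of infection
effects are out of scope). Cell identifiers from the tag library run and
the expression run must share the barcode namespace; droplet suffixes
("-1") are stripped on ingest so the two streams join.

# Tag processing

`extract_tags()` matches both flanks at their expected offsets, allowing
`max_flank_mismatch` (default 2) substitutions each; the intervening
`tag_length` bases (default 38) are the raw tag. Extraction is positional
rather than alignment-based because the cassette has fixed geometry and
the error model excludes indels; reads failing either flank are counted
per reason rather than silently dropped.

"High-confidence" cell identification is operationalized as an exact
whitelist match by default (`max_cid_hamming = 0`); a distance-1
correction to a unique whitelist neighbor is available but off by default
because the chemistry's own barcode calling already corrects sequencer
errors, and a conservative reading loses few reads at 1% error.
"Redundant reads" are collapsed per distinct (cell, UMI, tag) triple,
keeping read multiplicity as a weight; collapsing on (cell, tag) instead
would erase the UMI support needed for the purity rule below.

Library matching accepts exact hits and corrects a non-matching tag iff
exactly one library tag lies within `max_tag_hamming` (default 1);
ambiguous or distant tags are eliminated. Correction is implemented by
exhaustive Hamming-1 neighborhood hashing, which is exact and fast for
radius 1; radius ≥ 2 is rejected rather than approximated. On random
38-mers the library's minimum pairwise distance is far above 2, so a
unique distance-1 neighbor is essentially always the true tag
(`make_barcode_library()` reports the exact minimum pairwise distance so
this assumption is auditable).

The per-cell clone call is a plurality rule: the tag with most supporting
UMIs wins iff it has at least `min_umis = 2` UMIs and purity (supporting /
total UMIs) at least `min_purity = 0.6`; plurality ties are unassigned.
The thresholds absorb chimeric reads (a few percent of reads carry a
wrong tag after template switching) without discarding cells; a
`strict-single` policy is available for analyses that must exclude any
cell with conflicting tags.

# Transcriptional workflow

QC removes cells with fewer than 800 detected genes, then cells whose
total counts, detected genes, or mitochondrial fraction exceed
median + k·MAD (k = 3, a robust, parameter-light stand-in for doublet and
damaged-cell removal), then genes seen in fewer than 5 cells. The pass
sequence (cell filters before gene filters, so gene prevalence is
computed on retained cells) is iterated to a fixed point: gene removal can
push a cell's detected-gene count below threshold, and the MAD thresholds
move as outliers leave, so a single pass is not idempotent while the
fixed point is — which makes the filter safe to re-apply and its output
stable under re-analysis.

Normalization is global scaling to 10^4 counts per cell with a log1p
transform. Module scores subtract the mean of expression-matched control
genes (24 equal-frequency bins, 100 seeded control draws per set gene,
with replacement when a bin is small so tiny matrices cannot fail); the
gene set is canonically sorted before sampling so the score is invariant
to input order. Cell-cycle phase is G1 when both the S and G2M scores are
negative (or exactly tied), otherwise the larger score's phase. Cell-cycle
structure is regressed out per gene by OLS on the two scores before
per-gene scaling (clipped at ±10); constant or fully-explained genes map
to zero rows rather than amplified noise.

Highly variable genes are ranked by the variance of standardized counts
under a loess mean–variance trend (span 0.3, log10 scales, standardized
values clipped at √n_cells); ties break by gene identifier so the ranking
is deterministic. PCA is exact, with a fixed sign convention (the
largest-magnitude loading of each component is positive) and variance
fractions reported against the total variance of the input matrix. The
number of components is fixed at 20 rather than chosen per sample by an
elbow heuristic — an automatic elbow is unstable across samples while a
fixed depth keeps ITH scores comparable; the variance-explained report
makes the choice auditable.

Clustering runs Louvain modularity optimization on a shared-nearest-
neighbor graph (k = 20 neighbors, Jaccard edge weights, pruned below
1/15) across a resolution grid (0.1–2.0, step 0.1) under a fixed seed.
For each distinct cluster number k between 2 and 10 the best-modularity
partition is kept; the winner maximizes the mean silhouette width in the
same PC space used to build the graph, with ties to the smaller k and
lower resolution. Silhouette uses the clustering space deliberately: the
question it answers is how well-separated cells are in the representation
the clusters were formed in. Distance ties in neighbor selection break by
cell index, making the graph deterministic even with duplicate points.

Samples are combined by naive column concatenation over the gene union
(zero-filled), with cell identifiers prefixed by the sample label. No
batch-correction integration is applied: for replicate-consistent data
the merged representation is sufficient, and correction methods change
the geometry the ITH score is computed in.

# Heterogeneity statistics

The ITH score of a cell is its mean Euclidean distance to every other
cell of the same sample in the selected PCs, excluding the self distance
(including it deflates all scores by exactly (n−1)/n; a flag toggles the
convention). Samples are subsampled to equal size before scoring because
the score's scale depends on n through the density of the embedded cloud.

The distribution-overlap statistic is the overlapping index: Gaussian
KDEs with Silverman's rule-of-thumb bandwidth for each sample, evaluated
on a common 1024-point grid spanning the pooled range padded by three
bandwidths, then 100 · the trapezoidal integral of the pointwise minimum.
Raw scores are used (a per-sample standardization flag is not applied by
default, since standardizing erases exactly the scale differences the
comparison is about). Point-mass samples fall back to normalized
histograms on shared bins. Identical samples score 100 within numerical
tolerance; unit normals with mean gap 2 score 2Φ(−1) ≈ 31.7%, which the
test suite checks against the closed form.

Condition comparisons use one-way ANOVA on the per-cell scores followed
by all pairwise t tests with the pooled within-group variance and Šidák
adjustment p′ = 1 − (1 − p)^m. With thousands of cells per group the p
values are nearly always tiny; the overlap statistic is the quantity that
actually discriminates "different" from "shifted but largely coincident"
distributions, and both are reported.

# Differential expression and enrichment

The two-group test is a self-contained negative-binomial Wald test:
library-size size factors normalized to median 1; per-gene dispersion by
method of moments on pooled normalized counts (Var = μ + αμ², α floored
at 10⁻⁸); delta-method standard error on the log ratio of group means;
two-sided normal p values; BH adjustment over tested genes. Genes with
zero counts in both groups are skipped. A group with zero mean enters the
ratio and the variance at a pseudo-mean of half a normalized count over
the group (max(ε, 0.5/n)): this keeps the fold change finite and the
statistic consistent with its standard error, so a gene expressed at
depth in one group and absent in the other is significant, while a
1-count-vs-0-count gene is not — the type-I calibration of the test under
a pure NB null is verified by simulation in the test suite. Full
shrinkage machinery (empirical-Bayes dispersion moderation) is
deliberately out of scope; the acceptance surface is calibrated error
rates, not coefficient parity with any particular framework.

Cluster markers are positive-only (log2FC ≥ 0.25, BH-adjusted p < 0.05 by
default; both cutoffs surfaced as arguments since conventions differ).
Pseudo-bulk contrasts relabel cells by sample and test condition against
condition, returning both directions. Gene-set over-representation is the
upper-tail hypergeometric probability with the universe defaulting to the
genes expressed in the analyzed (post-QC) matrix — the standard choice
that conditions on detectability — with set sizes bounded to [10, 500]
after universe intersection.

# The synthetic-data generator

The generator is first-class, tested code; it defines the study
conditions the pipeline is validated under.

**Clonal structure.** Every founding clone is seeded with one cell and
the remaining cells are assigned uniformly at random, so the expected
singleton (unique-clone) fraction is controlled by n_clones / n_cells and
can reach any value up to 100%. Defaults (2000 cells, 1850 clones) give
≈85% unique clones — a high-diversity tagged culture. Each clone draws
i.i.d. standard-normal weights over M = 4 latent expression programs plus
a boost (default 2) on its largest-weight program; the boost makes
discrete program-dominant subsets exist alongside continuous variation,
which is what gives cluster recovery a defined ground truth. Cells
inherit their clone's vector plus N(0, σ²) jitter (σ = 0.1), so phenotype
is heritable and σ = 0 makes clonemates identical.

**Bottleneck.** A clone survives with probability min(1, p_s · s^α),
s ~ Uniform(0,1) a latent fitness; survivors expand by a shifted
geometric factor (support ≥ 1). The colonized sample of n_cells cells is
drawn by deterministic largest-remainder apportionment proportional to
expanded clone mass, so clone sizes sum exactly to n_cells and the
identity bottleneck (p_s = 1, α = 0, expansion 1) reproduces the input
sizes exactly. A per-program condition-effect vector shifts all cells,
modeling the condition-wide transcriptional response. The default
conditions were fixed once, by simulating the truth-level unique-clone
fraction over parameter grids, to emulate the diversity profile the assay
is designed around: permissive "tibia" (p_s = 1, α = 0, expansion 1.4,
≈78% unique) and bottlenecked "lung" (p_s = 1, α = 0.4, expansion 3,
≈34% unique) against the ≈85% culture baseline. Fitness is drawn
independently of the transcriptional programs, so expanded clones have no
systematic expression signature under the defaults — analyses of
expanded-clone signatures are validated against explicitly planted
program-dominant clone sets instead.

**Counts.** count ~ NB(μ, θ) with
μ = l_c · exp(b_g + Σ_m w_cm β_mg + phase effects), Var = μ + μ²/θ,
θ = 2 (strong over-dispersion typical of UMI data at per-gene depth).
Gene baselines are log-normal (meanlog 0.7, sdlog 1.2 over 2500 genes,
giving ~6000 counts and ~1400 detected genes per typical cell — enough
that the 800-detected-genes QC default is meaningful rather than
vacuous); library-size factors are log-normal (sdlog 0.25). Four disjoint
60-gene program blocks carry effect 1 per weight unit. Two 40-gene
cell-cycle blocks (S-like, G2M-like) respond to a latent phase label
(G1/S/G2M at 60/20/20%) with effect 1.2 — strong enough that cell-cycle
structure is a dominant variance component, as in proliferative tumor
data, and therefore worth regressing out. 25 `MT-` genes are pinned to a
5% healthy-cell count share and inflated 4× in a 5% "damaged" subset;
3% of cells are doublets formed by summing two cells' counts.

**Tag reads.** Poisson(λ = 20) reads per cell; read 2 is the flanked tag
with i.i.d. per-base substitutions at ε = 0.01 over the whole read;
UMIs are uniform random; 2% of reads are chimeric (random wrong library
tag), exercising the purity rule without dominating the signal.

**What the generator does not emulate.** Ambient RNA and empty droplets,
PCR duplication beyond UMI multiplicity, indel errors, batch effects
between replicates, multi-tag cells, and gene–gene correlation beyond the
program/cell-cycle block structure. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
robustness to every artifact of real droplet data; on real data the QC
thresholds and the assignment purity rule are the components that absorb
the unmodeled noise and may need retuning.

# Numerical choices and problem sizes

All stochastic stages take explicit seeds; identical inputs and seeds
give byte-identical outputs. Ties are resolved deterministically
throughout (neighbor selection by cell index, HVG ranks by gene
identifier, expanded-clone ranks by tag identifier, cluster-number ties
by smaller k then lower resolution). Distance computations use full
distance matrices — exact and comfortably within memory at the package's
design scale of 10³–10⁴ cells.

The test suite validates operations against independent oracles
(brute-force pairwise scans, closed-form binomial and hypergeometric
probabilities, exhaustive enumeration, textbook ANOVA, eigendecomposition,
replicate simulation) at desk scale: populations of a few hundred to 2000
cells, 200–2500 genes, 20 seeds for parameter-recovery checks. These
sizes were chosen so each property is measured with useful precision
while the whole suite runs in minutes; the acceptance script uses the
full default conditions (3 × 2000 cells × 2500 genes).

# Known limitations

The NB test uses a common MoM dispersion per gene without shrinkage, so
it is conservative for genes whose dispersion is inflated by real
between-group differences. Louvain partitions can depend on vertex order
for marginal structure; the silhouette criterion selects among partitions
but does not remove that sensitivity. The overlap statistic inherits KDE
boundary bias for sharply bounded score distributions. Hamming-radius-1
correction is exact but cannot rescue tags with two or more errors
(~5% of reads at ε = 0.01, length 38), which are dropped — a loss the
UMI-level plurality rule makes irrelevant for cells with typical read
depth.
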