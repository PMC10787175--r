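---
title: "Models and methods: spatial APA usage, KNN imputation and pattern detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: spatial APA usage, KNN imputation and pattern detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialAPA)
```

## The problem

Spatially barcoded spatial-transcriptomics (ST) arrays capture a small
transcriptome aggregate at each spot. Because most protocols enrich 3'
ends, the reads also locate cleavage/polyadenylation sites, so the same
experiment yields a poly(A)-site x spot count matrix alongside the usual
gene x spot matrix. Alternative polyadenylation (APA) — the modulated
choice among a gene's poly(A) sites — can then be quantified per spot and
examined in its spatial context. The catch is sparsity: APA usage is
measured per isoform, so the usage matrix is even sparser than the
already sparse expression matrix, and a (gene, spot) cell where no site
of the gene was captured is a *dropout*, not a zero.

## Usage indices

For a gene with at least two poly(A) sites in its (extended) 3' UTR, the
per-spot usage is the **relative usage of the distal site (RUD)**:

$$\mathrm{RUD}_{gs} = \frac{c_{\text{distal},s}}{\sum_{i \in \text{3'UTR}(g)} c_{is}}$$

where the distal site is the strand-aware farthest 3' UTR site from the
start codon. RUD = 1 means exclusive use of the longest 3' UTR. A zero
denominator makes the cell missing (`NA`), which the serialization keeps
distinct from a legal usage of 0.

For intronic APA, sites are first filtered (total support >= 3 reads,
present in >= 3 spots, both defaults); genes keeping multiple sites and
at least one intronic site get, per spot, the **highest intronic-site
ratio**: the intronic site's count over the summed counts of all the
gene's surviving sites. The denominator runs over surviving sites only —
the source method leaves this unstated, and using filtered-out sites in
the denominator would make the index depend on sites deemed unreliable.

Site-to-region assignment flattens multi-transcript genes into a union
model (RUD is defined per gene, not per transcript). Annotated 3' UTRs
are extended 1000 bp downstream to recruit intergenic sites that likely
belong to unannotated UTR ends; an annotated region in any gene beats
another gene's extension window, and remaining ties are resolved by
region priority (3UTR > extended3UTR > intron > CDS > exon), then by the
smallest containing gene.

## The KNN imputation model

Neighbourhoods come from the *expression* profile, not from the usage
matrix itself: the gene x spot matrix is scaled gene-wise (centred, unit
sample standard deviation; zero-variance genes become zero rows), the
Euclidean spot-spot distance matrix \(D\) is computed over all genes,
and each spot's neighbours are ranked by ascending distance (ties broken
by spot index). Borrowing structure from expression avoids circularity
and overfitting to the sparse usage signal.

A missing cell \((i, j)\) is filled by the mean usage of gene \(i\)
among spot \(j\)'s \(k\) nearest neighbours, **counting only donors with
non-zero, non-missing usage**. The step iterates synchronously — every
round reads the previous round's matrix, so the result does not depend
on cell visiting order — until nothing more can be filled or `max_iter`
(default 10) is reached; residual missing cells are set to 0 by default.
Observed cells are never modified. Key consequences, all under test:
imputed values stay inside the gene's observed non-zero range; the
missing set shrinks weakly each round; with \(k = m - 1\) and one
iteration every filled cell equals the gene's global non-zero mean.

Two conventions had to be fixed where the source description is loose:
the ranking is stored nearest-first (ascending distance — the text says
"descending" but then fetches the *nearest* spots), and scaling uses the
sample (n-1) standard deviation, matching R's `scale()`.

## Choosing k: the comprehensive index

For each candidate \(k\) the matrix is imputed, spots are clustered
(PCA, shared-nearest-neighbour graph, Louvain at a fixed resolution and
seed), and eight clustering-validation metrics are computed: ARI,
pairwise Jaccard, NMI (arithmetic-mean normalization) and purity against
reference layer labels, plus DBI, Calinski-Harabasz, mean silhouette and
Dunn from the data alone. Each metric is Z-scored across the grid (DBI
negated — summing a raw DBI Z-score would reward worse clusterings), and
the **comprehensive index** is the sum; the optimal \(k\) maximizes it,
with near-ties (1e-9) going to the smaller \(k\), since smaller
neighbourhoods avoid borrowing from other layers. Without reference
labels the index degrades to the four internal metrics. Clustering
hyper-parameters are held fixed across the grid.

All eight metrics and Moran's I are implemented from their definitions
and verified against independent brute-force oracles (exhaustive pair
enumeration, direct-formula transcriptions, O(n^2) double loops) in the
test suite.

## Detecting spatial APA dynamics

* **DEAPA** — per gene, a two-sided Wilcoxon rank-sum test between two
  layers; effect size `log2((mean_A + 0.01)/(mean_B + 0.01))` (usage
  means can be 0; the pseudocount is configurable). Reported when
  adjusted p < 0.05 and |log2FC| > 0.5 — two-sided, because both
  lengthening and shortening matter.
* **LSAPA** — the same contrast of each layer against the union of the
  others.
* **SVAPA** — a built-in detector tests each gene's usage for positive
  spatial autocorrelation with a Moran's I permutation test
  (binary k-nearest-neighbour weights, default k = 6 for the roughly
  hexagonal array; p = (b+1)/(n_perm+1); BH across genes). External
  count-based detectors such as SPARK are supported instead via
  `usage_to_counts()` — a monotone map of \([0,1]\) onto integer counts
  1..10, `round(10^u)` for RUD and `round(2^{c u})`, `c = log2(10)`, for
  intronic ratios — and `import_svapa()`, which ingests a gene/p-value
  table and BH-adjusts raw p-values on import. The exact base-10
  "transformation to counts" of the original description is ambiguous
  about exponentiation and rounding; the choice here is explicit and
  configurable, not a claim about the original code.

Multiple testing defaults to Bonferroni for DEAPA/LSAPA (the convention
of the wrapped marker-finding workflow) with BH one flag away; SVAPA
uses BH. The three gene sets are combined without redundancy
(`combine_gene_sets()`, upset-style membership flags).

For the robustness benchmarks the rank-sum tests, clustering and
Moran's I also accept a *raw* (still missing) matrix: NA cells are
dropped per gene in the tests and treated as 0 elsewhere. This
deliberately relaxes the "fully imputed" contract of the main path —
the before/after-imputation comparisons are meaningless without it.

## Patterns

The combined gene set is clustered by k-means on the gene usage
profiles (default 10 groups, 1000 restarts, fixed seed; profiles are
left unstandardized since usage already lies in \([0,1]\)). A group's
centroid is the per-spot mean usage of its members; representative genes
correlate with their centroid at r > 0.5 and p < 0.05 (correlation
t-test). Singletons trivially give r = 1 and are flagged so users can
discount them. "Most distinguished" patterns are undefined in the source
method; here groups are ranked by an explicit layer-contrast score —
variance of the centroid's layer means over its mean within-layer
variance — and the top five are flagged, with manual selection always
possible.

## The simulator: a stated world

`simulate_dataset()` emulates exactly the structure the method assumes,
no more: spots on an integer grid split into layers (stripes or
concentric rings) with fixed proportions; gene totals negative-binomial
(depth 20 reads/gene/spot, dispersion 0.3 — typical shallow-ST
magnitudes); layer-marker genes (5 per layer, 4-fold change) give the
expression profile its layer structure; each APA gene carries two 3' UTR
sites whose counts split the gene total binomially with distal
probability equal to the layer's true RUD (0.2 vs 0.6 for pattern
genes — the planted effect of 0.4 matching the effect range of the
robustness experiments — and flat 0.5 for the rest). Conditioning the
binomial split on the NB total keeps expression and APA statistically
separable, mirroring the premise that APA patterns are an independent
layer of information. Dropout is controllable at whole-spot and
per-cell level; the acceptance simulations add 30% cell dropout because
a sparse usage matrix is the method's premise. All randomness flows from
one seed through fixed per-stage child seeds.

What the simulator does **not** model: histology-shaped layers, UMI
duplication, sequencing error, gene-length or GC effects, more than one
gene per locus, or dependence between APA usage and expression level. A
green recovery test therefore establishes that the pipeline recovers the
statistical structure it assumes — not that real tissue meets those
assumptions.

The masking utilities reproduce the three robustness designs:
`mask_spots()` (whole spots, stratified by layer), `mask_entries()`
(random observed cells) and `subsample_spots()` (stratified
subsampling), plus `sensitivity()` and `silver_standard()` (genes
recurring in >= 2 replicates) for evaluation against planted or
consensus references.

## Numerical choices and degenerate inputs

* Distance and ranking ties break by ascending spot index; k-means
  restarts and Louvain are fixed-seed; everything is bit-reproducible.
* Zero-variance genes: skipped (with a warning) by the SV detector,
  zero rows after scaling, excluded from rank-sum tables.
* A clustering that collapses to one community yields an undefined
  internal panel; `select_k()` records an NA panel for that k and the
  affected metrics drop out of the Z-scoring.
* `stats::kmeans` cannot take as many centres as points; the
  one-gene-per-group case returns the exact zero-inertia partition
  directly.
* Permutation p-values are never 0 by construction; Moran's I on
  constant values is an error rather than NaN.

## Known limitations

Imputation borrows only across spots, never across genes, and cannot
rescue a gene observed in no spot. The Moran's-I SV detector tests
global positive autocorrelation only — ring-shaped or anisotropic
patterns with weak first-order autocorrelation need an external
detector. Bonferroni on hundreds of genes is conservative; use BH when
power matters. The intronic-ratio denominator choice (surviving sites
only) slightly inflates ratios for genes whose weak sites were filtered.
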