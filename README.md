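# spatialAPA

Mining spatial patterns of alternative polyadenylation (APA) usage from
spatially barcoded spatial-transcriptomics (ST) data.

3'-enriched ST protocols measure, at every spot, not just gene
expression but also the usage of each gene's poly(A) sites. From a
poly(A)-site × spot count matrix this package:

1. **quantifies APA usage** per gene and spot — the relative usage of
   the distal poly(A) site for 3' UTR APA,

   RUD<sub>gs</sub> = c<sub>distal,s</sub> / Σ<sub>i∈3'UTR(g)</sub> c<sub>is</sub> ∈ [0, 1],

   or the highest intronic-site ratio for intronic APA — keeping
   dropouts (zero denominators) explicitly missing, never 0;
2. **imputes** the sparse usage matrix with an iterative KNN model:
   spot neighbourhoods come from the Euclidean distances between scaled
   gene-*expression* profiles, and each missing cell becomes the mean of
   its k nearest neighbours' non-zero usages, iterated until no more
   cells can fill;
3. **selects k** by a comprehensive index — the sum of across-k
   Z-scores of eight clustering-validation metrics (ARI, Jaccard, NMI,
   purity; DBI, CH, silhouette, Dunn), all implemented in-package and
   oracle-verified;
4. **detects spatial APA dynamics**: DEAPA (Wilcoxon rank-sum between
   two layers, adjusted p < 0.05 and |log2FC| > 0.5), LSAPA (one layer
   vs the rest), and SVAPA (built-in Moran's-I permutation detector, or
   imported results from external tools such as SPARK via a unified
   interface);
5. **summarizes patterns**: k-means over the combined gene set, per-spot
   centroids, representative genes (r > 0.5, p < 0.05 against the
   centroid), and a layer-contrast ranking of the major patterns.

A simulator with planted layer structure, planted per-layer RUD values
and controllable dropout (`simulate_dataset()`, `mask_spots()`,
`mask_entries()`, `subsample_spots()`) makes the whole pipeline testable
without any external download. Gene annotation (GFF3/GTF) is supported
for site-to-region assignment, including the 1-kb 3' UTR extension that
recruits intergenic sites.

## Worked example

```r
library(spatialAPA)

spec <- SimulationSpec(n_spots = 200, n_genes = 60, n_apa_genes = 30,
                       depth = 20, dropout_cell_frac = 0.3, seed = 202)
ds <- simulate_dataset(spec)
u  <- compute_rud(ds$pa)
u
#> UsageMatrix (RUD): 30 genes x 200 spots, 30.2% missing

imp <- impute(u, build_ranking(scale_genes(ds$g)), ImputationConfig(k = 10))
imp
#> UsageMatrix (RUD): 30 genes x 200 spots, 0.0% missing

cl <- cluster_spots(imp, seed = 1)
unlist(external_metrics(cl, ds$layout$layer))
#>       ari   jaccard       nmi    purity
#> 0.9598077 0.9411998 0.9468434 0.9850000
```

After imputation the spot clustering recovers the four planted layers
almost perfectly (ARI 0.96). Downstream, layer-specific and spatially
variable genes and their patterns:

```r
res <- detect_lsapa(imp, ds$layout$layer, p_adjust = "BH")
head(res[, c("gene_id", "contrast", "p_adj", "log2fc")], 3)
#>     gene_id   contrast        p_adj   log2fc
#> 9    apa009 L1 vs rest 2.056004e-23 1.405556
#> 1    apa001 L1 vs rest 4.614830e-23 1.382408
#> 152  apa015 L3 vs rest 4.698479e-23 1.506488

sv <- detect_svapa_builtin(imp, ds$layout, n_perm = 199, seed = 1)
combined <- combine_gene_sets(lsapa = res, svapa = sv)
nrow(combined)
#> [1] 16

ps <- cluster_patterns(imp, combined$gene_id, n_groups = 4, seed = 1,
                       nstart = 50)
ps <- rank_patterns(select_representatives(ps, imp), ds$layout$layer, q = 2)
ps
#> PatternSet: 16 genes in 4 groups, 2 selected, 16 representative genes
#> group
#> 1 2 3 4
#> 4 4 4 4
```

The 16 genes in the combined set are exactly the planted pattern genes
that survived detection; each of the four pattern groups collects the
genes whose high-RUD layer coincides (one planted pattern per layer),
and the layer-contrast ranking flags the two most layer-distinct
centroids. `p_adj` is the BH-adjusted rank-sum p-value, `log2fc` the
log2 ratio of mean usage (pseudocount 0.01) — positive values mean
longer 3' UTRs in the named layer.

A command-line interface mirrors the pipeline
(`simulate | annotate | usage | impute | select-k | deapa | lsapa |
svapa | patterns | benchmark`):

```sh
Rscript -e 'quit(status = spatialAPA::apa_cli())' -- simulate --out demo --seed 7
Rscript -e 'quit(status = spatialAPA::apa_cli())' -- usage \
  --matrix demo/counts.mtx --sites demo/sites.tsv --spots demo/spots.tsv \
  --out demo/usage.tsv
```

## Vignette

`vignettes/spatial-apa-methods.Rmd` documents the models, parameter
defaults and their rationale, what the simulator does and does not
emulate, numerical tie-breaks, and known limitations.
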