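## KNN-based iterative imputation of the sparse APA usage matrix.
## Spot neighbourhoods come from the (scaled) gene-expression profile, not
## from the usage matrix itself, so imputation borrows information across
## the expression-defined tissue structure.

#' Centre and standardize a gene-spot matrix gene-wise
#'
#' Each gene row is centred to mean 0 and divided by its sample (n-1)
#' standard deviation; zero-variance rows become all-zero rows.
#'
#' @param g an unscaled [GeneSpotMatrix()].
#' @return The scaled matrix with `scaled = TRUE`.
#' @export
scale_genes <- function(g) {
  stopifnot(inherits(g, "GeneSpotMatrix"))
  if (g$scaled) stop_config("matrix is already scaled")
  v <- g$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  out <- (v - mu) / ifelse(sdv > 0, sdv, 1)
  out[sdv == 0, ] <- 0
  GeneSpotMatrix(out, scaled = TRUE)
}

#' Spot-spot distances and per-spot neighbour ranking
#'
#' Computes the Euclidean distance between every pair of spots over all
#' (scaled) gene values, and from it the ranking matrix whose i-th row
#' lists all other spot indices in ascending distance from spot i (nearest
#' first, self excluded, ties broken by ascending spot index).
#'
#' @param g_scaled a scaled [GeneSpotMatrix()].
#' @return An object of class `NeighborRanking`: list with `spot_ids`,
#'   `distance` (m x m symmetric) and `ranking` (m x (m-1) integer matrix).
#' @export
build_ranking <- function(g_scaled) {
  stopifnot(inherits(g_scaled, "GeneSpotMatrix"))
  if (!g_scaled$scaled) stop_config("build_ranking expects a scaled matrix")
  m <- ncol(g_scaled$values)
  if (m < 2) stop_data("need at least 2 spots")
  D <- as.matrix(stats::dist(t(g_scaled$values)))
  dimnames(D) <- list(colnames(g_scaled$values), colnames(g_scaled$values))
  ranking <- matrix(0L, m, m - 1)
  for (i in seq_len(m)) {
    ord <- order(D[i, ], seq_len(m))  # ties -> ascending spot index
    ranking[i, ] <- ord[ord != i]
  }
  rownames(ranking) <- colnames(g_scaled$values)
  structure(list(spot_ids = colnames(g_scaled$values),
                 distance = D, ranking = ranking),
            class = "NeighborRanking")
}

#' Imputation configuration
#'
#' @param k neighbour count (default 10); must satisfy 1 <= k < spots.
#' @param max_iter iteration cap (default 10).
#' @param fill_residual_zero set cells still missing after the iterations
#'   to 0 (default `TRUE`).
#' @return An object of class `ImputationConfig`.
#' @export
ImputationConfig <- function(k = 10, max_iter = 10, fill_residual_zero = TRUE) {
  if (k < 1) stop_config("k must be >= 1")
  if (max_iter < 1) stop_config("max_iter must be >= 1")
  structure(list(k = as.integer(k), max_iter = as.integer(max_iter),
                 fill_residual_zero = isTRUE(fill_residual_zero)),
            class = "ImputationConfig")
}

#' Impute missing APA usage from k nearest expression neighbours
#'
#' For each missing cell (gene i, spot j), the k spots nearest to j in the
#' expression-derived ranking are examined; neighbours whose usage of gene
#' i is non-zero and non-missing form the donor set, and the cell becomes
#' the donor mean. The step iterates synchronously (each round reads the
#' previous round's matrix) until no missing cells remain, no additional
#' cell can be filled, or `max_iter` is hit; residual missing cells are
#' then set to 0 when `cfg$fill_residual_zero`. Observed cells are never
#' modified.
#'
#' @param r a [UsageMatrix()].
#' @param ranking a `NeighborRanking` sharing `r`'s spot ids (same order).
#' @param cfg an [ImputationConfig()].
#' @param verbose print per-iteration filled-cell counts.
#' @return The imputed `UsageMatrix`.
#' @export
impute <- function(r, ranking, cfg = ImputationConfig(), verbose = FALSE) {
  stopifnot(inherits(r, "UsageMatrix"), inherits(ranking, "NeighborRanking"))
  m <- ncol(r$values)
  if (!identical(colnames(r$values), ranking$spot_ids))
    stop_data("usage matrix and ranking disagree on spot ids")
  if (cfg$k >= m) stop_config("k = %d must be smaller than the number of spots (%d)",
                              cfg$k, m)
  vals <- r$values
  nn <- ranking$ranking[, seq_len(cfg$k), drop = FALSE]
  for (it in seq_len(cfg$max_iter)) {
    miss <- which(is.na(vals), arr.ind = TRUE)
    if (nrow(miss) == 0) break
    prev <- vals
    filled <- 0L
    for (idx in seq_len(nrow(miss))) {
      i <- miss[idx, 1]; j <- miss[idx, 2]
      donors <- prev[i, nn[j, ]]
      donors <- donors[!is.na(donors) & donors != 0]
      if (length(donors) > 0) {
        vals[i, j] <- mean(donors)
        filled <- filled + 1L
      }
    }
    if (verbose)
      message(sprintf("iteration %d: filled %d of %d missing cells",
                      it, filled, nrow(miss)))
    if (filled == 0L) break
  }
  if (cfg$fill_residual_zero) vals[is.na(vals)] <- 0
  UsageMatrix(vals, usage_type = r$usage_type)
}

#' Benchmark a usage matrix before vs after imputation
#'
#' Computes the eight-metric clustering panel (after graph clustering of
#' spots) for both matrices against the layout's reference layer labels,
#' plus the per-layer median pairwise spot Pearson correlation. Missing
#' cells of the raw matrix are treated as 0 for clustering/correlation.
#'
#' @param raw,imputed [UsageMatrix()] objects over the same spots.
#' @param layout a [SpotLayout()] with layer labels.
#' @param resolution,seed passed to [cluster_spots()].
#' @return list with `raw` and `imputed` sub-lists, each holding `panel`
#'   (a `MetricPanel`) and `layer_cor` (named per-layer median pairwise
#'   correlation).
#' @export
evaluate_imputation <- function(raw, imputed, layout, resolution = 1, seed = 1) {
  if (!has_layers(layout)) stop_data("layout must carry reference layer labels")
  stopifnot(identical(colnames(raw$values), layout$spot_id),
            identical(colnames(imputed$values), layout$spot_id))
  eval_one <- function(u) {
    v <- u$values
    v[is.na(v)] <- 0
    uf <- UsageMatrix(v, usage_type = u$usage_type)
    cl <- cluster_spots(uf, resolution = resolution, seed = seed)
    panel <- metric_panel(t(v), cl, layout$layer)
    list(panel = panel, layer_cor = layer_correlations(v, layout$layer))
  }
  list(raw = eval_one(raw), imputed = eval_one(imputed))
}

## median pairwise spot-spot Pearson correlation within each layer
layer_correlations <- function(values, layers) {
  out <- vapply(unique(layers), function(L) {
    cols <- which(layers == L)
    if (length(cols) < 2) return(NA_real_)
    cc <- stats::cor(values[, cols, drop = FALSE])
    stats::median(cc[upper.tri(cc)])
  }, numeric(1))
  names(out) <- unique(layers)
  out
}
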