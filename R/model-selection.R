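## Choosing the imputation neighbourhood size k: impute at every k on a
## grid, cluster the spots, score each clustering with the eight-metric
## panel, Z-score every metric across the grid and sum the Z-scores into a
## comprehensive index; the optimal k maximizes the index (smaller k wins
## near-ties).

#' Graph-based clustering of spots from a usage matrix
#'
#' PCA to at most `ndim` components, a shared-nearest-neighbour graph on
#' the spots, then Louvain modularity optimization at the given
#' resolution. Deterministic for a fixed seed.
#'
#' @param u a fully imputed [UsageMatrix()] (no missing cells).
#' @param resolution Louvain resolution parameter (default 1; larger
#'   values yield more communities).
#' @param ndim maximum PCA dimensionality (default 30, capped at
#'   spots - 1 and the gene count).
#' @param nn neighbours for the SNN graph (default 20, capped at
#'   spots - 1).
#' @param seed RNG seed for the community search.
#' @return integer cluster label per spot (named by spot id).
#' @export
cluster_spots <- function(u, resolution = 1, ndim = 30, nn = 20, seed = 1) {
  stopifnot(inherits(u, "UsageMatrix"))
  if (anyNA(u$values)) stop_data("cluster_spots needs a fully imputed matrix")
  X <- t(u$values)  # spots x genes
  m <- nrow(X)
  if (m < 3) stop_data("need at least 3 spots to cluster")
  nn <- min(nn, m - 1)
  ndim <- min(ndim, m - 1, ncol(X))
  keep <- apply(X, 2, stats::var) > 0
  if (any(keep)) {
    pc <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    ndim <- min(ndim, ncol(pc$x))
    E <- pc$x[, seq_len(ndim), drop = FALSE]
  } else {
    return(stats::setNames(rep(1L, m), rownames(X)))  # no structure at all
  }
  D <- as.matrix(stats::dist(E))
  knn <- t(vapply(seq_len(m), function(i) {
    ord <- order(D[i, ], seq_len(m))
    setdiff(ord, i)[seq_len(nn)]
  }, integer(nn)))
  ## SNN weights: Jaccard overlap of neighbour sets for kNN-linked pairs
  adj <- matrix(0, m, m)
  for (i in seq_len(m)) adj[i, knn[i, ]] <- 1
  link <- pmax(adj, t(adj))
  w <- matrix(0, m, m)
  pairs <- which(link == 1 & upper.tri(link), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    shared <- length(intersect(knn[i, ], knn[j, ]))
    w[i, j] <- w[j, i] <- shared / (2 * nn - shared)
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  stats::setNames(as.integer(igraph::membership(comm)), rownames(X))
}

#' Comprehensive index across a k grid
#'
#' Each metric is Z-scored (sample sd) across the panels; lower-is-better
#' metrics contribute their negated Z-score; metrics constant across the
#' grid (or non-finite anywhere) contribute 0. The comprehensive index of
#' a grid point is the sum of its metric Z-scores.
#'
#' @param panels list of `MetricPanel` objects (>= 2), one per grid point.
#' @return numeric vector of comprehensive-index values, one per panel.
#' @export
comprehensive_index <- function(panels) {
  if (length(panels) < 2)
    stop_data("comprehensive index needs >= 2 panels (Z-scores need dispersion)")
  metrics <- names(panels[[1]])
  M <- vapply(panels, function(p) as.numeric(p[metrics]), numeric(length(metrics)))
  M <- matrix(M, nrow = length(metrics))  # metrics x grid
  dir <- attr(panels[[1]], "direction")[metrics]
  z <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) {
    v <- M[i, ]
    if (any(!is.finite(v))) next
    s <- stats::sd(v)
    if (s == 0) next
    zi <- (v - mean(v)) / s
    z[i, ] <- if (dir[i] == "lower_better") -zi else zi
  }
  colSums(z)
}

#' Select the imputation neighbourhood size k
#'
#' For every k on the grid: impute the raw usage matrix with that k,
#' cluster the spots, and compute the eight-metric panel against the
#' layout's reference layers (internal metrics only if layers are absent).
#' The optimal k maximizes the comprehensive index; near-ties (within
#' 1e-9) go to the smaller k. Grid values >= the spot count are skipped
#' with a warning.
#'
#' @param u_raw the raw (sparse) [UsageMatrix()].
#' @param g the gene-spot expression [GeneSpotMatrix()] (raw counts; it is
#'   scaled internally).
#' @param layout a [SpotLayout()]; layer labels enable the external
#'   metrics.
#' @param k_grid integer vector of candidate k values (default 2:100).
#' @param resolution,seed clustering parameters, held fixed across the
#'   grid.
#' @param max_iter imputation iteration cap.
#' @return An object of class `KSelectionResult`: list with `k_grid`,
#'   `panels`, `zsum` and `k_opt`.
#' @export
select_k <- function(u_raw, g, layout, k_grid = 2:100,
                     resolution = 1, seed = 1, max_iter = 10) {
  stopifnot(inherits(u_raw, "UsageMatrix"), inherits(g, "GeneSpotMatrix"))
  m <- ncol(u_raw$values)
  usable <- k_grid[k_grid < m]
  if (length(usable) < length(k_grid))
    warning(sprintf("dropping k values >= spot count (%d)", m))
  if (length(usable) < 2) stop_data("need >= 2 usable k values")
  ranking <- build_ranking(if (g$scaled) g else scale_genes(g))
  ref <- if (has_layers(layout)) layout$layer else NULL
  panel_names <- c(if (!is.null(ref)) c("ari", "jaccard", "nmi", "purity"),
                   c("dbi", "ch", "silhouette", "dunn"))
  na_panel <- structure(stats::setNames(rep(NA_real_, length(panel_names)),
                                        panel_names),
                        direction = stats::setNames(
                          ifelse(panel_names == "dbi", "lower_better",
                                 "higher_better"), panel_names),
                        class = "MetricPanel")
  panels <- lapply(usable, function(k) {
    imp <- impute(u_raw, ranking, ImputationConfig(k = k, max_iter = max_iter))
    cl <- cluster_spots(imp, resolution = resolution, seed = seed)
    if (length(unique(cl)) < 2) return(na_panel)  # degenerate clustering
    metric_panel(t(imp$values), cl, ref)
  })
  zsum <- comprehensive_index(panels)
  best <- max(zsum)
  k_opt <- usable[which(zsum >= best - 1e-9)[1]]  # smallest k on near-tie
  structure(list(k_grid = usable, panels = panels, zsum = zsum, k_opt = k_opt),
            class = "KSelectionResult")
}

#' @export
print.KSelectionResult <- function(x, ...) {
  cat(sprintf("KSelectionResult: grid of %d k values, k_opt = %d\n",
              length(x$k_grid), x$k_opt))
  print(data.frame(k = x$k_grid, zsum = round(x$zsum, 3)))
  invisible(x)
}
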