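## Self-contained clustering-validation metrics and Moran's I.
## Four external metrics compare a predicted labelling with a reference
## (ARI, pairwise Jaccard, NMI, purity); four internal metrics judge
## cluster separation from the data alone (DBI, CH, silhouette, Dunn).
## All are written directly from their definitions so they can be verified
## against independent brute-force oracles.

#' External clustering metrics: ARI, Jaccard, NMI, purity
#'
#' ARI is the permutation-model adjusted Rand index; Jaccard is the
#' pair-counting TP/(TP+FP+FN) over co-clustered pairs; NMI is mutual
#' information normalized by the arithmetic mean of the two label
#' entropies; purity is the summed majority count over predicted clusters
#' divided by n.
#'
#' @param pred,ref equal-length labelings (any atomic type).
#' @return named list with `ari`, `jaccard`, `nmi`, `purity`.
#' @export
external_metrics <- function(pred, ref) {
  if (length(pred) != length(ref))
    stop_data("labelings differ in length (%d vs %d)", length(pred), length(ref))
  n <- length(pred)
  ct <- table(pred, ref)
  ## pair counting
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(ct))
  sum_a <- sum(comb2(rowSums(ct)))
  sum_b <- sum(comb2(colSums(ct)))
  total <- comb2(n)
  exp_idx <- sum_a * sum_b / total
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == exp_idx) 1 else (sum_ij - exp_idx) / (max_idx - exp_idx)
  tp <- sum_ij
  fp <- sum_a - tp
  fn <- sum_b - tp
  jaccard <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  ## information-theoretic
  pj <- rowSums(ct) / n
  pk <- colSums(ct) / n
  pjk <- ct / n
  mi <- sum(ifelse(pjk > 0, pjk * log(pjk / outer(pj, pk)), 0))
  ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  hm <- (ent(pj) + ent(pk)) / 2
  nmi <- if (hm == 0) 1 else mi / hm
  purity <- sum(apply(ct, 1, max)) / n
  list(ari = ari, jaccard = jaccard, nmi = min(max(nmi, 0), 1), purity = purity)
}

#' Internal clustering metrics: DBI, CH, silhouette, Dunn
#'
#' Standard definitions on Euclidean geometry: DBI is the mean over
#' clusters of the worst pairwise (s_i + s_j)/d(c_i, c_j) with s the mean
#' distance to the centroid; CH is the between/within variance ratio
#' scaled by (n-k)/(k-1); silhouette is the mean silhouette width; Dunn is
#' the minimum inter-cluster point distance over the maximum intra-cluster
#' diameter.
#'
#' @param X numeric matrix, observations x features.
#' @param labels labelling of the rows (>= 2 non-empty clusters).
#' @return named list with `dbi`, `ch`, `silhouette`, `dunn`.
#' @export
internal_metrics <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  cl <- unique(labels)
  k <- length(cl)
  n <- nrow(X)
  if (k < 2) stop_data("internal metrics undefined for a single cluster")
  cent <- t(vapply(cl, function(L) colMeans(X[labels == L, , drop = FALSE]),
                   numeric(ncol(X))))
  sizes <- vapply(cl, function(L) sum(labels == L), numeric(1))
  euc <- function(a, b) sqrt(sum((a - b)^2))
  ## scatter per cluster
  s <- vapply(seq_len(k), function(i) {
    pts <- X[labels == cl[i], , drop = FALSE]
    mean(apply(pts, 1, euc, b = cent[i, ]))
  }, numeric(1))
  dbi <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j)
      (s[i] + s[j]) / euc(cent[i, ], cent[j, ]), numeric(1)))
  }, numeric(1)))
  grand <- colMeans(X)
  ssb <- sum(sizes * apply(cent, 1, function(c) sum((c - grand)^2)))
  ssw <- sum(vapply(seq_len(k), function(i) {
    pts <- X[labels == cl[i], , drop = FALSE]
    sum(sweep(pts, 2, cent[i, ])^2)
  }, numeric(1)))
  ch <- if (ssw == 0) Inf else (ssb / (k - 1)) / (ssw / (n - k))
  D <- as.matrix(stats::dist(X))
  sil <- mean(vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) == 1) 0 else sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(cl, labels[i]), function(L)
      mean(D[i, labels == L]), numeric(1)))
    if (sum(own) == 1) return(0)
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1)))
  inter <- min(vapply(seq_len(k - 1), function(i) {
    min(vapply((i + 1):k, function(j)
      min(D[labels == cl[i], labels == cl[j]]), numeric(1)))
  }, numeric(1)))
  intra <- max(vapply(cl, function(L) {
    d <- D[labels == L, labels == L, drop = FALSE]
    if (length(d) == 1) 0 else max(d)
  }, numeric(1)))
  dunn <- if (intra == 0) Inf else inter / intra
  list(dbi = dbi, ch = ch, silhouette = sil, dunn = dunn)
}

#' Eight-metric clustering panel
#'
#' Convenience wrapper combining [external_metrics()] (against reference
#' labels) and [internal_metrics()] (on the data), tagged with each
#' metric's direction. When `ref` is `NULL` only the four internal metrics
#' are produced.
#'
#' @param X observations x features matrix (spots in usage space).
#' @param pred predicted labelling of the rows.
#' @param ref optional reference labelling.
#' @return An object of class `MetricPanel`: named numeric vector with a
#'   `direction` attribute (`"higher_better"`/`"lower_better"`).
#' @export
metric_panel <- function(X, pred, ref = NULL) {
  int <- internal_metrics(X, pred)
  out <- c(if (!is.null(ref)) unlist(external_metrics(pred, ref)), unlist(int))
  dir <- ifelse(names(out) == "dbi", "lower_better", "higher_better")
  names(dir) <- names(out)
  structure(out, direction = dir, class = "MetricPanel")
}

#' Build spatial weights from spot coordinates
#'
#' Binary k-nearest-neighbour weights (default k = 6, reflecting the
#' roughly hexagonal spot array) or inverse-distance weights. kNN weights
#' are symmetrized (i~j if either is among the other's k nearest).
#'
#' @param layout a [SpotLayout()].
#' @param scheme `"knn"` or `"idw"`.
#' @param k neighbour count for `"knn"`.
#' @return symmetric numeric weight matrix with zero diagonal.
#' @export
spatial_weights <- function(layout, scheme = c("knn", "idw"), k = 6) {
  scheme <- match.arg(scheme)
  xy <- cbind(layout$x, layout$y)
  n <- nrow(xy)
  if (n < 3) stop_data("need at least 3 spots for spatial weights")
  D <- as.matrix(stats::dist(xy))
  if (scheme == "idw") {
    W <- 1 / D
    diag(W) <- 0
    return(W)
  }
  k <- min(k, n - 1)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    W[i, setdiff(ord, i)[seq_len(k)]] <- 1
  }
  W <- pmax(W, t(W))  # symmetrize
  W
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' I = (n / sum(W)) * (sum_ij w_ij z_i z_j) / sum_i z_i^2 with z the
#' centred values. The p-value comes from `n_perm` random permutations of
#' the values over the spots, computed as (b + 1) / (n_perm + 1) where b
#' counts permuted I at least as large as observed (one-sided, positive
#' autocorrelation).
#'
#' @param values numeric vector, one value per spot (non-constant).
#' @param layout a [SpotLayout()] giving the spot coordinates.
#' @param weights optional precomputed weight matrix; default kNN weights
#'   from [spatial_weights()].
#' @param k neighbour count when `weights` is `NULL`.
#' @param n_perm number of permutations (default 199; 0 skips the test).
#' @param seed RNG seed for the permutations.
#' @return list with `I` and `p_perm` (`NA` when `n_perm = 0`).
#' @export
morans_i <- function(values, layout, weights = NULL, k = 6,
                     n_perm = 199, seed = 1) {
  n <- length(values)
  if (stats::var(values) == 0)
    stop_data("Moran's I undefined for constant values")
  if (is.null(weights)) weights <- spatial_weights(layout, "knn", k = k)
  stopifnot(nrow(weights) == n)
  s0 <- sum(weights)
  stat <- function(z) (n / s0) * as.numeric(z %*% weights %*% z) / sum(z^2)
  z <- values - mean(values)
  I <- stat(z)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(b) stat(sample(z)), numeric(1))
    p <- (sum(perm >= I) + 1) / (n_perm + 1)
  }
  list(I = I, p_perm = p)
}
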