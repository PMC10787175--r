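## Major spatial usage patterns: k-means over the gene usage profiles of
## the combined spatial-APA gene set, centroid = per-spot mean profile of
## the member genes, with representative genes picked by correlation to
## the centroid and a layer-contrast ranking of the groups.

#' Cluster spatial-APA genes into usage patterns
#'
#' Multi-restart k-means on the gene usage profiles (genes as points in
#' spot space); the best-inertia solution under a fixed seed is kept.
#' Profiles are used unstandardized (usage already lies in \[0, 1\]).
#'
#' @param u a fully imputed [UsageMatrix()].
#' @param genes subset of `u`'s gene ids to cluster (the combined set).
#' @param n_groups number of k-means groups (default 10).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 1000; reduce for quick runs).
#' @param iter_max k-means iteration cap.
#' @return An object of class `PatternSet`: list with `n_groups`,
#'   `assignments` (named integer vector), `centroids` (group x spot),
#'   `selected` (initially empty) and `representatives` (initially `NULL`).
#' @export
cluster_patterns <- function(u, genes, n_groups = 10, seed = 1,
                             nstart = 1000, iter_max = 1e6) {
  stopifnot(inherits(u, "UsageMatrix"))
  if (anyNA(u$values)) stop_data("cluster_patterns needs a fully imputed matrix")
  missing_genes <- setdiff(genes, rownames(u$values))
  if (length(missing_genes) > 0)
    stop_data("genes not in the usage matrix: %s",
              paste(utils::head(missing_genes, 5), collapse = ", "))
  X <- u$values[genes, , drop = FALSE]
  if (length(genes) < n_groups)
    stop_data("fewer genes (%d) than groups (%d)", length(genes), n_groups)
  if (nrow(unique(X)) < n_groups)
    stop_data("fewer distinct usage profiles (%d) than groups (%d)",
              nrow(unique(X)), n_groups)
  if (length(genes) == n_groups) {
    ## one gene per group: the zero-inertia partition (kmeans needs
    ## centers < points)
    assignments <- stats::setNames(seq_along(genes), genes)
    centroids <- X
    rownames(centroids) <- paste0("pattern", seq_len(n_groups))
    return(structure(list(n_groups = n_groups, assignments = assignments,
                          centroids = centroids, selected = integer(0),
                          representatives = NULL),
                     class = "PatternSet"))
  }
  set.seed(seed)
  km <- stats::kmeans(X, centers = n_groups, nstart = nstart,
                      iter.max = iter_max)
  ## centroid = per-spot mean usage of member genes (== km centers)
  centroids <- km$centers
  rownames(centroids) <- paste0("pattern", seq_len(n_groups))
  structure(list(n_groups = n_groups,
                 assignments = stats::setNames(km$cluster, genes),
                 centroids = centroids,
                 selected = integer(0),
                 representatives = NULL),
            class = "PatternSet")
}

#' Select representative genes per pattern
#'
#' Pearson correlation between each member gene's usage profile and its
#' group centroid, with the standard correlation t-test; genes with
#' r > `r_thresh` and p < `p_thresh` become representatives, sorted by
#' descending r within each group. Singleton groups correlate their sole
#' gene with the centroid including it (r = 1) and are flagged.
#'
#' @param ps a `PatternSet` from [cluster_patterns()].
#' @param u the [UsageMatrix()] used for clustering.
#' @param r_thresh correlation threshold (default 0.5).
#' @param p_thresh p-value threshold (default 0.05).
#' @return `ps` with a `representatives` data.frame
#'   (gene_id, group, r, p, singleton).
#' @export
select_representatives <- function(ps, u, r_thresh = 0.5, p_thresh = 0.05) {
  stopifnot(inherits(ps, "PatternSet"), inherits(u, "UsageMatrix"))
  rows <- lapply(names(ps$assignments), function(g) {
    grp <- ps$assignments[[g]]
    prof <- u$values[g, ]
    cent <- ps$centroids[grp, ]
    singleton <- sum(ps$assignments == grp) == 1
    if (stats::sd(prof) == 0 || stats::sd(cent) == 0) {
      r <- if (singleton) 1 else NA_real_
      p <- if (singleton) 0 else NA_real_
    } else {
      ct <- stats::cor.test(prof, cent)
      r <- unname(ct$estimate)
      p <- ct$p.value
    }
    data.frame(gene_id = g, group = grp, r = r, p = p,
               singleton = singleton, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  keep <- !is.na(tab$r) & tab$r > r_thresh & tab$p < p_thresh
  reps <- tab[keep, , drop = FALSE]
  reps <- reps[order(reps$group, -reps$r), , drop = FALSE]
  ps$representatives <- reps
  ps
}

#' Rank patterns by layer contrast and flag the major ones
#'
#' Distinctness proxy: variance of the centroid's layer-wise means divided
#' by the mean within-layer variance of the centroid (a small epsilon
#' guards the denominator). The top `q` groups are flagged `selected`.
#'
#' @param ps a `PatternSet`.
#' @param labels layer label per spot (in centroid column order).
#' @param q number of groups to flag as major patterns (default 5).
#' @return `ps` with `selected` set to the top-q group indices (ranked)
#'   and a `scores` vector attached.
#' @export
rank_patterns <- function(ps, labels, q = 5) {
  stopifnot(inherits(ps, "PatternSet"))
  q <- min(q, ps$n_groups)
  scores <- apply(ps$centroids, 1, function(cent) {
    mu <- tapply(cent, labels, mean)
    wv <- tapply(cent, labels, function(v) if (length(v) < 2) 0 else stats::var(v))
    between <- stats::var(as.numeric(mu))
    if (is.na(between) || between == 0) return(0)
    between / (mean(as.numeric(wv)) + 1e-12)
  })
  ord <- order(scores, decreasing = TRUE)
  ps$selected <- ord[seq_len(q)]
  ps$scores <- scores
  ps
}

#' @export
print.PatternSet <- function(x, ...) {
  cat(sprintf("PatternSet: %d genes in %d groups", length(x$assignments),
              x$n_groups))
  if (length(x$selected)) cat(sprintf(", %d selected", length(x$selected)))
  if (!is.null(x$representatives))
    cat(sprintf(", %d representative genes", nrow(x$representatives)))
  cat("\n")
  print(table(group = x$assignments))
  invisible(x)
}
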