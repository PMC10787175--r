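## Detection of the three categories of spatial APA dynamics:
##   DEAPA — differential usage between two layers (pairwise rank-sum),
##   LSAPA — layer-specific usage (one layer vs all the rest),
##   SVAPA — globally spatially variable usage (built-in Moran's I
##           permutation detector, or imported from an external tool).

new_apa_result <- function(gene, category, contrast, statistic, p_raw, p_adj,
                           log2fc = NA_real_, moran_i = NA_real_) {
  n <- length(gene)
  data.frame(gene_id = gene, category = rep_len(category, n),
             contrast = rep_len(contrast, n),
             statistic = rep_len(statistic, n),
             p_raw = rep_len(p_raw, n), p_adj = rep_len(p_adj, n),
             log2fc = rep_len(log2fc, n), moran_i = rep_len(moran_i, n),
             stringsAsFactors = FALSE)
}

empty_apa_result <- function() new_apa_result(character(0), character(0),
                                              character(0), numeric(0),
                                              numeric(0), numeric(0))

rank_sum_table <- function(u, in_a, in_b, category, contrast,
                           p_adjust, pseudo) {
  vals <- u$values
  genes <- rownames(vals)
  res <- lapply(genes, function(g) {
    a <- vals[g, in_a]; b <- vals[g, in_b]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    if (stats::var(c(a, b)) == 0) return(NULL)
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    lfc <- log2((mean(a) + pseudo) / (mean(b) + pseudo))
    new_apa_result(g, category, contrast, unname(wt$statistic),
                   wt$p.value, NA_real_, log2fc = lfc)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0) return(res)
  res$p_adj <- stats::p.adjust(res$p_raw, method = p_adjust)
  res
}

#' Differential APA usage between two spot groups (DEAPA)
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of the usage values of
#' group A vs group B; the effect size is
#' log2((mean_A + eps)/(mean_B + eps)). Genes with adjusted p < `p_thresh`
#' and |log2fc| > `lfc_thresh` are returned, sorted by adjusted p.
#' Missing cells (raw, unimputed matrices) are dropped per gene.
#'
#' @param u a [UsageMatrix()] (normally fully imputed).
#' @param labels layer label per spot (in the matrix's spot order).
#' @param group_a,group_b the two layer labels to contrast.
#' @param p_thresh adjusted-p threshold (default 0.05).
#' @param lfc_thresh absolute log2-fold-change threshold (default 0.5).
#' @param p_adjust multiple-testing method (default `"bonferroni"`,
#'   `"BH"` available).
#' @param pseudo pseudocount on the group means (default 0.01).
#' @return data.frame of results (class `SpatialAPAResult` rows).
#' @export
detect_deapa <- function(u, labels, group_a, group_b,
                         p_thresh = 0.05, lfc_thresh = 0.5,
                         p_adjust = c("bonferroni", "BH"), pseudo = 0.01) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(u, "UsageMatrix"), length(labels) == ncol(u$values))
  in_a <- labels == group_a
  in_b <- labels == group_b
  if (sum(in_a) < 2 || sum(in_b) < 2)
    stop_data("each group needs at least 2 spots")
  res <- rank_sum_table(u, in_a, in_b, "DEAPA",
                        paste(group_a, "vs", group_b), p_adjust, pseudo)
  if (is.null(res)) return(empty_apa_result())
  res <- res[res$p_adj < p_thresh & abs(res$log2fc) > lfc_thresh, , drop = FALSE]
  res[order(res$p_adj), , drop = FALSE]
}

#' Layer-specific APA usage (LSAPA)
#'
#' Runs the DEAPA contrast of every layer against the union of all other
#' layers and concatenates the results.
#'
#' @inheritParams detect_deapa
#' @return data.frame of results across all layer-vs-rest contrasts.
#' @export
detect_lsapa <- function(u, labels, p_thresh = 0.05, lfc_thresh = 0.5,
                         p_adjust = c("bonferroni", "BH"), pseudo = 0.01) {
  p_adjust <- match.arg(p_adjust)
  out <- lapply(unique(labels), function(L) {
    in_a <- labels == L
    in_b <- !in_a
    if (sum(in_a) < 2 || sum(in_b) < 2)
      stop_data("layer %s leaves a group with < 2 spots", L)
    res <- rank_sum_table(u, in_a, in_b, "LSAPA",
                          paste(L, "vs rest"), p_adjust, pseudo)
    if (is.null(res)) return(NULL)
    res[res$p_adj < p_thresh & abs(res$log2fc) > lfc_thresh, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_apa_result())
  out[order(out$p_adj), , drop = FALSE]
}

#' Transform usage values to pseudo-counts for external SV detectors
#'
#' Count-based spatially-variable-gene detectors (e.g. Poisson models)
#' need count input; usage values in \[0, 1\] are mapped monotonically to
#' integers in \[1, 10\]: RUD via round(10^value), intronic ratio via
#' round(2^(c * value)) with c = log2(10) so both modes share the range.
#'
#' @param u a fully imputed [UsageMatrix()].
#' @param c_intronic exponent scale for the intronic mode
#'   (default `log2(10)`).
#' @return A [GeneSpotMatrix()] of transformed counts.
#' @export
usage_to_counts <- function(u, c_intronic = log2(10)) {
  stopifnot(inherits(u, "UsageMatrix"))
  if (anyNA(u$values)) stop_data("usage_to_counts needs a fully imputed matrix")
  v <- if (u$usage_type == "RUD") round(10^u$values)
       else round(2^(c_intronic * u$values))
  GeneSpotMatrix(v, scaled = FALSE)
}

#' Built-in spatially-variable APA detector (Moran's I permutation test)
#'
#' Per gene, a one-sided Moran's I permutation test for positive spatial
#' autocorrelation of the usage values over the spot coordinates, followed
#' by Benjamini-Hochberg adjustment across genes; genes with adjusted
#' p < `fdr` are reported. Zero-variance genes are skipped with a warning.
#'
#' @param u a [UsageMatrix()] (missing cells, if any, are treated as 0).
#' @param layout a [SpotLayout()].
#' @param n_perm permutations per gene (default 199).
#' @param seed RNG seed.
#' @param fdr adjusted-p threshold (default 0.05).
#' @param k neighbour count for the spatial weights.
#' @return data.frame of SVAPA results sorted by adjusted p.
#' @export
detect_svapa_builtin <- function(u, layout, n_perm = 199, seed = 1,
                                 fdr = 0.05, k = 6) {
  stopifnot(inherits(u, "UsageMatrix"))
  vals <- u$values
  vals[is.na(vals)] <- 0
  W <- spatial_weights(layout, "knn", k = k)
  n <- ncol(vals)
  s0 <- sum(W)
  keep <- apply(vals, 1, stats::var) > 0
  if (any(!keep))
    warning(sprintf("skipping %d zero-variance gene(s)", sum(!keep)))
  vals <- vals[keep, , drop = FALSE]
  if (nrow(vals) == 0) return(empty_apa_result())
  set.seed(seed)
  perm_idx <- replicate(n_perm, sample.int(n))
  Z <- vals - rowMeans(vals)
  stat_all <- function(Zm) {
    num <- rowSums((Zm %*% W) * Zm)
    (n / s0) * num / rowSums(Zm^2)
  }
  I_obs <- stat_all(Z)
  ge <- rep(0L, nrow(Z))
  for (b in seq_len(n_perm)) {
    Ib <- stat_all(Z[, perm_idx[, b], drop = FALSE])
    ge <- ge + (Ib >= I_obs)
  }
  p_raw <- (ge + 1) / (n_perm + 1)
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  res <- new_apa_result(rownames(Z), "SVAPA", "global", I_obs, p_raw, p_adj,
                        moran_i = I_obs)
  res <- res[res$p_adj < fdr, , drop = FALSE]
  res[order(res$p_adj), , drop = FALSE]
}

#' Import spatially-variable APA results from an external detector
#'
#' Reads a TSV with columns `gene` and `p_adj` and/or `p_raw` (e.g. a
#' reshaped SPARK output); when only `p_raw` is present it is BH-adjusted
#' on import (flagged in the `contrast` field). Rows with adjusted
#' p < `fdr` become SVAPA results.
#'
#' @param path TSV path.
#' @param fdr adjusted-p threshold (default 0.05).
#' @return data.frame of SVAPA results.
#' @export
import_svapa <- function(path, fdr = 0.05) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df))
    stop_data("imported SVAPA table needs a 'gene' column")
  if (!any(c("p_adj", "p_raw") %in% names(df)))
    stop_data("imported SVAPA table needs a 'p_adj' or 'p_raw' column")
  if (nrow(df) == 0) return(empty_apa_result())
  adjusted_on_import <- !"p_adj" %in% names(df)
  if (adjusted_on_import) df$p_adj <- stats::p.adjust(df$p_raw, method = "BH")
  if (!"p_raw" %in% names(df)) df$p_raw <- NA_real_
  res <- new_apa_result(df$gene, "SVAPA",
                        if (adjusted_on_import) "imported (BH on import)"
                        else "imported",
                        NA_real_, df$p_raw, df$p_adj)
  res <- res[res$p_adj < fdr, , drop = FALSE]
  res[order(res$p_adj), , drop = FALSE]
}

#' Combine DEAPA/LSAPA/SVAPA gene sets without redundancy
#'
#' @param deapa,lsapa,svapa result data.frames (or `NULL`).
#' @return data.frame with one row per unique gene and logical membership
#'   flags `deapa`, `lsapa`, `svapa`.
#' @export
combine_gene_sets <- function(deapa = NULL, lsapa = NULL, svapa = NULL) {
  gs <- function(x) if (is.null(x) || nrow(x) == 0) character(0) else unique(x$gene_id)
  d <- gs(deapa); l <- gs(lsapa); s <- gs(svapa)
  genes <- sort(unique(c(d, l, s)))
  data.frame(gene_id = genes,
             deapa = genes %in% d,
             lsapa = genes %in% l,
             svapa = genes %in% s,
             stringsAsFactors = FALSE)
}
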