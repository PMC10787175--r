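## Per-gene, per-spot APA usage indices computed from an annotated
## poly(A)-site matrix.  Two usage types are supported:
##   RUD            — relative usage of the distal 3' UTR site,
##   intronic_ratio — highest per-gene fraction of reads at an intronic site.
## A zero denominator (no site of the gene captured in a spot) is a dropout
## and becomes NA, never 0.

UTR_REGIONS <- c("3UTR", "extended3UTR")

## distal = strand-aware farthest 3' UTR site from the start codon:
## largest coord on "+", smallest on "-"
distal_site_index <- function(sites) {
  if (sites$strand[1] == "+") which.max(sites$coord) else which.min(sites$coord)
}

#' Relative usage of the distal poly(A) site (RUD)
#'
#' For every gene with at least two poly(A) sites in the (extended) 3' UTR,
#' RUD in a spot is the count at the distal site divided by the summed
#' counts of all the gene's 3' UTR sites in that spot. The distal site is
#' the strand-aware farthest 3' UTR site from the start codon. Spots where
#' no site of the gene was captured (zero denominator) are dropouts (`NA`).
#'
#' @param pa an annotated [PolyASiteMatrix()] (extended3UTR sites are pooled
#'   with 3UTR sites).
#' @return A [UsageMatrix()] with `usage_type = "RUD"`, one row per
#'   eligible 3' UTR APA gene.
#' @export
compute_rud <- function(pa) {
  stopifnot(inherits(pa, "PolyASiteMatrix"))
  utr <- pa$sites$region %in% UTR_REGIONS & !is.na(pa$sites$gene)
  tab <- table(pa$sites$gene[utr])
  genes <- sort(names(tab[tab >= 2]))
  if (length(genes) == 0)
    stop_data("no gene has >= 2 poly(A) sites in the 3' UTR")
  vals <- matrix(NA_real_, length(genes), length(pa$spot_ids),
                 dimnames = list(genes, pa$spot_ids))
  for (g in genes) {
    idx <- which(utr & pa$sites$gene == g)
    sub <- pa$sites[idx, , drop = FALSE]
    distal <- idx[distal_site_index(sub)]
    denom <- colSums(pa$counts[idx, , drop = FALSE])
    num <- pa$counts[distal, ]
    v <- ifelse(denom > 0, num / denom, NA_real_)
    vals[g, ] <- v
  }
  UsageMatrix(vals, usage_type = "RUD")
}

#' Intronic APA usage (highest intronic-site ratio)
#'
#' Sites are first filtered: a site must be supported by at least
#' `min_reads` reads in total and be non-zero in at least `min_spots`
#' spots. Among surviving sites, genes with multiple sites and at least one
#' intronic site are retained. Per gene and spot, each intronic site's
#' ratio is its count over the summed counts of all the gene's surviving
#' sites; the gene's usage is the highest intronic ratio. Zero denominator
#' means dropout (`NA`). The denominator runs over surviving sites only.
#'
#' @param pa an annotated [PolyASiteMatrix()].
#' @param min_reads minimum total read support per site (default 3).
#' @param min_spots minimum number of spots a site must appear in
#'   (default 3).
#' @return A [UsageMatrix()] with `usage_type = "intronic_ratio"`.
#' @export
compute_intronic_ratio <- function(pa, min_reads = 3, min_spots = 3) {
  stopifnot(inherits(pa, "PolyASiteMatrix"))
  keep_site <- rowSums(pa$counts) >= min_reads &
    rowSums(pa$counts > 0) >= min_spots & !is.na(pa$sites$gene)
  sites <- pa$sites[keep_site, , drop = FALSE]
  counts <- pa$counts[keep_site, , drop = FALSE]
  tab <- table(sites$gene)
  multi <- names(tab[tab >= 2])
  has_intron <- unique(sites$gene[sites$region == "intron"])
  genes <- sort(intersect(multi, has_intron))
  if (length(genes) == 0)
    stop_data("no gene passes the intronic APA filters")
  vals <- matrix(NA_real_, length(genes), length(pa$spot_ids),
                 dimnames = list(genes, pa$spot_ids))
  for (g in genes) {
    idx <- which(sites$gene == g)
    denom <- colSums(counts[idx, , drop = FALSE])
    iidx <- idx[sites$region[idx] == "intron"]
    imax <- apply(counts[iidx, , drop = FALSE], 2, max)
    vals[g, ] <- ifelse(denom > 0, imax / denom, NA_real_)
  }
  UsageMatrix(vals, usage_type = "intronic_ratio")
}

#' Gene-level expression from summed poly(A)-site counts
#'
#' The summed expression of a gene's poly(A) sites serves as its gene
#' expression when no independent gene-spot matrix is available.
#' Intergenic/unassigned sites contribute to no gene.
#'
#' @param pa an annotated [PolyASiteMatrix()].
#' @return A raw-count [GeneSpotMatrix()].
#' @export
gene_level_counts <- function(pa) {
  stopifnot(inherits(pa, "PolyASiteMatrix"))
  keep <- !is.na(pa$sites$gene)
  genes <- sort(unique(pa$sites$gene[keep]))
  vals <- matrix(0, length(genes), length(pa$spot_ids),
                 dimnames = list(genes, pa$spot_ids))
  agg <- rowsum(pa$counts[keep, , drop = FALSE], group = pa$sites$gene[keep])
  vals[rownames(agg), ] <- agg
  GeneSpotMatrix(vals, scaled = FALSE)
}
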