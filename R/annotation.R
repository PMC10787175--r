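#' @importFrom GenomicRanges GRanges reduce start end strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
NULL

#' Build flattened gene models from a GFF3/GTF annotation
#'
#' Each gene is flattened to a union model across its transcripts: exons are
#' reduced, introns are the gaps between reduced exons inside the gene span,
#' and 3' UTRs are taken from annotated `three_prime_UTR` features or, when
#' absent, inferred as exonic sequence strictly downstream (in transcription
#' direction) of the union CDS. Genes without CDS get no 3' UTR.
#'
#' @param annotation_path path to a GFF3 or GTF file (format inferred from
#'   the extension by rtracklayer).
#' @return A named list of `GeneModel` objects, each a list with fields
#'   `gene_id`, `chrom`, `strand`, interval data.frames `utr3`, `cds`,
#'   `exon`, `intron` (columns start/end, 1-based inclusive) and `utr3_end`,
#'   the most-downstream 3' UTR coordinate in transcription direction
#'   (`NA` if the gene has no 3' UTR).
#' @export
build_gene_models <- function(annotation_path) {
  gr <- rtracklayer::import(annotation_path)
  md <- as.data.frame(mcols(gr))
  type <- as.character(md$type)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr), end = end(gr),
                   strand = as.character(strand(gr)),
                   type = type, stringsAsFactors = FALSE)
  ## resolve gene id per feature: GTF carries gene_id; GFF3 uses Parent chains
  if ("gene_id" %in% names(md) && !all(is.na(md$gene_id))) {
    df$gene <- as.character(md$gene_id)
  } else {
    id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, nrow(df))
    parent <- if ("Parent" %in% names(md)) {
      vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
             character(1))
    } else rep(NA_character_, nrow(df))
    is_gene <- type == "gene"
    gene_ids <- id[is_gene]
    ## transcript -> gene map
    is_tx <- type %in% c("mRNA", "transcript") & parent %in% gene_ids
    tx2gene <- stats::setNames(parent[is_tx], id[is_tx])
    df$gene <- NA_character_
    df$gene[is_gene] <- gene_ids
    df$gene[is_tx] <- parent[is_tx]
    leaf <- !is_gene & !is_tx
    df$gene[leaf] <- ifelse(parent[leaf] %in% gene_ids, parent[leaf],
                            unname(tx2gene[parent[leaf]]))
    orphan <- leaf & is.na(df$gene) & df$type %in% c("exon", "CDS", "three_prime_UTR")
    if (any(orphan))
      stop_data("malformed annotation hierarchy: features without resolvable gene parent: %s",
                paste(utils::head(id[orphan], 5), collapse = ", "))
  }
  df <- df[!is.na(df$gene), , drop = FALSE]
  genes <- unique(df$gene[df$type %in% c("gene", "exon", "CDS")])
  models <- lapply(genes, function(g) {
    sub <- df[df$gene == g, , drop = FALSE]
    str <- sub$strand[1]
    chrom <- sub$chrom[1]
    redu <- function(tt) {
      s <- sub[sub$type %in% tt, , drop = FALSE]
      if (nrow(s) == 0) return(data.frame(start = integer(0), end = integer(0)))
      r <- reduce(IRanges(s$start, s$end))
      data.frame(start = start(r), end = end(r))
    }
    exon <- redu("exon")
    cds <- redu("CDS")
    utr3 <- redu(c("three_prime_UTR", "3UTR"))
    if (nrow(utr3) == 0 && nrow(cds) > 0 && nrow(exon) > 0) {
      ## exonic sequence downstream of the stop codon
      ex <- IRanges(exon$start, exon$end)
      if (str == "+") {
        stop_pos <- max(cds$end)
        down <- IRanges::restrict(ex, start = stop_pos + 1L)
      } else {
        stop_pos <- min(cds$start)
        down <- IRanges::restrict(ex, end = stop_pos - 1L)
      }
      utr3 <- data.frame(start = start(down), end = end(down))
      utr3 <- utr3[utr3$end >= utr3$start, , drop = FALSE]
    }
    intron <- data.frame(start = integer(0), end = integer(0))
    if (nrow(exon) > 1) {
      ex <- IRanges(exon$start, exon$end)
      gap <- IRanges::gaps(ex, start = min(exon$start), end = max(exon$end))
      intron <- data.frame(start = start(gap), end = end(gap))
    }
    utr3_end <- if (nrow(utr3) == 0) NA_integer_ else
      if (str == "+") max(utr3$end) else min(utr3$start)
    structure(list(gene_id = g, chrom = chrom, strand = str,
                   utr3 = utr3, cds = cds, exon = exon, intron = intron,
                   utr3_end = utr3_end),
              class = "GeneModel")
  })
  names(models) <- genes
  models
}

in_intervals <- function(pos, iv) {
  nrow(iv) > 0 && any(pos >= iv$start & pos <= iv$end)
}

## region of `pos` inside one gene model, ignoring the extension window
model_region <- function(model, pos) {
  if (in_intervals(pos, model$utr3)) return("3UTR")
  if (in_intervals(pos, model$intron)) return("intron")
  if (in_intervals(pos, model$cds)) return("CDS")
  if (in_intervals(pos, model$exon)) return("exon")
  NA_character_
}

in_extension <- function(model, pos, utr_extension) {
  if (is.na(model$utr3_end) || utr_extension <= 0) return(FALSE)
  if (model$strand == "+")
    pos > model$utr3_end && pos <= model$utr3_end + utr_extension
  else
    pos < model$utr3_end && pos >= model$utr3_end - utr_extension
}

gene_span <- function(model) {
  iv <- rbind(model$exon, model$cds, model$utr3)
  if (nrow(iv) == 0) return(c(NA_integer_, NA_integer_))
  c(min(iv$start), max(iv$end))
}

#' Assign a poly(A) site to a gene and genomic region
#'
#' A site is assigned to the same-strand, same-chromosome gene whose
#' annotated intervals contain it, with region priority
#' 3UTR > extended3UTR > intron > CDS > exon. A site lying within
#' `utr_extension` bp downstream (strand-aware) of a gene's 3' UTR end and
#' inside no gene's annotated region is labelled `extended3UTR` for that
#' gene; anything else is `intergenic`. An annotated region in one gene
#' beats another gene's extension window; ties on priority go to the
#' smallest containing gene.
#'
#' @param site list or one-row data.frame with fields `chrom`, `strand`,
#'   `coord`.
#' @param models gene models from [build_gene_models()].
#' @param utr_extension downstream extension in bp (default 1000) used to
#'   recruit intergenic sites originating from unannotated 3' UTRs.
#' @return list with `gene` (id or `NA`) and `region`.
#' @export
assign_region <- function(site, models, utr_extension = 1000) {
  stopifnot(utr_extension >= 0)
  pos <- as.integer(site$coord)
  priority <- c("3UTR" = 1, "extended3UTR" = 2, "intron" = 3,
                "CDS" = 4, "exon" = 5)
  best <- NULL
  ext_best <- NULL
  for (model in models) {
    if (model$chrom != site$chrom || model$strand != site$strand) next
    reg <- model_region(model, pos)
    span <- gene_span(model)
    width <- span[2] - span[1] + 1
    if (is.na(reg)) {
      ## extension window candidate, only usable if no gene's annotated
      ## region contains the site
      if (in_extension(model, pos, utr_extension) &&
          (is.null(ext_best) || width < ext_best$width))
        ext_best <- list(gene = model$gene_id, region = "extended3UTR",
                         width = width)
      next
    }
    cand <- list(gene = model$gene_id, region = reg,
                 prio = priority[[reg]], width = width)
    if (is.null(best) || cand$prio < best$prio ||
        (cand$prio == best$prio && cand$width < best$width))
      best <- cand
  }
  if (is.null(best)) best <- ext_best
  if (is.null(best)) return(list(gene = NA_character_, region = "intergenic"))
  list(gene = best$gene, region = best$region)
}

#' Annotate every site of a poly(A)-site matrix
#'
#' @param pa a [PolyASiteMatrix()].
#' @param models gene models from [build_gene_models()].
#' @param utr_extension see [assign_region()].
#' @return The matrix with its `sites$gene` and `sites$region` columns
#'   replaced by the assignments.
#' @export
annotate_sites <- function(pa, models, utr_extension = 1000) {
  stopifnot(inherits(pa, "PolyASiteMatrix"))
  res <- lapply(seq_len(nrow(pa$sites)), function(i)
    assign_region(pa$sites[i, ], models, utr_extension))
  pa$sites$gene <- vapply(res, function(r) as.character(r$gene), character(1))
  pa$sites$region <- vapply(res, function(r) r$region, character(1))
  pa
}
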