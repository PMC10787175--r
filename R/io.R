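#' @importFrom Matrix readMM writeMM Matrix
#' @importFrom utils read.delim write.table
NULL

VALID_REGIONS <- c("3UTR", "extended3UTR", "intron", "CDS", "exon",
                   "intergenic", "unassigned")

stop_data <- function(fmt, ...) {
  stop(structure(class = c("spatialAPA_data_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
stop_config <- function(fmt, ...) {
  stop(structure(class = c("spatialAPA_config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' Poly(A)-site count matrix with site metadata
#'
#' Container for the quantified 3'-end landscape: a non-negative integer
#' matrix with one row per poly(A) site and one column per spatial spot,
#' plus per-site genomic metadata (chromosome, strand, cleavage coordinate,
#' gene and genomic region).
#'
#' @param counts integer matrix, sites x spots, non-negative.
#' @param sites data.frame with columns `site_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `coord` (1-based cleavage position), `gene` (id or `NA`),
#'   `region` (one of 3UTR, extended3UTR, intron, CDS, exon, intergenic,
#'   unassigned).
#' @param spot_ids character vector of unique spot identifiers, one per
#'   column of `counts`.
#' @return An object of class `PolyASiteMatrix`.
#' @export
PolyASiteMatrix <- function(counts, sites, spot_ids) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (anyDuplicated(sites$site_id))
    stop_data("duplicate site ids: %s",
              paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "))
  if (anyDuplicated(spot_ids))
    stop_data("duplicate spot ids")
  if (nrow(counts) != nrow(sites))
    stop_data("matrix has %d rows but sites metadata has %d rows (site axis mismatch)",
              nrow(counts), nrow(sites))
  if (ncol(counts) != length(spot_ids))
    stop_data("matrix has %d columns but %d spot ids (spot axis mismatch)",
              ncol(counts), length(spot_ids))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_data("negative or non-integer count at site row %d, spot column %d",
              bad[1, 1], bad[1, 2])
  if (!all(sites$strand %in% c("+", "-")))
    stop_data("site strand must be '+' or '-'")
  if (!is.null(sites$region) && !all(sites$region %in% VALID_REGIONS))
    stop_data("unknown region label: %s",
              paste(setdiff(sites$region, VALID_REGIONS), collapse = ", "))
  rownames(counts) <- sites$site_id
  colnames(counts) <- spot_ids
  structure(list(counts = counts, sites = sites,
                 spot_ids = as.character(spot_ids)),
            class = "PolyASiteMatrix")
}

#' @export
print.PolyASiteMatrix <- function(x, ...) {
  cat(sprintf("PolyASiteMatrix: %d poly(A) sites x %d spots (total count %g)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  tab <- table(x$sites$region)
  cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Gene-by-spot expression matrix
#'
#' @param values numeric matrix, genes x spots; raw counts (`scaled = FALSE`)
#'   or centred/standardized values (`scaled = TRUE`).
#' @param gene_ids,spot_ids unique identifiers for rows / columns.
#' @param scaled logical flag; unscaled matrices must be non-negative.
#' @return An object of class `GeneSpotMatrix`.
#' @export
GeneSpotMatrix <- function(values, gene_ids = rownames(values),
                           spot_ids = colnames(values), scaled = FALSE) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(spot_ids))
    stop_data("gene_ids and spot_ids are required")
  if (anyDuplicated(gene_ids)) stop_data("duplicate gene ids")
  if (anyDuplicated(spot_ids)) stop_data("duplicate spot ids")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(spot_ids))
    stop_data("dimension mismatch between values and id vectors")
  if (!scaled && any(values < 0))
    stop_data("unscaled gene-spot matrix must be non-negative")
  rownames(values) <- gene_ids
  colnames(values) <- spot_ids
  structure(list(values = values, scaled = isTRUE(scaled)),
            class = "GeneSpotMatrix")
}

#' @export
print.GeneSpotMatrix <- function(x, ...) {
  cat(sprintf("GeneSpotMatrix: %d genes x %d spots (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$scaled) "scaled" else "raw counts"))
  invisible(x)
}

#' Spot layout: array coordinates and optional morphological layers
#'
#' @param spot_ids unique spot identifiers.
#' @param x,y numeric array coordinates.
#' @param layer optional character vector of reference layer labels (all
#'   non-empty if supplied).
#' @return A data.frame of class `SpotLayout` with columns
#'   `spot_id`, `x`, `y` and optionally `layer`.
#' @export
SpotLayout <- function(spot_ids, x, y, layer = NULL) {
  if (anyDuplicated(spot_ids)) stop_data("duplicate spot ids in layout")
  if (length(x) != length(spot_ids) || length(y) != length(spot_ids))
    stop_data("coordinate vectors must match spot_ids in length")
  if (any(is.na(x)) || any(is.na(y)))
    stop_data("missing spot coordinate")
  df <- data.frame(spot_id = as.character(spot_ids),
                   x = as.numeric(x), y = as.numeric(y),
                   stringsAsFactors = FALSE)
  if (!is.null(layer)) {
    layer <- as.character(layer)
    if (length(layer) != length(spot_ids) || any(is.na(layer)) || any(!nzchar(layer)))
      stop_data("every spot needs a non-empty layer label when layers are supplied")
    df$layer <- layer
  }
  class(df) <- c("SpotLayout", "data.frame")
  df
}

has_layers <- function(layout) "layer" %in% names(layout)

#' Gene-by-spot APA usage matrix with explicit missingness
#'
#' Values are relative usages in \[0, 1\] (RUD for 3' UTR APA, intronic
#' ratio for intronic APA); dropout cells — (gene, spot) pairs whose site
#' counts give a zero denominator — are `NA`, which is distinct from a
#' legitimate usage of 0.
#'
#' @param values numeric matrix genes x spots; `NA` marks missing cells,
#'   all non-missing values must lie in \[0, 1\].
#' @param gene_ids,spot_ids unique identifiers (default: dimnames).
#' @param usage_type `"RUD"` or `"intronic_ratio"`.
#' @return An object of class `UsageMatrix`.
#' @export
UsageMatrix <- function(values, gene_ids = rownames(values),
                        spot_ids = colnames(values),
                        usage_type = c("RUD", "intronic_ratio")) {
  usage_type <- match.arg(usage_type)
  values <- as.matrix(values)
  if (is.null(gene_ids) && nrow(values) == 0) gene_ids <- character(0)
  if (is.null(gene_ids) || is.null(spot_ids))
    stop_data("gene_ids and spot_ids are required")
  if (anyDuplicated(gene_ids)) stop_data("duplicate gene ids")
  if (anyDuplicated(spot_ids)) stop_data("duplicate spot ids")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(spot_ids))
    stop_data("dimension mismatch")
  obs <- values[!is.na(values)]
  if (length(obs) && (min(obs) < 0 || max(obs) > 1))
    stop_data("non-missing usage values must lie in [0, 1]")
  rownames(values) <- gene_ids
  colnames(values) <- spot_ids
  structure(list(values = values, usage_type = usage_type),
            class = "UsageMatrix")
}

#' Missingness mask of a usage matrix
#' @param u a `UsageMatrix`.
#' @return logical matrix, `TRUE` where the usage value is a dropout.
#' @export
usage_missing <- function(u) is.na(u$values)

#' @export
print.UsageMatrix <- function(x, ...) {
  miss <- mean(is.na(x$values))
  cat(sprintf("UsageMatrix (%s): %d genes x %d spots, %.1f%% missing\n",
              x$usage_type, nrow(x$values), ncol(x$values), 100 * miss))
  invisible(x)
}

## ---- readers / writers -----------------------------------------------------

read_count_matrix <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    as.matrix(readMM(path))
  } else {
    as.matrix(read.delim(path, header = FALSE, sep = "\t"))
  }
}

#' Read a poly(A)-site count matrix with sidecar metadata
#'
#' The count matrix may be sparse matrix-market (`.mtx`) or a dense TSV
#' (no header). `sites_path` is a TSV with header columns `site_id`,
#' `chrom`, `strand`, `coord`, `gene`, `region` and one row per matrix row;
#' `spots_path` is a TSV with a `spot_id` column and one row per matrix
#' column. Row/column order follows the metadata files.
#'
#' @param matrix_path,sites_path,spots_path file paths.
#' @return A validated [PolyASiteMatrix()].
#' @export
read_polya_matrix <- function(matrix_path, sites_path, spots_path) {
  counts <- read_count_matrix(matrix_path)
  sites <- read.delim(sites_path, stringsAsFactors = FALSE)
  spots <- read.delim(spots_path, stringsAsFactors = FALSE)
  need <- c("site_id", "chrom", "strand", "coord")
  if (!all(need %in% names(sites)))
    stop_data("sites file must have columns %s", paste(need, collapse = ", "))
  if (!"gene" %in% names(sites)) sites$gene <- NA_character_
  if (!"region" %in% names(sites)) sites$region <- "unassigned"
  if (!"spot_id" %in% names(spots))
    stop_data("spots file must have a spot_id column")
  PolyASiteMatrix(counts, sites, spots$spot_id)
}

#' Read a spot layout table
#'
#' TSV with header columns `spot_id` (or `id`), `x`, `y` and optional
#' `layer`; file order is preserved.
#'
#' @param path file path.
#' @return A [SpotLayout()].
#' @export
read_spot_layout <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("id" %in% names(df) && !"spot_id" %in% names(df))
    names(df)[names(df) == "id"] <- "spot_id"
  if (!all(c("spot_id", "x", "y") %in% names(df)))
    stop_data("layout file must have columns spot_id (or id), x, y")
  SpotLayout(df$spot_id, df$x, df$y,
             layer = if ("layer" %in% names(df)) df$layer else NULL)
}

#' Write / read a spot layout table
#' @param layout a [SpotLayout()].
#' @param path file path.
#' @return `write_spot_layout` returns `path` invisibly.
#' @export
write_spot_layout <- function(layout, path) {
  write.table(as.data.frame(layout), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop spots with too few total reads
#'
#' Spots whose column sum is below `min_total` are removed (the retention
#' threshold is inclusive: a spot with exactly `min_total` reads stays).
#'
#' @param g an unscaled [GeneSpotMatrix()].
#' @param min_total minimum total read count per spot (default 10).
#' @return A filtered `GeneSpotMatrix`.
#' @export
filter_low_count_spots <- function(g, min_total = 10) {
  stopifnot(inherits(g, "GeneSpotMatrix"))
  if (g$scaled) stop_data("filter_low_count_spots needs raw counts")
  keep <- colSums(g$values) >= min_total
  if (!any(keep)) stop_data("all spots removed by min_total = %g", min_total)
  GeneSpotMatrix(g$values[, keep, drop = FALSE], scaled = FALSE)
}

#' Serialize a usage matrix as TSV with an NA sentinel
#'
#' Missing cells are written as the literal token `NA`, never as 0 (0 is a
#' legal usage value); the round-trip is lossless including the mask.
#'
#' @param u a [UsageMatrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_usage_matrix <- function(u, path) {
  stopifnot(inherits(u, "UsageMatrix"))
  df <- as.data.frame(u$values, check.names = FALSE)
  df <- cbind(gene_id = rownames(u$values), df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# usage_type=%s", u$usage_type), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_usage_matrix
#' @export
read_usage_matrix <- function(path) {
  first <- readLines(path, n = 1)
  usage_type <- "RUD"
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    m <- regmatches(first, regexec("usage_type=(\\S+)", first))[[1]]
    if (length(m) == 2) usage_type <- m[2]
  }
  df <- read.delim(path, skip = skip, check.names = FALSE,
                   stringsAsFactors = FALSE)
  genes <- df$gene_id
  vals <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(vals) <- "double"
  UsageMatrix(vals, gene_ids = genes, spot_ids = colnames(vals),
              usage_type = usage_type)
}

#' Write a poly(A)-site matrix as matrix-market plus sidecar TSVs
#' @param pa a [PolyASiteMatrix()].
#' @param matrix_path,sites_path,spots_path output paths (`.mtx` + TSVs).
#' @return `matrix_path`, invisibly.
#' @export
write_polya_matrix <- function(pa, matrix_path, sites_path, spots_path) {
  writeMM(Matrix(pa$counts, sparse = TRUE), matrix_path)
  write.table(pa$sites, sites_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(spot_id = pa$spot_ids), spots_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}
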