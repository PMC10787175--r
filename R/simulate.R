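## Simulator for spatially barcoded ST data with planted layer structure,
## planted APA patterns and controllable dropout.  Gene totals are
## negative-binomial (layer-dependent means for marker genes, flat for APA
## genes, so expression structure and APA structure stay statistically
## separable); APA-gene site counts split the gene total binomially with
## distal probability equal to the layer's true RUD.

#' Simulation specification
#'
#' @param n_spots number of spots (default 200), laid out on a near-square
#'   integer grid.
#' @param layer_geometry `"stripes"` (vertical bands) or
#'   `"concentric_rings"` (rings around the array centre).
#' @param layer_proportions per-layer spot proportions, must sum to 1
#'   (default four equal layers).
#' @param n_genes total genes (default 60).
#' @param n_apa_genes genes carrying two 3' UTR poly(A) sites
#'   (default 30); the rest are single-site genes, some of which act as
#'   layer markers.
#' @param planted_patterns optional matrix (APA genes x layers) of true
#'   per-layer RUD values in \[0, 1\]; by default `pattern_frac` of the
#'   APA genes alternate between `base_rud` and `base_rud + delta_rud`
#'   across layers and the rest are flat at 0.5.
#' @param pattern_frac fraction of APA genes given a planted layer
#'   pattern (default 0.5).
#' @param base_rud,delta_rud low per-layer RUD and planted effect size
#'   (defaults 0.2 and 0.4, the effect range of the robustness
#'   experiments).
#' @param depth mean reads per gene per spot (default 20).
#' @param marker_per_layer,marker_fc layer-marker genes per layer among
#'   the non-APA genes and their fold change (defaults 5 and 4), giving
#'   the expression profile its layer structure.
#' @param dropout_spot_frac fraction of spots (stratified by layer) whose
#'   counts are fully zeroed (default 0).
#' @param dropout_cell_frac fraction of (gene, spot) cells whose site
#'   counts are zeroed (default 0).
#' @param nb_dispersion negative-binomial dispersion (default 0.3;
#'   `size = 1/dispersion`).
#' @param sites_per_apa 2 (default) or 3 3' UTR sites per APA gene (the
#'   three-site mode splits the proximal mass over two sites).
#' @param seed master seed; all stage seeds derive from it.
#' @return An object of class `SimulationSpec`.
#' @export
SimulationSpec <- function(n_spots = 200,
                           layer_geometry = c("stripes", "concentric_rings"),
                           layer_proportions = rep(0.25, 4),
                           n_genes = 60, n_apa_genes = 30,
                           planted_patterns = NULL, pattern_frac = 0.5,
                           base_rud = 0.2, delta_rud = 0.4,
                           depth = 20, marker_per_layer = 5, marker_fc = 4,
                           dropout_spot_frac = 0, dropout_cell_frac = 0,
                           nb_dispersion = 0.3, sites_per_apa = 2, seed = 1) {
  layer_geometry <- match.arg(layer_geometry)
  if (abs(sum(layer_proportions) - 1) > 1e-8)
    stop_config("layer proportions must sum to 1")
  if (dropout_spot_frac < 0 || dropout_spot_frac >= 1 ||
      dropout_cell_frac < 0 || dropout_cell_frac >= 1)
    stop_config("dropout fractions must lie in [0, 1)")
  if (n_apa_genes > n_genes) stop_config("n_apa_genes cannot exceed n_genes")
  if (!sites_per_apa %in% c(2, 3)) stop_config("sites_per_apa must be 2 or 3")
  spec <- list(n_spots = n_spots, layer_geometry = layer_geometry,
               layer_proportions = layer_proportions, n_genes = n_genes,
               n_apa_genes = n_apa_genes, planted_patterns = planted_patterns,
               pattern_frac = pattern_frac, base_rud = base_rud,
               delta_rud = delta_rud, depth = depth,
               marker_per_layer = marker_per_layer, marker_fc = marker_fc,
               dropout_spot_frac = dropout_spot_frac,
               dropout_cell_frac = dropout_cell_frac,
               nb_dispersion = nb_dispersion, sites_per_apa = sites_per_apa,
               seed = as.integer(seed))
  class(spec) <- "SimulationSpec"
  spec
}

## deterministic child seed per stage, kept under 2^31
child_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 131L) %% 2000000011L
}

layer_sizes <- function(n, props) {
  sizes <- diff(round(cumsum(c(0, props)) * n))
  if (any(sizes == 0)) stop_data("a layer would receive 0 spots")
  sizes
}

default_patterns <- function(spec, n_layers) {
  n_pat <- round(spec$pattern_frac * spec$n_apa_genes)
  P <- matrix(0.5, spec$n_apa_genes, n_layers)
  hi <- spec$base_rud + spec$delta_rud
  if (hi > 1) stop_config("base_rud + delta_rud exceeds 1")
  for (i in seq_len(n_pat)) {
    ## each pattern gene is "high" in one layer block, low elsewhere,
    ## cycling through the layers
    hi_layer <- ((i - 1) %% n_layers) + 1
    P[i, ] <- spec$base_rud
    P[i, hi_layer] <- hi
  }
  P
}

#' Simulate a layered ST dataset with planted APA patterns
#'
#' @param spec a [SimulationSpec()].
#' @return An object of class `SimulatedDataset`: list with `pa`
#'   ([PolyASiteMatrix()]), `g` ([GeneSpotMatrix()] of summed site
#'   counts), `layout` ([SpotLayout()] with true layer labels) and `truth`
#'   (data.frame gene x layer of true RUD plus `pattern_flag`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  n <- spec$n_spots
  n_layers <- length(spec$layer_proportions)
  ## --- spot placement and layer assignment -------------------------------
  nx <- ceiling(sqrt(n))
  xy <- cbind(x = (seq_len(n) - 1) %% nx + 1,
              y = (seq_len(n) - 1) %/% nx + 1)
  sizes <- layer_sizes(n, spec$layer_proportions)
  key <- if (spec$layer_geometry == "stripes") {
    order(xy[, "x"], xy[, "y"])
  } else {
    ctr <- colMeans(xy)
    order(sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2), seq_len(n))
  }
  layers <- character(n)
  layers[key] <- rep(paste0("L", seq_len(n_layers)), times = sizes)
  spot_ids <- sprintf("s%03d", seq_len(n))
  layout <- SpotLayout(spot_ids, xy[, "x"], xy[, "y"], layer = layers)
  ## --- gene roles ---------------------------------------------------------
  apa_genes <- sprintf("apa%03d", seq_len(spec$n_apa_genes))
  n_bg <- spec$n_genes - spec$n_apa_genes
  bg_genes <- if (n_bg > 0) sprintf("bg%03d", seq_len(n_bg)) else character(0)
  n_marker <- min(spec$marker_per_layer * n_layers, n_bg)
  marker_layer <- rep(NA_character_, n_bg)
  if (n_marker > 0)
    marker_layer[seq_len(n_marker)] <- rep(paste0("L", seq_len(n_layers)),
                                           length.out = n_marker)
  P <- spec$planted_patterns
  if (is.null(P)) P <- default_patterns(spec, n_layers)
  if (nrow(P) != spec$n_apa_genes || ncol(P) != n_layers)
    stop_config("planted_patterns must be n_apa_genes x n_layers")
  if (any(P < 0 | P > 1)) stop_config("true RUD values must lie in [0, 1]")
  layer_idx <- match(layers, paste0("L", seq_len(n_layers)))
  ## --- counts -------------------------------------------------------------
  size <- 1 / spec$nb_dispersion
  set.seed(child_seed(spec$seed, 1L))
  rows <- list(); meta <- list(); coord <- 1000L
  nb <- function(mu) stats::rnbinom(n, mu = mu, size = size)
  for (gi in seq_along(apa_genes)) {
    total <- nb(spec$depth)
    rud <- P[gi, layer_idx]
    distal <- stats::rbinom(n, total, rud)
    proximal <- total - distal
    if (spec$sites_per_apa == 3) {
      p1 <- stats::rbinom(n, proximal, 0.5)
      p2 <- proximal - p1
      rows <- c(rows, list(p1, p2, distal))
      meta <- c(meta, list(
        list(paste0(apa_genes[gi], ":p1"), coord, apa_genes[gi]),
        list(paste0(apa_genes[gi], ":p2"), coord + 100L, apa_genes[gi]),
        list(paste0(apa_genes[gi], ":d"), coord + 200L, apa_genes[gi])))
      coord <- coord + 1000L
    } else {
      rows <- c(rows, list(proximal, distal))
      meta <- c(meta, list(
        list(paste0(apa_genes[gi], ":p"), coord, apa_genes[gi]),
        list(paste0(apa_genes[gi], ":d"), coord + 100L, apa_genes[gi])))
      coord <- coord + 1000L
    }
  }
  for (bi in seq_along(bg_genes)) {
    mu <- rep(spec$depth, n)
    if (!is.na(marker_layer[bi]))
      mu[layers == marker_layer[bi]] <- spec$depth * spec$marker_fc
    rows <- c(rows, list(nb(mu)))
    meta <- c(meta, list(list(paste0(bg_genes[bi], ":s"), coord, bg_genes[bi])))
    coord <- coord + 1000L
  }
  counts <- do.call(rbind, rows)
  site_gene <- vapply(meta, function(m) m[[3]], character(1))
  sites <- data.frame(site_id = vapply(meta, function(m) m[[1]], character(1)),
                      chrom = "chr1", strand = "+",
                      coord = vapply(meta, function(m) m[[2]], integer(1)),
                      gene = site_gene,
                      region = "3UTR", stringsAsFactors = FALSE)
  ## --- dropout ------------------------------------------------------------
  if (spec$dropout_spot_frac > 0) {
    set.seed(child_seed(spec$seed, 2L))
    drop <- unlist(lapply(unique(layers), function(L) {
      in_l <- which(layers == L)
      sample(in_l, floor(spec$dropout_spot_frac * length(in_l)))
    }))
    counts[, drop] <- 0
  }
  if (spec$dropout_cell_frac > 0) {
    set.seed(child_seed(spec$seed, 3L))
    all_genes <- c(apa_genes, bg_genes)
    cells <- which(matrix(TRUE, length(all_genes), n))
    sel <- sample(cells, floor(spec$dropout_cell_frac * length(cells)))
    gi <- (sel - 1) %% length(all_genes) + 1
    sj <- (sel - 1) %/% length(all_genes) + 1
    for (ci in seq_along(sel))
      counts[site_gene == all_genes[gi[ci]], sj[ci]] <- 0
  }
  pa <- PolyASiteMatrix(counts, sites, spot_ids)
  truth <- data.frame(gene = rep(apa_genes, each = n_layers),
                      layer = rep(paste0("L", seq_len(n_layers)),
                                  spec$n_apa_genes),
                      true_rud = as.numeric(t(P)),
                      pattern_flag = rep(apply(P, 1, function(r)
                        max(r) - min(r) > 1e-12), each = n_layers),
                      stringsAsFactors = FALSE)
  structure(list(pa = pa, g = gene_level_counts(pa), layout = layout,
                 truth = truth, spec = spec),
            class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf("SimulatedDataset: %d spots, %d genes (%d APA), %d layers\n",
              x$spec$n_spots, x$spec$n_genes, x$spec$n_apa_genes,
              length(x$spec$layer_proportions)))
  invisible(x)
}

#' True per-spot usage matrix implied by the planted patterns
#' @param ds a `SimulatedDataset`.
#' @return A dense [UsageMatrix()] of the planted RUD values.
#' @export
truth_usage <- function(ds) {
  stopifnot(inherits(ds, "SimulatedDataset"))
  genes <- unique(ds$truth$gene)
  P <- matrix(ds$truth$true_rud, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, unique(ds$truth$layer)))
  vals <- P[, ds$layout$layer, drop = FALSE]
  colnames(vals) <- ds$layout$spot_id
  UsageMatrix(vals, usage_type = "RUD")
}

#' Mask whole spots in a usage matrix (dropout-spot experiment)
#'
#' Per layer, `floor(frac * layer_size)` spots are selected and all their
#' usage entries set missing, so layer proportions are preserved.
#'
#' @param u a [UsageMatrix()].
#' @param layout a [SpotLayout()] with layer labels (same spot order).
#' @param frac fraction of spots to mask per layer, in \[0, 0.9\].
#' @param seed RNG seed.
#' @return list with `usage` (masked matrix) and `masked_spots`
#'   (character vector of spot ids).
#' @export
mask_spots <- function(u, layout, frac, seed = 1) {
  stopifnot(inherits(u, "UsageMatrix"), frac >= 0, frac <= 0.9)
  if (!has_layers(layout)) stop_data("mask_spots needs layer labels")
  if (frac == 0) return(list(usage = u, masked_spots = character(0)))
  set.seed(child_seed(seed, 4L))
  masked <- unlist(lapply(unique(layout$layer), function(L) {
    ids <- layout$spot_id[layout$layer == L]
    n_mask <- floor(frac * length(ids))
    if (length(ids) - n_mask < 2)
      stop_data("masking %g of layer %s leaves < 2 observed spots", frac, L)
    sample(ids, n_mask)
  }))
  vals <- u$values
  vals[, masked] <- NA_real_
  list(usage = UsageMatrix(vals, usage_type = u$usage_type),
       masked_spots = masked)
}

#' Mask random observed entries of a usage matrix (extra-dropout experiment)
#'
#' @param u a [UsageMatrix()].
#' @param frac fraction of currently observed entries to set missing,
#'   in \[0, 0.5\].
#' @param seed RNG seed.
#' @return The masked `UsageMatrix`.
#' @export
mask_entries <- function(u, frac, seed = 1) {
  stopifnot(inherits(u, "UsageMatrix"), frac >= 0, frac <= 0.5)
  if (frac == 0) return(u)
  obs <- which(!is.na(u$values))
  set.seed(child_seed(seed, 5L))
  sel <- sample(obs, floor(frac * length(obs)))
  vals <- u$values
  vals[sel] <- NA_real_
  UsageMatrix(vals, usage_type = u$usage_type)
}

#' Stratified spot subsample of a simulated dataset
#'
#' @param ds a `SimulatedDataset`.
#' @param frac fraction of spots to keep per layer, in (0, 1\].
#' @param seed RNG seed.
#' @return The subsampled `SimulatedDataset`.
#' @export
subsample_spots <- function(ds, frac, seed = 1) {
  stopifnot(inherits(ds, "SimulatedDataset"), frac > 0, frac <= 1)
  if (frac == 1) return(ds)
  set.seed(child_seed(seed, 6L))
  keep <- unlist(lapply(unique(ds$layout$layer), function(L) {
    ids <- ds$layout$spot_id[ds$layout$layer == L]
    n_keep <- max(1, round(frac * length(ids)))
    if (n_keep == 0) stop_data("layer %s empty after subsampling", L)
    sort(sample(ids, n_keep))
  }))
  keep <- ds$layout$spot_id[ds$layout$spot_id %in% keep]  # original order
  sel <- match(keep, ds$pa$spot_ids)
  pa <- PolyASiteMatrix(ds$pa$counts[, sel, drop = FALSE], ds$pa$sites, keep)
  li <- match(keep, ds$layout$spot_id)
  layout <- SpotLayout(keep, ds$layout$x[li], ds$layout$y[li],
                       layer = ds$layout$layer[li])
  structure(list(pa = pa, g = gene_level_counts(pa), layout = layout,
                 truth = ds$truth, spec = ds$spec),
            class = "SimulatedDataset")
}

#' Sensitivity of detection against a reference gene set
#'
#' TP/(TP+FN): the fraction of reference genes that were detected. Only
#' true positives and false negatives are computable when the reference
#' lists true instances only.
#'
#' @param reference_genes non-empty character vector of true genes.
#' @param detected character vector of detected genes.
#' @return sensitivity in \[0, 1\].
#' @export
sensitivity <- function(reference_genes, detected) {
  if (length(reference_genes) == 0) stop_data("empty reference set")
  length(intersect(reference_genes, detected)) / length(unique(reference_genes))
}

#' Silver-standard gene set from replicate results
#'
#' Genes present in at least `min_support` of the replicate gene sets.
#'
#' @param replicate_results list (>= 2) of character vectors.
#' @param min_support minimum number of supporting replicates (default 2).
#' @return character vector of consensus genes.
#' @export
silver_standard <- function(replicate_results, min_support = 2) {
  if (length(replicate_results) < 2)
    stop_data("need at least 2 replicate result sets")
  tab <- table(unlist(lapply(replicate_results, unique)))
  sort(names(tab[tab >= min_support]))
}
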