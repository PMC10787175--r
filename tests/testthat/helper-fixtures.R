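# Shared in-code fixtures. Small objects are built by hand; the standard
# simulation is memoised so the suite pays for it once.

# 2 genes x 3 spots; gene gA has proximal/distal 3'UTR sites on "+",
# gene gB mirrors it on "-" (distal = smallest coordinate)
toy_pa <- function() {
  counts <- rbind(
    c(3, 0, 2),   # gA proximal (coord 1100)
    c(1, 0, 2),   # gA distal   (coord 1200)
    c(2, 5, 0),   # gB distal   (coord 2100, "-" strand)
    c(3, 5, 0))   # gB proximal (coord 2200, "-" strand)
  sites <- data.frame(
    site_id = c("gA:p", "gA:d", "gB:d", "gB:p"),
    chrom = "chr1",
    strand = c("+", "+", "-", "-"),
    coord = c(1100L, 1200L, 2100L, 2200L),
    gene = c("gA", "gA", "gB", "gB"),
    region = "3UTR",
    stringsAsFactors = FALSE)
  PolyASiteMatrix(counts, sites, c("s1", "s2", "s3"))
}

toy_layout <- function(n = 3) {
  SpotLayout(paste0("s", seq_len(n)), x = seq_len(n), y = rep(1, n))
}

# standard recovery simulation used across tests: 200 spots, 4 layers,
# planted delta-RUD 0.4, depth 20 (the stated world of the acceptance runs)
std_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(SimulationSpec(
        n_spots = 200, n_genes = 60, n_apa_genes = 30,
        depth = 20, delta_rud = 0.4, seed = 42))
    cache
  }
})

rmse <- function(est, truth) sqrt(mean((est - truth)^2, na.rm = TRUE))

# deterministic little usage matrix with NAs
toy_usage <- function() {
  v <- rbind(g1 = c(0.2, NA, 0.8, 0.6),
             g2 = c(NA, 0.5, NA, 0.1))
  colnames(v) <- paste0("s", 1:4)
  UsageMatrix(v, usage_type = "RUD")
}

# ranking where every spot's neighbours are simply the other spots in
# index order (profiles equally spaced on a line)
line_ranking <- function(m) {
  g <- GeneSpotMatrix(matrix(seq_len(m), nrow = 1,
                             dimnames = list("g", paste0("s", seq_len(m)))) ,
                      scaled = FALSE)
  build_ranking(scale_genes(g))
}
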