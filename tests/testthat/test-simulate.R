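test_that("simulate_dataset honours layer proportions and reproducibility", {
  spec <- SimulationSpec(n_spots = 100, layer_proportions = c(0.5, 0.5),
                         n_genes = 20, n_apa_genes = 10, seed = 7)
  ds <- simulate_dataset(spec)
  expect_equal(unname(table(ds$layout$layer)), c(50, 50), ignore_attr = TRUE)
  # shared spot ids across the three containers
  expect_identical(ds$pa$spot_ids, ds$layout$spot_id)
  expect_identical(colnames(ds$g$values), ds$layout$spot_id)
  # truth covers exactly the planted APA genes
  expect_setequal(unique(ds$truth$gene), sprintf("apa%03d", 1:10))
  # same seed -> identical dataset; different seed -> different counts
  ds2 <- simulate_dataset(spec)
  expect_identical(ds$pa$counts, ds2$pa$counts)
  ds3 <- simulate_dataset(SimulationSpec(n_spots = 100,
                                         layer_proportions = c(0.5, 0.5),
                                         n_genes = 20, n_apa_genes = 10,
                                         seed = 8))
  expect_false(identical(ds$pa$counts, ds3$pa$counts))
  # infeasible spec: a layer with zero spots
  expect_error(simulate_dataset(SimulationSpec(n_spots = 10,
    layer_proportions = c(0.99, 0.01))), "0 spots")
})

test_that("empirical per-layer RUD converges to the planted truth at depth 1e4", {
  spec <- SimulationSpec(n_spots = 60, n_genes = 10, n_apa_genes = 6,
                         depth = 1e4, nb_dispersion = 0.05, seed = 11)
  ds <- simulate_dataset(spec)
  u <- compute_rud(ds$pa)
  for (g in c("apa001", "apa002")) {
    tr <- ds$truth[ds$truth$gene == g, ]
    for (L in tr$layer) {
      est <- mean(u$values[g, ds$layout$layer == L], na.rm = TRUE)
      expect_equal(est, tr$true_rud[tr$layer == L], tolerance = 0.02,
                   label = paste(g, L))
    }
  }
})

test_that("a planted flat gene shows no significant spatial autocorrelation", {
  # calibration: the flat gene's empirical RUD should clear alpha = 0.05
  # in at least 90% of seeds
  hits <- vapply(1:20, function(s) {
    ds <- simulate_dataset(SimulationSpec(n_spots = 80, n_genes = 12,
                                          n_apa_genes = 8, depth = 30,
                                          seed = 100 + s))
    flat <- unique(ds$truth$gene[!ds$truth$pattern_flag])[1]
    u <- compute_rud(ds$pa)
    v <- u$values[flat, ]
    v[is.na(v)] <- 0
    morans_i(v, ds$layout, n_perm = 99, seed = s)$p_perm < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("mask_spots stratifies by layer and is deterministic", {
  ds <- std_sim()
  u <- compute_rud(ds$pa)
  mk <- mask_spots(u, ds$layout, 0.5, seed = 3)
  per_layer <- table(ds$layout$layer[match(mk$masked_spots, ds$layout$spot_id)])
  expect_true(all(per_layer == 25))          # floor(0.5 * 50) per layer
  expect_true(all(is.na(mk$usage$values[, mk$masked_spots])))
  # determinism and identity at frac 0
  mk2 <- mask_spots(u, ds$layout, 0.5, seed = 3)
  expect_identical(sort(mk$masked_spots), sort(mk2$masked_spots))
  expect_identical(mask_spots(u, ds$layout, 0)$usage$values, u$values)
  # leaving < 2 observed spots in a layer errors
  small <- SimulationSpec(n_spots = 16, layer_proportions = c(0.25, 0.75),
                          n_genes = 8, n_apa_genes = 4, seed = 2)
  ds_s <- simulate_dataset(small)
  u_s <- compute_rud(ds_s$pa)
  expect_error(mask_spots(u_s, ds_s$layout, 0.9, seed = 1), "< 2 observed")
})

test_that("mask_entries masks the requested share of observed cells only", {
  u <- std_sim() |> (\(d) compute_rud(d$pa))()
  n_obs <- sum(!is.na(u$values))
  m <- mask_entries(u, 0.3, seed = 5)
  expect_equal(sum(!is.na(u$values)) - sum(!is.na(m$values)),
               floor(0.3 * n_obs))
  # masked set is disjoint from previously missing cells
  newly <- is.na(m$values) & !is.na(u$values)
  expect_equal(sum(newly), floor(0.3 * n_obs))
  expect_identical(mask_entries(u, 0)$values, u$values)
  expect_identical(mask_entries(u, 0.2, seed = 9)$values,
                   mask_entries(u, 0.2, seed = 9)$values)
})

test_that("subsample_spots keeps layer proportions and container consistency", {
  ds <- std_sim()
  sub <- subsample_spots(ds, 0.5, seed = 4)
  expect_equal(unname(table(sub$layout$layer)), rep(25, 4), ignore_attr = TRUE)
  expect_identical(sub$pa$spot_ids, sub$layout$spot_id)
  expect_identical(colnames(sub$g$values), sub$layout$spot_id)
  expect_identical(subsample_spots(ds, 1), ds)
  expect_identical(subsample_spots(ds, 0.5, seed = 4)$layout$spot_id,
                   sub$layout$spot_id)
})

test_that("sensitivity and silver_standard match hand-computed values", {
  expect_equal(sensitivity(c("a", "b", "c", "d"), c("a", "b", "c", "x")), 0.75)
  expect_equal(sensitivity(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(sensitivity(c("a", "b"), character(0)), 0)
  expect_error(sensitivity(character(0), "a"), "empty reference")
  sets <- list(c("a", "b"), c("b", "c"), "a")
  expect_identical(silver_standard(sets, 2), c("a", "b"))
  expect_identical(silver_standard(sets, 1), c("a", "b", "c"))
  expect_identical(silver_standard(sets, 4), character(0))
  expect_error(silver_standard(list("a")), "2 replicate")
})

test_that("empirical dropout rate tracks the cell-level dropout setting", {
  spec <- SimulationSpec(n_spots = 150, n_genes = 40, n_apa_genes = 20,
                         depth = 50, dropout_cell_frac = 0.4, seed = 13)
  ds <- simulate_dataset(spec)
  u <- compute_rud(ds$pa)
  # at depth 50 nearly all non-dropped cells are observed, so the missing
  # share approximates the planted cell dropout within 2 points
  expect_equal(mean(is.na(u$values)), 0.4, tolerance = 0.05)
})
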