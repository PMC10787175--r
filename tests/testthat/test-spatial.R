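# shared small usage fixture with a planted two-group difference
mk_groups_usage <- function(n_per = 10, n_null = 20, seed = 2) {
  set.seed(seed)
  labels <- rep(c("A", "B"), each = n_per)
  vals <- matrix(runif((n_null + 1) * 2 * n_per, 0.3, 0.7),
                 n_null + 1, 2 * n_per)
  vals[1, labels == "A"] <- 0.9
  vals[1, labels == "B"] <- 0.1
  rownames(vals) <- c("planted", paste0("null", seq_len(n_null)))
  colnames(vals) <- paste0("s", seq_len(2 * n_per))
  list(u = UsageMatrix(vals), labels = labels)
}

test_that("detect_deapa applies rank-sum + effect filters", {
  f <- mk_groups_usage()
  res <- detect_deapa(f$u, f$labels, "A", "B")
  expect_identical(res$gene_id, "planted")
  expect_equal(res$category, "DEAPA")
  # exact two-sided rank-sum p for complete separation (10 vs 10) via the
  # normal approximation used by wilcox.test on this data
  wt <- suppressWarnings(stats::wilcox.test(rep(0.9, 10), rep(0.1, 10),
                                            exact = FALSE))
  expect_equal(res$p_raw, wt$p.value)
  expect_equal(res$p_adj, min(1, res$p_raw * 21))   # Bonferroni over 21 genes
  expect_equal(res$log2fc, log2(0.91 / 0.11))
  # identical distributions -> nothing reported
  null_u <- UsageMatrix(f$u$values[-1, , drop = FALSE])
  expect_equal(nrow(detect_deapa(null_u, f$labels, "A", "B")), 0)
  # effect-size filter: mean ratio 1.2 is log2fc ~ 0.26 < 0.5
  v <- rbind(g = c(rep(0.6, 10), rep(0.5, 10)))
  colnames(v) <- paste0("s", 1:20)
  expect_equal(nrow(detect_deapa(UsageMatrix(v), f$labels, "A", "B")), 0)
  expect_error(detect_deapa(f$u, f$labels, "A", "missing"), "2 spots")
})

test_that("detect_deapa(A,B) and detect_deapa(B,A) mirror with negated log2fc", {
  f <- mk_groups_usage(seed = 5)
  ab <- detect_deapa(f$u, f$labels, "A", "B")
  ba <- detect_deapa(f$u, f$labels, "B", "A")
  expect_setequal(ab$gene_id, ba$gene_id)
  expect_equal(ab$log2fc, -ba$log2fc[match(ab$gene_id, ba$gene_id)])
})

test_that("detect_lsapa reports the planted layer and only that layer", {
  set.seed(8)
  labels <- rep(c("L1", "L2", "L3"), each = 8)
  vals <- matrix(runif(10 * 24, 0.4, 0.6), 10, 24,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:24)))
  vals["g1", labels == "L2"] <- 0.95
  res <- detect_lsapa(UsageMatrix(vals), labels)
  expect_true("g1" %in% res$gene_id)
  expect_identical(unique(res$contrast[res$gene_id == "g1"]), "L2 vs rest")
  # a constant gene is never reported
  vals["g2", ] <- 0.5
  res2 <- detect_lsapa(UsageMatrix(vals), labels)
  expect_false("g2" %in% res2$gene_id)
  # contrast count: at most one contrast per layer per gene
  expect_lte(max(table(res2$gene_id)), 3)
})

test_that("usage_to_counts maps [0,1] to {1..10} monotonically in both modes", {
  v <- matrix(c(0, 0.5, 1), 1, 3,
              dimnames = list("g", paste0("s", 1:3)))
  rud <- usage_to_counts(UsageMatrix(v, usage_type = "RUD"))
  expect_equal(unname(rud$values[1, ]), c(1, round(10^0.5), 10))
  expect_equal(round(10^0.5), 3)
  intr <- usage_to_counts(UsageMatrix(v, usage_type = "intronic_ratio"))
  expect_equal(unname(intr$values[1, ]), c(1, 3, 10))
  # monotone over a grid
  grid <- matrix(seq(0, 1, by = 0.01), 1,
                 dimnames = list("g", paste0("s", 1:101)))
  out <- usage_to_counts(UsageMatrix(grid, usage_type = "RUD"))$values[1, ]
  expect_true(all(diff(out) >= 0))
  v[1, 2] <- NA
  expect_error(usage_to_counts(UsageMatrix(v)), "fully imputed")
})

test_that("built-in SVAPA detector recovers a planted smooth pattern", {
  ds <- std_sim()
  u <- compute_rud(ds$pa)
  rk <- build_ranking(scale_genes(ds$g))
  imp <- impute(u, rk, ImputationConfig(k = 10))
  res <- detect_svapa_builtin(imp, ds$layout, n_perm = 99, seed = 3)
  planted <- unique(ds$truth$gene[ds$truth$pattern_flag])
  flat <- setdiff(unique(ds$truth$gene), planted)
  expect_gt(sensitivity(planted, res$gene_id), 0.8)
  expect_true(all(res$moran_i[res$gene_id %in% planted] > 0))
  # flat genes are mostly not called
  expect_lt(length(intersect(flat, res$gene_id)) / length(flat), 0.3)
})

test_that("import_svapa handles p_adj, p_raw-only and empty files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = c("a", "b"), p_adj = c(0.01, 0.2)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- import_svapa(path, fdr = 0.05)
  expect_identical(res$gene_id, "a")
  # p_raw only: BH on import, provenance flagged
  write.table(data.frame(gene = c("a", "b", "c"),
                         p_raw = c(0.001, 0.5, 0.9)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  res2 <- import_svapa(path, fdr = 0.05)
  expect_identical(res2$gene_id, "a")
  expect_match(res2$contrast, "BH on import")
  expect_equal(res2$p_adj, 0.003)
  # empty file -> empty result; missing columns -> format error
  write.table(data.frame(gene = character(0), p_adj = numeric(0)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(import_svapa(path)), 0)
  write.table(data.frame(id = "a", p = 0.1), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(import_svapa(path), "gene")
})

test_that("combine_gene_sets unions with correct membership flags", {
  mk <- function(g) if (length(g)) data.frame(gene_id = g) else NULL
  out <- combine_gene_sets(mk(c("a", "b")), mk(c("b", "c")), mk("c"))
  expect_identical(out$gene_id, c("a", "b", "c"))
  expect_equal(out$deapa, c(TRUE, TRUE, FALSE))
  expect_equal(out$lsapa, c(FALSE, TRUE, TRUE))
  expect_equal(out$svapa, c(FALSE, FALSE, TRUE))
  expect_equal(nrow(combine_gene_sets(NULL, NULL, NULL)), 0)
  all3 <- combine_gene_sets(mk("x"), mk("x"), mk("x"))
  expect_true(all(unlist(all3[1, c("deapa", "lsapa", "svapa")])))
})
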