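test_that("scale_genes centres and standardizes with the sample-sd convention", {
  g <- GeneSpotMatrix(rbind(a = c(1, 2, 3), b = c(5, 5, 5)),
                      spot_ids = paste0("s", 1:3))
  s <- scale_genes(g)
  expect_true(s$scaled)
  expect_equal(unname(s$values["a", ]), c(-1, 0, 1))     # sample sd = 1
  expect_equal(unname(s$values["b", ]), c(0, 0, 0))      # zero-variance rule
  expect_error(scale_genes(s), "already scaled")
})

test_that("build_ranking computes Euclidean distances and ascending ranks", {
  g <- GeneSpotMatrix(rbind(c(0, 3), c(0, 4)),
                      gene_ids = c("g1", "g2"), spot_ids = c("a", "b"),
                      scaled = TRUE)
  r <- build_ranking(g)
  expect_equal(r$distance["a", "b"], 5)                 # 3-4-5 triangle
  expect_equal(unname(diag(r$distance)), c(0, 0))
  expect_true(isSymmetric(r$distance))

  # identical profiles -> distance 0, ranked first (tie-break by index)
  g3 <- GeneSpotMatrix(rbind(c(1, 1, 9)), gene_ids = "g",
                       spot_ids = c("a", "b", "c"), scaled = TRUE)
  r3 <- build_ranking(g3)
  expect_equal(r3$distance["a", "b"], 0)
  expect_equal(unname(r3$ranking[1, 1]), 2L)

  # brute-force argsort oracle on random spots
  set.seed(11)
  X <- matrix(rnorm(40), 8, 5)
  gs <- GeneSpotMatrix(X, gene_ids = paste0("g", 1:8),
                       spot_ids = paste0("s", 1:5), scaled = TRUE)
  rr <- build_ranking(gs)
  for (i in 1:5) {
    d <- sqrt(colSums((X - X[, i])^2))
    expect_equal(rr$ranking[i, ], setdiff(order(d, 1:5), i),
                 label = paste("row", i))
  }
  expect_error(build_ranking(GeneSpotMatrix(matrix(1, 1, 1),
                                            gene_ids = "g", spot_ids = "s",
                                            scaled = TRUE)), "2 spots")
})

test_that("impute averages non-zero donors and excludes zero/missing ones", {
  rk <- line_ranking(4)
  # spot s2 is missing for g1; neighbours under k=2 are s1 and s3
  v <- rbind(g1 = c(0.8, NA, 0.2, 0.5))
  colnames(v) <- paste0("s", 1:4)
  u <- impute(UsageMatrix(v), rk, ImputationConfig(k = 2))
  expect_equal(u$values["g1", "s2"], 0.5)
  # a zero neighbour is excluded from the donor set (L = 1)
  v2 <- rbind(g1 = c(0, NA, 0.2, 0.5))
  colnames(v2) <- paste0("s", 1:4)
  u2 <- impute(UsageMatrix(v2), rk, ImputationConfig(k = 2))
  expect_equal(u2$values["g1", "s2"], 0.2)
  # k >= spot count is a config error
  expect_error(impute(UsageMatrix(v), rk, ImputationConfig(k = 4)),
               "smaller than the number of spots")
})

test_that("iteration propagates along a chain (two-pass hand trace)", {
  # chain a-b-c: only c observed (0.6); k = 1 so a's neighbour is b and
  # b's neighbour is c; iteration 1 fills b, iteration 2 fills a
  g <- GeneSpotMatrix(matrix(c(0, 1.4, 2), 1,
                             dimnames = list("g", c("a", "b", "c"))),
                      scaled = TRUE)
  rk <- build_ranking(g)
  v <- matrix(c(NA, NA, 0.6), 1, dimnames = list("g1", c("a", "b", "c")))
  u1 <- impute(UsageMatrix(v), rk, ImputationConfig(k = 1, max_iter = 1,
                                                    fill_residual_zero = FALSE))
  expect_equal(u1$values["g1", "b"], 0.6)
  expect_true(is.na(u1$values["g1", "a"]))     # needs the second pass
  u2 <- impute(UsageMatrix(v), rk, ImputationConfig(k = 1, max_iter = 10))
  expect_equal(unname(u2$values["g1", ]), c(0.6, 0.6, 0.6))
})

test_that("observed entries are fixed points; residual fill and bounds hold", {
  set.seed(5)
  m <- 12
  rk <- line_ranking(m)
  v <- matrix(runif(5 * m), 5, m,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:m)))
  v[sample(length(v), 25)] <- NA
  u0 <- UsageMatrix(v)
  u1 <- impute(u0, rk, ImputationConfig(k = 4))
  obs <- !is.na(v)
  expect_identical(u1$values[obs], v[obs])     # bit-identical observed cells
  expect_false(anyNA(u1$values))
  # imputed values stay inside the gene's observed non-zero range
  for (g in rownames(v)) {
    donors <- v[g, ][!is.na(v[g, ]) & v[g, ] != 0]
    imp <- u1$values[g, is.na(v[g, ])]
    imp <- imp[imp != 0]   # residual zero-fill is exempt
    if (length(imp) > 0)
      expect_true(all(imp >= min(donors) - 1e-12 & imp <= max(donors) + 1e-12))
  }
})

test_that("k = m-1 with one iteration equals the gene's global non-zero mean", {
  set.seed(9)
  m <- 10
  rk <- line_ranking(m)
  v <- matrix(round(runif(m), 2), 1, m,
              dimnames = list("g", paste0("s", 1:m)))
  v[1, c(3, 7)] <- NA
  v[1, 5] <- 0
  u <- impute(UsageMatrix(v), rk, ImputationConfig(k = m - 1, max_iter = 1))
  expected <- mean(v[1, -c(3, 7)][v[1, -c(3, 7)] != 0])
  expect_equal(unname(u$values[1, 3]), expected)
  expect_equal(unname(u$values[1, 7]), expected)
})

test_that("imputation is equivariant under spot permutation", {
  set.seed(21)
  m <- 9
  X <- matrix(rnorm(4 * m), 4, m, dimnames = list(paste0("g", 1:4),
                                                  paste0("s", 1:m)))
  g <- GeneSpotMatrix(abs(X), scaled = FALSE)
  v <- matrix(runif(3 * m), 3, m, dimnames = list(paste0("u", 1:3),
                                                  paste0("s", 1:m)))
  v[sample(length(v), 8)] <- NA
  u <- UsageMatrix(v)
  imp <- impute(u, build_ranking(scale_genes(g)), ImputationConfig(k = 3))
  perm <- sample(m)
  g_p <- GeneSpotMatrix(abs(X)[, perm], scaled = FALSE)
  u_p <- UsageMatrix(v[, perm])
  imp_p <- impute(u_p, build_ranking(scale_genes(g_p)), ImputationConfig(k = 3))
  expect_equal(imp_p$values, imp$values[, perm])
})

test_that("missing set shrinks weakly and evaluate_imputation is consistent", {
  ds <- std_sim()
  u <- compute_rud(ds$pa)
  rk <- build_ranking(scale_genes(ds$g))
  n_miss <- sum(is.na(u$values))
  u1 <- impute(u, rk, ImputationConfig(k = 10, max_iter = 1,
                                       fill_residual_zero = FALSE))
  expect_lte(sum(is.na(u1$values)), n_miss)
  ev <- evaluate_imputation(u, u, ds$layout)
  expect_equal(ev$raw$panel, ev$imputed$panel)   # identical input, identical panel
  expect_equal(ev$raw$layer_cor, ev$imputed$layer_cor)
  expect_error(evaluate_imputation(u, u, toy_layout(200)), "layer labels")
})
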