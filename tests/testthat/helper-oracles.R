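# Independent brute-force oracles. Deliberately written from first
# principles (explicit loops over pairs / points) so they share no code
# path with the package implementations they verify.

# pair-counting external metrics by explicit enumeration of all n(n-1)/2 pairs
oracle_pair_metrics <- function(pred, ref) {
  n <- length(pred)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_p <- pred[i] == pred[j]
      same_r <- ref[i] == ref[j]
      if (same_p && same_r) tp <- tp + 1
      else if (same_p && !same_r) fp <- fp + 1
      else if (!same_p && same_r) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  total <- tp + fp + fn + tn
  # adjusted Rand via pair counts: index = tp, expected = rowpairs*colpairs/total
  rowpairs <- tp + fp
  colpairs <- tp + fn
  expected <- rowpairs * colpairs / total
  maxidx <- (rowpairs + colpairs) / 2
  ari <- if (maxidx == expected) 1 else (tp - expected) / (maxidx - expected)
  jac <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  list(ari = ari, jaccard = jac)
}

oracle_nmi_purity <- function(pred, ref) {
  n <- length(pred)
  up <- unique(pred); ur <- unique(ref)
  mi <- 0
  for (a in up) for (b in ur) {
    nab <- sum(pred == a & ref == b)
    if (nab > 0)
      mi <- mi + (nab / n) * log((nab / n) / ((sum(pred == a) / n) * (sum(ref == b) / n)))
  }
  H <- function(lab) {
    h <- 0
    for (a in unique(lab)) { p <- sum(lab == a) / n; h <- h - p * log(p) }
    h
  }
  denom <- (H(pred) + H(ref)) / 2
  nmi <- if (denom == 0) 1 else mi / denom
  pur <- 0
  for (a in up) {
    best <- 0
    for (b in ur) best <- max(best, sum(pred == a & ref == b))
    pur <- pur + best
  }
  list(nmi = nmi, purity = pur / n)
}

# direct-formula internal metrics, transcribed independently
oracle_internal <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)  # list lookups below are by name
  labs <- unique(labels)
  k <- length(labs)
  n <- nrow(X)
  d <- function(a, b) sqrt(sum((a - b)^2))
  centro <- lapply(labs, function(L) colMeans(X[labels == L, , drop = FALSE]))
  names(centro) <- labs
  # DBI
  S <- sapply(labs, function(L) {
    pts <- X[labels == L, , drop = FALSE]
    mean(sapply(seq_len(nrow(pts)), function(r) d(pts[r, ], centro[[L]])))
  })
  names(S) <- labs
  dbi <- mean(sapply(labs, function(Li) {
    max(sapply(setdiff(labs, Li), function(Lj)
      (S[[Li]] + S[[Lj]]) / d(centro[[Li]], centro[[Lj]])))
  }))
  # CH
  gmean <- colMeans(X)
  B <- sum(sapply(labs, function(L) sum(labels == L) * sum((centro[[L]] - gmean)^2)))
  W <- sum(sapply(seq_len(n), function(i) sum((X[i, ] - centro[[labels[i]]])^2)))
  ch <- (B / (k - 1)) / (W / (n - k))
  # silhouette
  sil <- mean(sapply(seq_len(n), function(i) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) return(0)
    a <- mean(sapply(own, function(j) d(X[i, ], X[j, ])))
    b <- min(sapply(setdiff(labs, labels[i]), function(L)
      mean(sapply(which(labels == L), function(j) d(X[i, ], X[j, ])))))
    (b - a) / max(a, b)
  }))
  # Dunn
  inter <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (labels[i] != labels[j]) inter <- min(inter, d(X[i, ], X[j, ]))
  intra <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (labels[i] == labels[j]) intra <- max(intra, d(X[i, ], X[j, ]))
  list(dbi = dbi, ch = ch, silhouette = sil, dunn = inter / intra)
}

# O(n^2) double-loop Moran's I
oracle_moran <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * z[i] * z[j]
    s0 <- s0 + W[i, j]
  }
  (n / s0) * num / sum(z^2)
}

# all labelings of n points over at most q labels (first point fixed to
# label 1 is NOT applied: metrics must be invariant, enumeration is cheap)
all_labelings <- function(n, q) {
  grid <- do.call(expand.grid, rep(list(seq_len(q)), n))
  as.matrix(grid)
}
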