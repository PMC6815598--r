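# Shared fixtures and independent oracles.

# 7-gene absolute-correlation worked example and its expected adjacency at
# r0 = 0.35 (the g2-g3 entry 0.36 sits just above the threshold).
example_correlation_7 <- function() {
  r <- matrix(c(
    1,    0.59, 0.19, 0.45, 0.1,  0.24, 0.67,
    0.59, 1,    0.36, 0.3,  0.11, 0.07, 0.66,
    0.19, 0.36, 1,    0.31, 0.24, 0.06, 0.29,
    0.45, 0.3,  0.31, 1,    0.49, 0.81, 0.12,
    0.1,  0.11, 0.24, 0.49, 1,    0.72, 0.66,
    0.24, 0.07, 0.06, 0.81, 0.72, 1,    0.57,
    0.67, 0.66, 0.29, 0.12, 0.66, 0.57, 1), 7, 7, byrow = TRUE)
  dimnames(r) <- list(paste0("g", 1:7), paste0("g", 1:7))
  r
}

example_adjacency_7 <- function() {
  a <- matrix(c(
    0, 1, 0, 1, 0, 0, 1,
    1, 0, 1, 0, 0, 0, 1,
    0, 1, 0, 0, 0, 0, 0,
    1, 0, 0, 0, 1, 1, 0,
    0, 0, 0, 1, 0, 1, 1,
    0, 0, 0, 1, 1, 0, 1,
    1, 1, 0, 0, 1, 1, 0), 7, 7, byrow = TRUE)
  dimnames(a) <- list(paste0("g", 1:7), paste0("g", 1:7))
  a
}

# vertex weights consistent with the worked greedy selection order
# (g1 is the global maximum; g5 the maximum of the surviving {g3, g5, g6})
example_weights_7 <- function() c(1.6, 0.9, 0.5, 1.0, 1.2, 0.8, 1.1)

# small labelled dataset with two tight, well-separated class clusters;
# every sample has an exact duplicate so its LOOCV neighbor is its twin
duplicate_cluster_dataset <- function(n_pairs_per_class = 2) {
  base <- rbind(c(0, 0, 0), c(10, 10, 10))
  rows <- list(); labs <- character(0)
  for (k in 1:2) {
    for (j in seq_len(n_pairs_per_class)) {
      jit <- base[k, ] + j * 0.01
      rows <- c(rows, list(jit, jit))
      labs <- c(labs, rep(c("a", "b")[k], 2))
    }
  }
  expression_dataset(do.call(rbind, rows), labels = labs,
                     gene_ids = paste0("g", 1:3))
}

random_dataset <- function(M, N, n_classes = 2) {
  repeat {
    y <- sample(rep(paste0("k", seq_len(n_classes)), length.out = M))
    if (min(table(y)) >= 2) break
  }
  expression_dataset(matrix(rnorm(M * N), M, N), labels = y,
                     gene_ids = paste0("g", seq_len(N)))
}

# --- independent oracles (naive formulations, no shared code paths) -------

oracle_fisher <- function(X, y) {
  y <- as.factor(y)
  vapply(seq_len(ncol(X)), function(i) {
    g <- X[, i]
    num <- 0; den <- 0
    for (k in levels(y)) {
      gk <- g[y == k]
      nk <- length(gk)
      num <- num + nk * (mean(gk) - mean(g))^2
      den <- den + nk * mean((gk - mean(gk))^2)   # population variance
    }
    num / max(den, 1e-12)
  }, numeric(1))
}

oracle_abs_correlation <- function(X) {
  N <- ncol(X)
  r <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      si <- stats::sd(X[, i]); sj <- stats::sd(X[, j])
      r[i, j] <- if (si == 0 || sj == 0) 0 else
        abs(stats::cov(X[, i], X[, j]) / (si * sj))
    }
  }
  diag(r) <- 1
  r
}

# brute-force LOOCV with explicit per-fold z-scoring
oracle_loocv_1nn <- function(X, y, subset) {
  X <- X[, subset, drop = FALSE]
  M <- nrow(X)
  correct <- 0
  for (i in seq_len(M)) {
    tr <- X[-i, , drop = FALSE]
    mu <- colMeans(tr)
    sdv <- apply(tr, 2, stats::sd)
    sdv[sdv <= 1e-12] <- 1
    trz <- sweep(sweep(tr, 2, mu), 2, sdv, "/")
    tez <- (X[i, ] - mu) / sdv
    d <- apply(trz, 1, function(r) sum((r - tez)^2))
    j <- which.min(d)
    if (y[-i][j] == y[i]) correct <- correct + 1
  }
  correct / M
}

# exact maximum-weight independent set by subset enumeration (n <= 20)
oracle_exact_mwis <- function(adj, w) {
  n <- length(w)
  masks <- 0:(2^n - 1)
  bits <- matrix(0L, length(masks), n)
  for (b in seq_len(n)) bits[, b] <- (masks %/% 2^(b - 1)) %% 2
  ok <- rep(TRUE, length(masks))
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      if (adj[u, v] == 1) ok <- ok & !(bits[, u] & bits[, v])
    }
  }
  weights <- as.numeric(bits %*% w)
  weights[!ok] <- -Inf
  best <- which.max(weights)
  list(weight = weights[best], members = which(bits[best, ] == 1L))
}

random_similarity_graph <- function(n, edge_prob = 0.3) {
  adj <- matrix(0L, n, n)
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      if (stats::runif(1) < edge_prob) adj[u, v] <- adj[v, u] <- 1L
    }
  }
  w <- stats::runif(n, 0.1, 2)
  r <- adj * 0.9           # correlation proxy: edges at 0.9, non-edges 0
  diag(r) <- 1
  list(graph = build_graph(r, w, r0 = 0.35, gene_ids = paste0("g", 1:n)),
       adj = adj, w = w)
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
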