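#' Per-gene Fisher scores
#'
#' For gene `i` with per-class means `mu_ik`, per-class population variances
#' `sigma_ik^2` (divide by `n_k`), class sizes `n_k` and global mean `mu_i`:
#'
#' \deqn{F_i = \frac{\sum_k n_k (\mu_{ik} - \mu_i)^2}
#'                  {\sum_k n_k \sigma_{ik}^2}}
#'
#' A higher score means the gene separates the classes better. The
#' denominator is floored at `eps` so a gene that is constant within every
#' class gets a very large but finite score (keeping downstream roulette
#' probabilities finite); a gene constant everywhere scores exactly 0.
#' Scores are invariant to per-gene affine rescaling.
#'
#' @param ds an `ExpressionDataset` with at least 2 classes.
#' @param eps denominator floor (default `1e-12`).
#' @return An object of class `GeneScores`: list with `fisher` (length-`N`
#'   vector, index-aligned with `ds$gene_ids`), `class_means` and `class_sds`
#'   (`c x N` matrices, population convention), `global_means`, `classes`,
#'   `class_counts`.
#' @export
fisher_scores <- function(ds, eps = 1e-12) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$c < 2L) stop("Fisher score undefined for a single class",
                      call. = FALSE)
  X <- ds$matrix
  cls <- levels(ds$labels)
  nk <- ds$class_counts
  mu_k <- matrix(0, length(cls), ds$N, dimnames = list(cls, ds$gene_ids))
  var_k <- mu_k
  for (k in seq_along(cls)) {
    Xk <- X[ds$labels == cls[k], , drop = FALSE]
    m <- colMeans(Xk)
    mu_k[k, ] <- m
    var_k[k, ] <- colMeans(Xk^2) - m^2          # population variance
  }
  var_k[var_k < 0] <- 0                          # numerical guard
  mu <- colMeans(X)
  num <- colSums(nk * (mu_k - rep(mu, each = length(cls)))^2)
  den <- pmax(colSums(nk * var_k), eps)
  structure(
    list(fisher = as.numeric(num / den),
         class_means = mu_k,
         class_sds = sqrt(var_k),
         global_means = mu,
         classes = cls,
         class_counts = nk),
    class = "GeneScores"
  )
}

#' @export
print.GeneScores <- function(x, ...) {
  cat(sprintf("GeneScores: %d genes, %d classes; Fisher score range [%.4g, %.4g]\n",
              length(x$fisher), length(x$classes),
              min(x$fisher), max(x$fisher)))
  invisible(x)
}

#' Absolute Pearson correlation matrix between genes
#'
#' `r[i, j] = |cor(g_i, g_j)|` across samples. Any pair involving a
#' zero-variance gene is set to 0 (no linear association is defined); the
#' diagonal is 1 uniformly. Computed in column blocks so that tens of
#' thousands of genes fit in ordinary memory; the result is identical to the
#' whole-matrix computation.
#'
#' @param ds an `ExpressionDataset` with `M >= 3`.
#' @param block_size number of genes per block (default 2048).
#' @return `N x N` symmetric numeric matrix with entries in `[0, 1]`.
#' @export
abs_correlation_matrix <- function(ds, block_size = 2048L) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (ds$M < 3L) stop("need M >= 3 samples for correlations", call. = FALSE)
  Z <- .standardize_columns(ds$matrix)
  N <- ds$N
  r <- matrix(0, N, N, dimnames = list(ds$gene_ids, ds$gene_ids))
  starts <- seq(1L, N, by = block_size)
  for (s in starts) {
    cols <- s:min(s + block_size - 1L, N)
    r[, cols] <- abs(crossprod(Z$z, Z$z[, cols, drop = FALSE]) / (ds$M - 1))
  }
  r[Z$constant, ] <- 0
  r[, Z$constant] <- 0
  r[r > 1] <- 1
  diag(r) <- 1
  r
}

# column z-scores (sample SD); constant columns flagged and left at zero
.standardize_columns <- function(X) {
  mu <- colMeans(X)
  sd <- sqrt(pmax(colMeans(X^2) - mu^2, 0) * nrow(X) / (nrow(X) - 1))
  constant <- sd <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  sd[constant] <- 1
  z <- sweep(sweep(X, 2L, mu), 2L, sd, "/")
  z[, constant] <- 0
  list(z = z, constant = constant)
}
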