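#' Fitness parameters
#'
#' @param p total candidate-gene count (the subset-size penalty denominator).
#' @param w1 weight in `[0, 1]` trading accuracy against subset size
#'   (default 0.99: accuracy dominates, size breaks near-ties).
#' @return An object of class `FitnessParams`.
#' @export
fitness_params <- function(p, w1 = 0.99) {
  p <- as.integer(p)
  if (p < 1L) stop("p must be >= 1", call. = FALSE)
  if (w1 < 0 || w1 > 1) stop("w1 must be in [0, 1]", call. = FALSE)
  structure(list(w1 = as.numeric(w1), p = p), class = "FitnessParams")
}

#' Aggregate fitness of a candidate subset
#'
#' `f = w1 * CA + (1 - w1) * (1 - n_genes / p)`: a convex combination of the
#' classification accuracy and the fraction of candidate genes left out, so
#' fitness strictly increases in accuracy (for `w1 > 0`) and strictly
#' decreases in subset size (for `w1 < 1`).
#'
#' @param ca classification accuracy in `[0, 1]`.
#' @param n_genes selected-subset size, `1 <= n_genes <= p`.
#' @param params a [fitness_params()].
#' @return The fitness value.
#' @export
fitness <- function(ca, n_genes, params) {
  stopifnot(inherits(params, "FitnessParams"))
  if (ca < 0 || ca > 1) stop("ca must be in [0, 1]", call. = FALSE)
  if (n_genes < 1 || n_genes > params$p) {
    stop("n_genes must be in [1, p]", call. = FALSE)
  }
  params$w1 * ca + (1 - params$w1) * (1 - n_genes / params$p)
}

#' Leave-one-out 1NN accuracy with fold-wise normalization
#'
#' For each held-out sample the per-gene mean and standard deviation are
#' computed on the remaining `M - 1` training samples (restricted to
#' `subset`), the training data are z-scored with them, the held-out sample
#' is scaled with the same training statistics, and its class is predicted by
#' the Euclidean-nearest training sample (distance ties broken by lowest
#' training-sample index). Returns the fraction of samples predicted
#' correctly. A training-fold SD of zero for a gene is replaced by 1, so the
#' gene contributes its centered raw value.
#'
#' Because both the training rows and the test row are centered by the same
#' fold means, fold distances reduce to SD-scaled raw differences; the
#' implementation uses that identity (the naive recomputation is the
#' contract and is what the test oracle does).
#'
#' @param ds an `ExpressionDataset`.
#' @param subset non-empty vector of gene indices (1-based).
#' @return LOOCV accuracy in `[0, 1]`.
#' @export
loocv_accuracy_1nn <- function(ds, subset) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  subset <- as.integer(subset)
  if (length(subset) < 1L) stop("subset must be non-empty", call. = FALSE)
  if (anyNA(subset) || any(subset < 1L | subset > ds$N)) {
    stop("invalid gene indices in subset", call. = FALSE)
  }
  X <- ds$matrix[, subset, drop = FALSE]
  y <- ds$labels
  M <- nrow(X)
  n_tr <- M - 1L
  X2 <- X^2
  # per-fold training mean and sample variance from cached column sums
  mu <- sweep(-X, 2L, colSums(X), "+") / n_tr           # M x s, row i = fold i
  v <- (sweep(-X2, 2L, colSums(X2), "+") - n_tr * mu^2) / (n_tr - 1L)
  sdv <- sqrt(pmax(v, 0))
  sdv[sdv <= 1e-12] <- 1
  # fold-scaled squared distance expands to three bilinear terms:
  # d2[i, j] = sum_g w[i, g] (x[i, g] - x[j, g])^2, w = 1 / sd^2
  w <- 1 / sdv^2
  d2 <- rowSums(w * X2) + w %*% t(X2) - 2 * (w * X) %*% t(X)
  diag(d2) <- Inf
  nn <- max.col(-d2, ties.method = "first")             # lowest index on ties
  mean(y[nn] == y)
}

#' Evaluate a gene subset: accuracy, size and fitness
#'
#' @param ds an `ExpressionDataset` over the `p` candidate genes.
#' @param subset non-empty vector of gene indices into `ds`.
#' @param params a [fitness_params()] (its `p` should equal `ds$N`).
#' @return An object of class `EvaluationResult`: list with `accuracy`,
#'   `n_genes`, `fitness`.
#' @export
evaluate_subset <- function(ds, subset, params) {
  ca <- loocv_accuracy_1nn(ds, subset)
  n <- length(subset)
  structure(list(accuracy = ca, n_genes = n,
                 fitness = fitness(ca, n, params)),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf("EvaluationResult: accuracy %.4f, %d genes, fitness %.6f\n",
              x$accuracy, x$n_genes, x$fitness))
  invisible(x)
}
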