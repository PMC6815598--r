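#' Build the gene-similarity graph
#'
#' One vertex per gene, weighted by its Fisher score; an undirected edge
#' joins genes `i != j` exactly when their absolute Pearson correlation
#' strictly exceeds the threshold: `a_ij = 1` iff `r_ij > r0`. A correlation
#' exactly equal to `r0` yields no edge. Vertex weights are floored at a tiny
#' positive `eps` so all weights are strictly positive; zero-score genes are
#' then only ever picked when isolated and nothing better remains.
#'
#' @param r `N x N` absolute-correlation matrix (entries in `[0, 1]`,
#'   symmetric), e.g. from [abs_correlation_matrix()].
#' @param scores a `GeneScores` object, or a numeric vector of vertex weights,
#'   index-aligned with `r`.
#' @param r0 threshold in `[0, 1]`; 0.35 behaves well on high-dimensional
#'   expression data and is the pipeline default.
#' @param gene_ids optional ids (default from `r` dimnames).
#' @return An object of class `SimilarityGraph`: list with `neighbors`
#'   (length-`N` list of sorted integer neighbor vectors), `weights`,
#'   `r0`, `n_vertices`, `n_edges`, `gene_ids`.
#' @export
build_graph <- function(r, scores, r0 = 0.35,
                        gene_ids = rownames(r)) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) {
    stop("r must be a square matrix", call. = FALSE)
  }
  if (r0 < 0 || r0 > 1) stop("r0 must be in [0, 1]", call. = FALSE)
  w <- if (inherits(scores, "GeneScores")) scores$fisher else as.numeric(scores)
  N <- nrow(r)
  if (length(w) != N) {
    stop("scores are not index-aligned with the correlation matrix",
         call. = FALSE)
  }
  adj <- r > r0
  diag(adj) <- FALSE
  neighbors <- lapply(seq_len(N), function(i) which(adj[i, ]))
  .new_similarity_graph(neighbors, w, r0, gene_ids)
}

#' Gene-similarity graph straight from a dataset
#'
#' Convenience wrapper computing Fisher scores and blockwise correlations and
#' thresholding block by block, so the full `N x N` correlation matrix never
#' needs to be held for very large `N`. Same contract as
#' [abs_correlation_matrix()] + [build_graph()].
#'
#' @inheritParams build_graph
#' @param ds an `ExpressionDataset`.
#' @param scores optional precomputed `GeneScores` (computed if `NULL`).
#' @param block_size genes per correlation block.
#' @return A `SimilarityGraph`.
#' @export
similarity_graph <- function(ds, r0 = 0.35, scores = NULL,
                             block_size = 2048L) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(scores)) scores <- fisher_scores(ds)
  Z <- .standardize_columns(ds$matrix)
  N <- ds$N
  neighbors <- vector("list", N)
  starts <- seq(1L, N, by = block_size)
  for (s in starts) {
    cols <- s:min(s + block_size - 1L, N)
    rb <- abs(crossprod(Z$z, Z$z[, cols, drop = FALSE]) / (ds$M - 1))
    rb[Z$constant, ] <- 0
    rb[, Z$constant[cols]] <- 0
    for (j in seq_along(cols)) {
      nb <- which(rb[, j] > r0)
      neighbors[[cols[j]]] <- nb[nb != cols[j]]
    }
  }
  .new_similarity_graph(neighbors, scores$fisher, r0, ds$gene_ids)
}

.new_similarity_graph <- function(neighbors, weights, r0, gene_ids,
                                  eps = 1e-12) {
  N <- length(neighbors)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(N))
  structure(
    list(neighbors = neighbors,
         weights = pmax(as.numeric(weights), eps),
         r0 = r0,
         n_vertices = N,
         n_edges = sum(lengths(neighbors)) %/% 2L,
         gene_ids = as.character(gene_ids)),
    class = "SimilarityGraph"
  )
}

#' @export
print.SimilarityGraph <- function(x, ...) {
  cat(sprintf("SimilarityGraph: %d vertices, %d edges, r0 = %g\n",
              x$n_vertices, x$n_edges, x$r0))
  invisible(x)
}

#' Dense 0/1 adjacency matrix view of a similarity graph
#'
#' @param g a `SimilarityGraph`.
#' @return `N x N` integer matrix, symmetric with zero diagonal.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "SimilarityGraph"))
  N <- g$n_vertices
  a <- matrix(0L, N, N, dimnames = list(g$gene_ids, g$gene_ids))
  for (i in seq_len(N)) a[i, g$neighbors[[i]]] <- 1L
  a
}

#' Greedy maximum-weight independent set
#'
#' Repeatedly picks the remaining vertex of maximum weight (ties broken by
#' lowest index), adds it to the set, and deletes it together with its whole
#' neighborhood; stops when no vertices remain. The result is always an
#' independent and maximal set, and a fast approximation to the NP-hard
#' exact maximum-weight independent set. On an edgeless graph every vertex is
#' returned (in descending weight order); on a complete graph only the
#' max-weight vertex.
#'
#' @param g a `SimilarityGraph` with positive finite weights.
#' @return An object of class `IndependentSet`: list with `members`
#'   (gene indices in selection order), `total_weight`, `gene_ids`.
#' @export
greedy_mwis <- function(g) {
  stopifnot(inherits(g, "SimilarityGraph"))
  w <- g$weights
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("vertex weights must be positive and finite", call. = FALSE)
  }
  alive <- rep(TRUE, g$n_vertices)
  members <- integer(0)
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[which.max(w[cand])]   # which.max -> lowest index on ties
    members <- c(members, best)
    alive[best] <- FALSE
    alive[g$neighbors[[best]]] <- FALSE
  }
  structure(
    list(members = members,
         total_weight = sum(w[members]),
         gene_ids = g$gene_ids[members]),
    class = "IndependentSet"
  )
}

#' @export
print.IndependentSet <- function(x, ...) {
  cat(sprintf("IndependentSet: %d vertices, total weight %.6g\n",
              length(x$members), x$total_weight))
  invisible(x)
}

#' Check independence and maximality of a vertex set
#'
#' @param g a `SimilarityGraph`.
#' @param members integer vertex indices.
#' @return list with logical elements `independent` and `maximal`.
#' @export
check_independent_set <- function(g, members) {
  stopifnot(inherits(g, "SimilarityGraph"))
  in_set <- logical(g$n_vertices)
  in_set[members] <- TRUE
  independent <- !any(vapply(members, function(v)
    any(in_set[g$neighbors[[v]]]), logical(1)))
  outside <- which(!in_set)
  maximal <- all(vapply(outside, function(v)
    any(in_set[g$neighbors[[v]]]), logical(1)))
  list(independent = independent, maximal = maximal)
}
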