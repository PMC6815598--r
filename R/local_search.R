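#' Local-search parameters
#'
#' The defaults are the per-iteration refinement used inside the ant colony
#' loop (`it_max = 5`, `n_add = 3`, `n_del = 5`). Setting `n_add = 0` turns
#' the search into a pure backward generation; [backward_params()] provides
#' its published setting (`it_max = 20`, `n_add = 0`, `n_del = 2`).
#'
#' @param it_max maximum number of consecutive iterations without an accepted
#'   improvement before stopping.
#' @param n_add maximum Add moves per iteration.
#' @param n_del maximum Del moves per iteration.
#' @return An object of class `LsParams`.
#' @export
ls_params <- function(it_max = 5L, n_add = 3L, n_del = 5L) {
  p <- list(it_max = as.integer(it_max), n_add = as.integer(n_add),
            n_del = as.integer(n_del))
  stopifnot(p$it_max >= 1L, p$n_add >= 0L, p$n_del >= 0L,
            p$n_add + p$n_del >= 1L)
  structure(p, class = "LsParams")
}

#' @rdname ls_params
#' @export
backward_params <- function(it_max = 20L, n_add = 0L, n_del = 2L) {
  ls_params(it_max = it_max, n_add = n_add, n_del = n_del)
}

#' Roulette probabilities for the Add operator
#'
#' Over the excluded genes `Y`, gene `i` is drawn with probability
#' `P_i = F_i / sum_j F_j`, so high-scoring genes are preferred for addition.
#' If every score is zero the draw is uniform.
#'
#' @param fisher_excluded Fisher scores of the excluded genes (all `>= 0`).
#' @return Probability vector summing to 1.
#' @export
add_probabilities <- function(fisher_excluded) {
  if (length(fisher_excluded) == 0L) {
    stop("no excluded genes: Add is impossible", call. = FALSE)
  }
  tot <- sum(fisher_excluded)
  if (tot <= 0) {
    return(rep(1 / length(fisher_excluded), length(fisher_excluded)))
  }
  fisher_excluded / tot
}

#' Roulette probabilities for the Del operator
#'
#' Over the included genes `X`, scores are reflected about their maximum
#' (`Fbar_j = max(F) - F_j`) and normalized, so low-scoring genes are
#' preferred for deletion and the top-scoring gene is never drawn. If all
#' scores are equal the draw is uniform.
#'
#' @param fisher_included Fisher scores of the included genes (all `>= 0`).
#' @return Probability vector summing to 1.
#' @export
del_probabilities <- function(fisher_included) {
  if (length(fisher_included) == 0L) {
    stop("no included genes: Del is impossible", call. = FALSE)
  }
  fbar <- max(fisher_included) - fisher_included
  tot <- sum(fbar)
  if (tot <= 0) {
    return(rep(1 / length(fisher_included), length(fisher_included)))
  }
  fbar / tot
}

#' Fisher-score-biased Add/Del local search
#'
#' Iterative single-flip improvement of a candidate subset. Each iteration
#' proposes up to `n_add` Add moves and then up to `n_del` Del moves. A move
#' roulette-draws a gene ([add_probabilities()] / [del_probabilities()]),
#' flips it, re-evaluates the fitness, and keeps the flip only if fitness
#' strictly improves — otherwise the flip is reverted and the gene is not
#' redrawn within the same iteration. A deletion that would empty the subset
#' is skipped. A counter of consecutive iterations with no accepted move
#' stops the search at `it_max`. The returned fitness is never below the
#' start's and the returned subset is never empty; with `n_add = 0` the
#' subset size is non-increasing (backward generation).
#'
#' @param start an `AntSolution` (or any list with `bits` and `evaluation`)
#'   with a non-empty selection, already evaluated.
#' @param ds the `ExpressionDataset` over the `p` candidate genes.
#' @param fisher length-`p` Fisher scores of the candidate genes.
#' @param params an [ls_params()].
#' @param fit a [fitness_params()].
#' @param evaluator optional `function(bits) -> EvaluationResult`; defaults
#'   to a plain [evaluate_subset()] call (the ant colony passes its cached
#'   evaluator).
#' @return An `AntSolution` with fitness `>=` the start's.
#' @export
local_search <- function(start, ds, fisher, params = ls_params(),
                         fit = fitness_params(ds$N), evaluator = NULL) {
  stopifnot(inherits(params, "LsParams"), inherits(fit, "FitnessParams"))
  bits <- start$bits
  p <- length(bits)
  stopifnot(length(fisher) == p, sum(bits) >= 1L)
  if (is.null(evaluator)) {
    evaluator <- function(b) evaluate_subset(ds, which(b == 1L), fit)
  }
  best_eval <- start$evaluation
  stagnation <- 0L
  while (stagnation < params$it_max) {
    improved <- FALSE
    # Add moves: draw from excluded genes, high Fisher score preferred
    tried <- logical(p)
    for (. in seq_len(params$n_add)) {
      pool <- which(bits == 0L & !tried)
      if (length(pool) == 0L) break
      g <- .roulette_draw(pool, add_probabilities(fisher[pool]))
      tried[g] <- TRUE
      bits[g] <- 1L
      cand <- evaluator(bits)
      if (cand$fitness > best_eval$fitness) {
        best_eval <- cand
        improved <- TRUE
      } else {
        bits[g] <- 0L
      }
    }
    # Del moves: draw from included genes, low Fisher score preferred
    tried <- logical(p)
    for (. in seq_len(params$n_del)) {
      pool <- which(bits == 1L & !tried)
      if (length(pool) == 0L || sum(bits) <= 1L) break
      g <- .roulette_draw(pool, del_probabilities(fisher[pool]))
      tried[g] <- TRUE
      bits[g] <- 0L
      cand <- evaluator(bits)
      if (cand$fitness > best_eval$fitness) {
        best_eval <- cand
        improved <- TRUE
      } else {
        bits[g] <- 1L
      }
    }
    stagnation <- if (improved) 0L else stagnation + 1L
  }
  structure(list(bits = bits, selected = which(bits == 1L),
                 evaluation = best_eval),
            class = "AntSolution")
}

.roulette_draw <- function(pool, prob) {
  if (length(pool) == 1L) return(pool)
  sample(pool, 1L, prob = prob)
}
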