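#' Ant colony parameters
#'
#' Defaults follow the method's published tuning on microarray data.
#'
#' @param m ants per iteration.
#' @param n_max iterations (`0` is allowed and disables the search: the
#'   all-genes solution is returned, which is how the pipeline runs its
#'   filter-only ablation).
#' @param alpha pheromone exponent in the transition rule.
#' @param beta heuristic exponent in the transition rule.
#' @param rho_loc local (per-ant) evaporation coefficient in `(0, 1)`.
#' @param rho_glob global (iteration-best) evaporation coefficient in `(0, 1)`.
#' @param lambda weight (`>= 1`) of the accuracy term in the pheromone
#'   deposit `max(0, lambda * CA - n_genes / p)`.
#' @param tau_init initial trail intensity for both pathways of every gene.
#' @param tau_min,tau_max clamping interval for every trail, enforced after
#'   every update to avoid search stagnation.
#' @param seed integer seed for the run (set once by [run_aco()]); `NULL`
#'   continues the caller's RNG stream.
#' @return An object of class `AcoParams`.
#' @export
aco_params <- function(m = 30L, n_max = 100L, alpha = 1.2, beta = 0.2,
                       rho_loc = 0.002, rho_glob = 0.06, lambda = 1.6,
                       tau_init = 1.0, tau_min = 0.05, tau_max = 1.4,
                       seed = NULL) {
  p <- list(m = as.integer(m), n_max = as.integer(n_max),
            alpha = as.numeric(alpha), beta = as.numeric(beta),
            rho_loc = as.numeric(rho_loc), rho_glob = as.numeric(rho_glob),
            lambda = as.numeric(lambda), tau_init = as.numeric(tau_init),
            tau_min = as.numeric(tau_min), tau_max = as.numeric(tau_max),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(p$m >= 1L, p$n_max >= 0L,
            p$rho_loc > 0, p$rho_loc < 1,
            p$rho_glob > 0, p$rho_glob < 1,
            p$lambda >= 1,
            p$tau_min > 0, p$tau_min <= p$tau_init,
            p$tau_init <= p$tau_max)
  structure(p, class = "AcoParams")
}

#' Initial pheromone state
#'
#' @param p number of candidate genes.
#' @param params an [aco_params()].
#' @return A `p x 2` matrix `tau`; column 1 is pathway 0 (skip), column 2 is
#'   pathway 1 (select), all entries at `tau_init`.
#' @export
init_pheromone <- function(p, params = aco_params()) {
  matrix(params$tau_init, nrow = p, ncol = 2L,
         dimnames = list(NULL, c("skip", "select")))
}

#' Heuristic desirability of selecting a gene
#'
#' `eta_i1 = F_i / (1 + N_s)`: the gene's Fisher score discounted by the
#' number of genes `N_s` the ant has already selected, nudging ants toward
#' small subsets of relevant genes.
#'
#' @param fisher_i Fisher score of gene `i` (`>= 0`).
#' @param n_s genes already selected on the ant's path before gene `i`.
#' @return The desirability value.
#' @export
heuristic_select <- function(fisher_i, n_s) {
  fisher_i / (1 + n_s)
}

#' Heuristic desirability of skipping a gene
#'
#' `eta_i0 = (sum_k F_k) / (p * (1 + N_s))`: the mean Fisher score over all
#' `p` candidates, under the same subset-size discount.
#'
#' @param mean_fisher mean Fisher score over the `p` candidate genes.
#' @param n_s genes already selected on the ant's path.
#' @return The desirability value.
#' @export
heuristic_skip <- function(mean_fisher, n_s) {
  mean_fisher / (1 + n_s)
}

#' Pathway transition probabilities for one gene
#'
#' `p_ij = tau_ij^alpha eta_ij^beta / (tau_i0^alpha eta_i0^beta +
#'  tau_i1^alpha eta_i1^beta)`. If both weighted terms vanish the rule is
#' undefined and an unbiased coin `(0.5, 0.5)` is used.
#'
#' @param tau_i0,tau_i1 trail intensities for skip / select.
#' @param eta_i0,eta_i1 heuristic desirabilities (`>= 0`).
#' @param alpha,beta exponents.
#' @return Numeric vector `c(p_i0, p_i1)` summing to 1.
#' @export
transition_probability <- function(tau_i0, tau_i1, eta_i0, eta_i1,
                                   alpha, beta) {
  t0 <- tau_i0^alpha * eta_i0^beta
  t1 <- tau_i1^alpha * eta_i1^beta
  tot <- t0 + t1
  if (!is.finite(tot) || tot <= 0) return(c(0.5, 0.5))
  c(t0, t1) / tot
}

#' Construct one ant's path
#'
#' Visits genes in index order `1..p`; at each step draws pathway 1 (select)
#' with the transition probability computed from the current pheromones and
#' the heuristics with `N_s` equal to the count selected so far. If the draw
#' selects nothing at all, the gene with the largest
#' `tau_i1^alpha * eta_i1^beta` is force-selected (the fitness function is
#' undefined on empty subsets). Consumes the caller's RNG stream.
#'
#' @param pher `p x 2` pheromone matrix.
#' @param fisher length-`p` vector of Fisher scores for the candidate genes.
#' @param params an [aco_params()].
#' @return Integer 0/1 vector of length `p` (unevaluated `AntSolution` bits).
#' @export
construct_path <- function(pher, fisher, params) {
  p <- nrow(pher)
  mean_f <- mean(fisher)
  bits <- integer(p)
  n_s <- 0L
  u <- stats::runif(p)
  for (i in seq_len(p)) {
    pr <- transition_probability(pher[i, 1L], pher[i, 2L],
                                 heuristic_skip(mean_f, n_s),
                                 heuristic_select(fisher[i], n_s),
                                 params$alpha, params$beta)
    if (u[i] < pr[2L]) {
      bits[i] <- 1L
      n_s <- n_s + 1L
    }
  }
  if (n_s == 0L) {
    score <- pher[, 2L]^params$alpha *
      heuristic_select(fisher, 0L)^params$beta
    bits[which.max(score)] <- 1L
  }
  bits
}

# Pheromone deposit of a solution (shared by local and global updates):
# max(0, lambda * CA - n_genes / p)
.pheromone_deposit <- function(accuracy, n_genes, p, lambda) {
  max(0, lambda * accuracy - n_genes / p)
}

#' Local pheromone update after one ant
#'
#' Every trail evaporates (`tau <- (1 - rho_loc) tau + rho_loc * Delta_tau`);
#' the pathway the ant actually used on each gene receives the deposit
#' `Delta_tau = max(0, lambda * CA - n_genes / p)`, the unused pathway gets
#' `Delta_tau = 0`. The result is clamped to `[tau_min, tau_max]`.
#'
#' @param pher `p x 2` pheromone matrix.
#' @param bits the ant's 0/1 path.
#' @param accuracy the ant's LOOCV accuracy.
#' @param params an [aco_params()].
#' @return Updated, clamped pheromone matrix.
#' @export
local_pheromone_update <- function(pher, bits, accuracy, params) {
  p <- nrow(pher)
  dep <- .pheromone_deposit(accuracy, sum(bits), p, params$lambda)
  delta <- matrix(0, p, 2L)
  delta[cbind(seq_len(p), bits + 1L)] <- dep
  out <- (1 - params$rho_loc) * pher + params$rho_loc * delta
  .clamp_pheromone(out, params)
}

#' Global pheromone update from the iteration-best ant
#'
#' Only the entries on the best ant's path (pathway `bits[i]` of every gene
#' `i`) are updated, with the same deposit form as the local rule, at rate
#' `rho_glob`; all other entries are untouched. Clamped.
#'
#' @inheritParams local_pheromone_update
#' @param bits the iteration-best ant's 0/1 path.
#' @param accuracy the iteration-best ant's LOOCV accuracy.
#' @return Updated, clamped pheromone matrix.
#' @export
global_pheromone_update <- function(pher, bits, accuracy, params) {
  p <- nrow(pher)
  dep <- .pheromone_deposit(accuracy, sum(bits), p, params$lambda)
  idx <- cbind(seq_len(p), bits + 1L)
  pher[idx] <- (1 - params$rho_glob) * pher[idx] + params$rho_glob * dep
  .clamp_pheromone(pher, params)
}

.clamp_pheromone <- function(pher, params) {
  pher[pher < params$tau_min] <- params$tau_min
  pher[pher > params$tau_max] <- params$tau_max
  pher
}

#' Run the ant colony search over a candidate-gene dataset
#'
#' `n_max` iterations of `m` ants. Ants are processed sequentially; each
#' constructs a binary path, is evaluated by LOOCV 1NN fitness (with caching
#' keyed on the bit vector, since ants frequently regenerate identical
#' subsets), and immediately triggers the local pheromone update, so later
#' ants within an iteration see earlier ants' trails. The iteration-best ant
#' optionally passes through a local-search hook before driving the global
#' update. The best-so-far solution (higher fitness, then fewer genes, then
#' earlier discovery) is tracked and per-iteration trajectories recorded.
#'
#' @param ds an `ExpressionDataset` restricted to the `p` candidate genes.
#' @param fisher length-`p` Fisher scores for those genes (used by the
#'   construction heuristics; recomputed from `ds` if `NULL`).
#' @param params an [aco_params()]; if `params$seed` is non-`NULL` the RNG is
#'   seeded once at entry.
#' @param fit a [fitness_params()] (default `p = ds$N`, `w1 = 0.99`).
#' @param ls_hook optional `function(solution) -> solution` applied to each
#'   iteration-best ant (a list with `bits` and `evaluation`); used by the
#'   pipeline to plug in [local_search()].
#' @return A list with `best` (an `AntSolution`: `bits`, `selected`,
#'   `evaluation`), `trajectory` (data.frame with per-iteration best-so-far
#'   `fitness`, `accuracy`, `n_genes`), `pheromone` (final state),
#'   `n_evaluations`.
#' @export
run_aco <- function(ds, fisher = NULL, params = aco_params(),
                    fit = fitness_params(ds$N), ls_hook = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(params, "AcoParams"),
            inherits(fit, "FitnessParams"))
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- ds$N
  if (is.null(fisher)) fisher <- fisher_scores(ds)$fisher
  stopifnot(length(fisher) == p)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_bits <- function(bits) {
    key <- paste(bits, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    n_eval <<- n_eval + 1L
    res <- evaluate_subset(ds, which(bits == 1L), fit)
    cache[[key]] <- res
    res
  }

  as_solution <- function(bits, evaluation) {
    structure(list(bits = bits, selected = which(bits == 1L),
                   evaluation = evaluation), class = "AntSolution")
  }

  # filter-only degenerate run: all candidate genes, no search
  if (params$n_max == 0L) {
    bits <- rep(1L, p)
    best <- as_solution(bits, eval_bits(bits))
    return(list(best = best,
                trajectory = data.frame(fitness = numeric(0),
                                        accuracy = numeric(0),
                                        n_genes = integer(0)),
                pheromone = init_pheromone(p, params),
                n_evaluations = n_eval))
  }

  pher <- init_pheromone(p, params)
  best <- NULL
  better_than <- function(a, b) {       # strict: a beats b
    if (is.null(b)) return(TRUE)
    if (a$evaluation$fitness != b$evaluation$fitness) {
      return(a$evaluation$fitness > b$evaluation$fitness)
    }
    a$evaluation$n_genes < b$evaluation$n_genes
  }
  traj <- data.frame(fitness = numeric(params$n_max),
                     accuracy = numeric(params$n_max),
                     n_genes = integer(params$n_max))

  for (it in seq_len(params$n_max)) {
    iter_best <- NULL
    for (k in seq_len(params$m)) {
      bits <- construct_path(pher, fisher, params)
      sol <- as_solution(bits, eval_bits(bits))
      pher <- local_pheromone_update(pher, bits, sol$evaluation$accuracy,
                                     params)
      if (better_than(sol, iter_best)) iter_best <- sol
    }
    if (!is.null(ls_hook)) iter_best <- ls_hook(iter_best)
    pher <- global_pheromone_update(pher, iter_best$bits,
                                    iter_best$evaluation$accuracy, params)
    if (better_than(iter_best, best)) best <- iter_best
    traj$fitness[it] <- best$evaluation$fitness
    traj$accuracy[it] <- best$evaluation$accuracy
    traj$n_genes[it] <- best$evaluation$n_genes
  }
  list(best = best, trajectory = traj, pheromone = pher,
       n_evaluations = n_eval)
}

#' @export
print.AntSolution <- function(x, ...) {
  cat(sprintf("AntSolution: %d/%d genes, accuracy %.4f, fitness %.6f\n",
              x$evaluation$n_genes, length(x$bits),
              x$evaluation$accuracy, x$evaluation$fitness))
  invisible(x)
}
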