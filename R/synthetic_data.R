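#' Specification for a synthetic expression dataset
#'
#' Describes a multi-class microarray-like dataset with three planted gene
#' populations: `n_informative` marker genes whose class-conditional means
#' differ, `n_blocks` blocks of `block_size` mutually correlated redundant
#' genes driven by a shared latent factor, and label-independent noise genes
#' filling the remaining columns.
#'
#' @param M sample count (`M >= 2c`).
#' @param N gene count.
#' @param c class count (`>= 2`).
#' @param n_informative number of planted discriminative genes.
#' @param effect_size between-class mean shift delta, in within-class SD
#'   units: planted gene `j` is up-shifted by `effect_size * noise_sd` in
#'   class `((j - 1) mod c) + 1` (a one-vs-rest marker design).
#' @param n_blocks,block_size layout of the redundant blocks.
#' @param block_rho target within-block absolute pairwise correlation in
#'   `[0, 1)`, achieved by the shared-factor construction
#'   `g = sqrt(rho) z_block + sqrt(1 - rho) eps`.
#' @param noise_sd within-class standard deviation of every gene.
#' @param seed integer seed; a fixed seed gives a byte-identical dataset.
#' @return An object of class `SyntheticSpec` (a validated list).
#' @export
synthetic_spec <- function(M = 60L, N = 500L, c = 3L, n_informative = 5L,
                           effect_size = 3, n_blocks = 10L, block_size = 10L,
                           block_rho = 0.9, noise_sd = 1, seed = 1L) {
  spec <- list(M = as.integer(M), N = as.integer(N), c = as.integer(c),
               n_informative = as.integer(n_informative),
               effect_size = as.numeric(effect_size),
               n_blocks = as.integer(n_blocks),
               block_size = as.integer(block_size),
               block_rho = as.numeric(block_rho),
               noise_sd = as.numeric(noise_sd), seed = as.integer(seed))
  if (spec$c < 2L) stop("need c >= 2 classes", call. = FALSE)
  if (spec$M < 2L * spec$c) stop("need M >= 2c samples", call. = FALSE)
  if (spec$n_informative + spec$n_blocks * spec$block_size > spec$N) {
    stop("infeasible layout: n_informative + n_blocks*block_size > N",
         call. = FALSE)
  }
  if (spec$block_rho < 0 || spec$block_rho >= 1) {
    stop("block_rho must be in [0, 1)", call. = FALSE)
  }
  if (spec$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  structure(spec, class = "SyntheticSpec")
}

#' Generate a synthetic expression dataset with planted structure
#'
#' Balanced class labels (floor division, remainder to the first class),
#' class-conditional Gaussian expression. Column layout: planted informative
#' genes first, then the redundant blocks, then pure noise. Deterministic for
#' a fixed `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `dataset` (an `ExpressionDataset`),
#'   `ground_truth` (1-based indices of the planted informative genes),
#'   `blocks` (list of index vectors, one per redundant block) and `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)

  M <- spec$M; N <- spec$N; c <- spec$c
  base <- M %/% c
  sizes <- rep(base, c)
  sizes[1L] <- sizes[1L] + (M - base * c)
  labels <- rep(paste0("C", seq_len(c)), times = sizes)

  X <- matrix(0, M, N)
  # planted markers: gene j elevated in class ((j-1) mod c)+1
  for (j in seq_len(spec$n_informative)) {
    k <- ((j - 1L) %% c) + 1L
    mu <- ifelse(labels == paste0("C", k), spec$effect_size * spec$noise_sd, 0)
    X[, j] <- mu + stats::rnorm(M, sd = spec$noise_sd)
  }
  # redundant blocks: shared latent factor gives pairwise correlation rho
  blocks <- list()
  pos <- spec$n_informative
  for (b in seq_len(spec$n_blocks)) {
    idx <- pos + seq_len(spec$block_size)
    z <- stats::rnorm(M)
    for (j in idx) {
      X[, j] <- spec$noise_sd *
        (sqrt(spec$block_rho) * z +
           sqrt(1 - spec$block_rho) * stats::rnorm(M))
    }
    blocks[[b]] <- idx
    pos <- pos + spec$block_size
  }
  # label-independent noise genes
  if (pos < N) {
    n_noise <- N - pos
    X[, (pos + 1L):N] <- stats::rnorm(M * n_noise, sd = spec$noise_sd)
  }
  ds <- expression_dataset(X, labels = labels,
                           gene_ids = paste0("g", seq_len(N)))
  list(dataset = ds,
       ground_truth = seq_len(spec$n_informative),
       blocks = blocks,
       spec = spec)
}

#' Write a synthetic dataset plus its ground-truth sidecar
#'
#' Emits the dataset as CSV via [write_dataset()] and a JSON sidecar holding
#' the planted informative indices, block layout and a full spec echo.
#'
#' @param gen result of [generate_dataset()].
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".truth.json")`.
#' @export
write_synthetic <- function(gen, path) {
  write_dataset(gen$dataset, path, delimiter = "csv")
  sidecar <- list(ground_truth = gen$ground_truth,
                  blocks = gen$blocks,
                  spec = unclass(gen$spec))
  jsonlite::write_json(sidecar, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
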