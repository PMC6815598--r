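#' Run the full two-stage gene-selection pipeline
#'
#' Stage 1 (filter): Fisher scores and the absolute-correlation structure
#' give the gene-similarity graph at threshold `r0`; the greedy
#' maximum-weight independent set yields `p` candidate genes with maximum
#' relevance and minimum redundancy. Stage 2 (wrapper): the ant colony
#' search runs on the dataset restricted to those `p` genes, with the
#' Add/Del local search applied to each iteration-best ant, and the
#' deletion-only backward generation applied once to the overall best
#' solution. The ant colony never sees genes outside the independent set,
#' and the final gene ids are mapped back to the original dataset columns.
#'
#' @param ds an `ExpressionDataset`.
#' @param r0 correlation threshold for the similarity graph.
#' @param aco an [aco_params()]; `n_max = 0` gives the filter-only ablation.
#' @param ls an [ls_params()] for the per-iteration refinement, or `NULL` to
#'   disable the local search (the ant-colony-only ablation).
#' @param backward an [ls_params()] (typically [backward_params()]) for the
#'   final deletion-only pass, or `NULL` to disable it.
#' @param w1 fitness weight; the penalty denominator is the MWIS size `p`.
#' @param seed integer seed for the stochastic stage; seeds R's RNG once at
#'   entry (`NULL` continues the caller's stream).
#' @param fisher,corr optional precomputed `GeneScores` / absolute-correlation
#'   matrix overriding the stage-1 statistics (used for worked examples where
#'   the graph is given directly; `corr` forces the dense graph path).
#' @param verbose print one line per stage.
#' @return An object of class `RunReport` (a list): selection and evaluation
#'   of the final subset, stage trajectories, timings, config echo. See
#'   [write_run_report()].
#' @export
run_pipeline <- function(ds, r0 = 0.35, aco = aco_params(),
                         ls = ls_params(), backward = backward_params(),
                         w1 = 0.99, seed = NULL,
                         fisher = NULL, corr = NULL, verbose = FALSE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- proc.time()[["elapsed"]]

  # stage 1: scores, graph, greedy MWIS
  if (is.null(fisher)) fisher <- fisher_scores(ds)
  stopifnot(inherits(fisher, "GeneScores"))
  graph <- if (is.null(corr)) {
    similarity_graph(ds, r0 = r0, scores = fisher)
  } else {
    build_graph(corr, fisher, r0 = r0, gene_ids = ds$gene_ids)
  }
  mwis <- greedy_mwis(graph)
  cand <- sort(mwis$members)
  p <- length(cand)
  t1 <- proc.time()[["elapsed"]]
  say("filter: %d genes -> graph (%d edges) -> MWIS of %d genes",
      ds$N, graph$n_edges, p)

  ds_p <- subset_genes(ds, cand)
  fisher_p <- fisher$fisher[cand]
  fit <- fitness_params(p, w1 = w1)

  ls_hook <- if (!is.null(ls)) {
    function(sol) local_search(sol, ds_p, fisher_p, params = ls, fit = fit)
  } else {
    NULL
  }
  aco_res <- run_aco(ds_p, fisher = fisher_p, params = aco, fit = fit,
                     ls_hook = ls_hook)
  best <- aco_res$best
  t2 <- proc.time()[["elapsed"]]
  say("search: best of %d evaluations -> %d genes, accuracy %.4f",
      aco_res$n_evaluations, best$evaluation$n_genes,
      best$evaluation$accuracy)

  pre_backward <- best$evaluation
  if (!is.null(backward) && sum(best$bits) >= 1L) {
    best <- local_search(best, ds_p, fisher_p, params = backward, fit = fit)
  }
  t3 <- proc.time()[["elapsed"]]
  say("backward: final %d genes, accuracy %.4f, fitness %.6f",
      best$evaluation$n_genes, best$evaluation$accuracy,
      best$evaluation$fitness)

  sel_local <- best$selected
  structure(
    list(r0 = r0,
         p = p,
         mwis_indices = cand,
         mwis_gene_ids = ds$gene_ids[cand],
         selected_indices = cand[sel_local],
         selected_gene_ids = ds$gene_ids[cand[sel_local]],
         accuracy = best$evaluation$accuracy,
         n_genes = best$evaluation$n_genes,
         fitness = best$evaluation$fitness,
         pre_backward = unclass(pre_backward),
         trajectory = aco_res$trajectory,
         n_evaluations = aco_res$n_evaluations,
         timings = c(filter = t1 - t0, search = t2 - t1,
                     backward = t3 - t2),
         config = list(r0 = r0, w1 = w1, aco = unclass(aco),
                       ls = if (is.null(ls)) NULL else unclass(ls),
                       backward = if (is.null(backward)) NULL else
                         unclass(backward),
                       seed = if (is.null(seed)) NA_integer_ else
                         as.integer(seed))),
    class = "RunReport"
  )
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf(paste0(
    "RunReport: r0 = %g, MWIS %d genes -> selected %d genes\n",
    "  LOOCV accuracy %.4f, fitness %.6f\n",
    "  genes: %s\n"),
    x$r0, x$p, x$n_genes, x$accuracy, x$fitness,
    paste(x$selected_gene_ids, collapse = ", ")))
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Round-trips through [jsonlite::read_json()]; numbers are written at full
#' precision.
#'
#' @param report a `RunReport`.
#' @param path output path.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "RunReport"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
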