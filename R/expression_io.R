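#' Construct an expression dataset
#'
#' Bundles an `M x N` samples-by-genes expression matrix with per-sample class
#' labels and validates the invariants every downstream stage relies on:
#' no missing values, unique gene identifiers, at least two samples per class
#' (needed for within-class standard deviations and for leave-one-out
#' cross-validation to be meaningful), `M >= 4` and `N >= 2`.
#'
#' @param matrix numeric matrix, samples in rows, genes in columns.
#' @param labels character or factor vector of length `M`; class labels are
#'   treated as opaque strings.
#' @param gene_ids character vector of `N` unique gene identifiers; defaults
#'   to the matrix column names.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `matrix`, `gene_ids`, `labels` (factor), `class_counts`, `M`, `N`, `c`.
#' @export
expression_dataset <- function(matrix, labels, gene_ids = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) {
    stop("expression matrix must be numeric", call. = FALSE)
  }
  if (anyNA(matrix)) {
    bad <- which(is.na(matrix), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing expression value at sample %d, gene %d",
                 bad[[1L]], bad[[2L]]), call. = FALSE)
  }
  M <- nrow(matrix)
  N <- ncol(matrix)
  if (M < 4L) stop("need at least 4 samples", call. = FALSE)
  if (N < 2L) stop("need at least 2 genes", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(N))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != N) {
    stop("gene_ids length must equal the number of genes", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("gene_ids must be unique", call. = FALSE)
  }
  if (length(labels) != M) {
    stop("labels length must equal the number of samples", call. = FALSE)
  }
  labels <- factor(as.character(labels))
  counts <- table(labels)
  if (nlevels(labels) < 2L) {
    stop("need at least 2 classes", call. = FALSE)
  }
  if (any(counts < 2L)) {
    small <- names(counts)[counts < 2L]
    stop(sprintf("class '%s' has fewer than 2 samples", small[[1L]]),
         call. = FALSE)
  }
  colnames(matrix) <- gene_ids
  structure(
    list(matrix = matrix, gene_ids = gene_ids, labels = labels,
         class_counts = as.integer(counts), M = M, N = N,
         c = nlevels(labels)),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d samples x %d genes, %d classes (%s)\n",
              x$M, x$N, x$c,
              paste(sprintf("%s:%d", levels(x$labels), x$class_counts),
                    collapse = ", ")))
  invisible(x)
}

#' Restrict a dataset to a subset of genes
#'
#' Keeps the gene index to gene id mapping a bijection: column `j` of the
#' result is the `subset[j]`-th gene of the input, ids included.
#'
#' @param ds an `ExpressionDataset`.
#' @param subset integer vector of gene indices (1-based) or character vector
#'   of gene ids.
#' @return An `ExpressionDataset` over the selected genes, in `subset` order.
#' @export
subset_genes <- function(ds, subset) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.character(subset)) subset <- match(subset, ds$gene_ids)
  subset <- as.integer(subset)
  if (length(subset) < 1L || anyNA(subset) ||
      any(subset < 1L | subset > ds$N)) {
    stop("invalid gene subset", call. = FALSE)
  }
  # direct construction: the parent's invariants carry over, and unlike a
  # freshly loaded dataset a restriction may legitimately hold a single gene
  out <- ds
  out$matrix <- ds$matrix[, subset, drop = FALSE]
  out$gene_ids <- ds$gene_ids[subset]
  out$N <- length(subset)
  out
}

#' Load an expression dataset from delimited text
#'
#' Reads a CSV or TSV file with a header row of gene identifiers, one row per
#' sample, and one designated label column. Gene column order is preserved and
#' defines the gene index order used in all reports.
#'
#' @param path path to the file.
#' @param label_column name of the class-label column.
#' @param delimiter `"csv"` or `"tsv"`.
#' @param impute_missing if `TRUE`, missing expression cells are replaced by
#'   the per-gene mean; the default is to reject files with missing values.
#' @param transpose if `TRUE`, the file holds genes in rows and samples in
#'   columns and is transposed after reading (the label column then names a
#'   row).
#' @return An `ExpressionDataset`.
#' @export
load_dataset <- function(path, label_column = "class",
                         delimiter = c("csv", "tsv"),
                         impute_missing = FALSE, transpose = FALSE) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  sep <- if (delimiter == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (transpose) {
    rn <- df[[1L]]
    df <- as.data.frame(t(df[, -1L, drop = FALSE]))
    colnames(df) <- rn
  }
  if (!label_column %in% colnames(df)) {
    stop(sprintf("label column '%s' not found", label_column), call. = FALSE)
  }
  labels <- as.character(df[[label_column]])
  expr <- df[, setdiff(colnames(df), label_column), drop = FALSE]
  for (j in seq_along(expr)) {
    col <- expr[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)))
      if (length(bad)) {
        stop(sprintf("non-numeric expression value at row %d, column '%s'",
                     bad[[1L]], colnames(expr)[j]), call. = FALSE)
      }
      col <- num
    }
    if (anyNA(col)) {
      if (impute_missing) {
        col[is.na(col)] <- mean(col, na.rm = TRUE)
      } else {
        stop(sprintf("missing expression value at row %d, column '%s'",
                     which(is.na(col))[[1L]], colnames(expr)[j]),
             call. = FALSE)
      }
    }
    expr[[j]] <- col
  }
  expression_dataset(as.matrix(expr), labels = labels,
                     gene_ids = colnames(expr))
}

#' Write a dataset back to delimited text
#'
#' Inverse of [load_dataset()]: full-precision values, gene order preserved.
#'
#' @param ds an `ExpressionDataset`.
#' @param path output path.
#' @param label_column name used for the label column.
#' @param delimiter `"csv"` or `"tsv"`.
#' @export
write_dataset <- function(ds, path, label_column = "class",
                          delimiter = c("csv", "tsv")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  delimiter <- match.arg(delimiter)
  sep <- if (delimiter == "csv") "," else "\t"
  df <- as.data.frame(ds$matrix, check.names = FALSE)
  df[[label_column]] <- as.character(ds$labels)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a selected-gene list
#'
#' One gene per line (`gene_id TAB fisher_score`) under a header; round-trips
#' through [read_selection()].
#'
#' @param gene_ids character vector of selected gene ids.
#' @param scores numeric vector of matching Fisher scores.
#' @param path output path.
#' @export
write_selection <- function(gene_ids, scores, path) {
  if (length(gene_ids) != length(scores)) {
    stop("gene_ids and scores must have equal length", call. = FALSE)
  }
  df <- data.frame(gene_id = as.character(gene_ids),
                   fisher_score = as.numeric(scores),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a selected-gene list written by [write_selection()]
#'
#' @param path path to the file.
#' @return data.frame with columns `gene_id` (character) and `fisher_score`.
#' @export
read_selection <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric"))
  df
}
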