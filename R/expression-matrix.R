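#' Construct an ExpressionMatrix
#'
#' The universal data container of the pipeline: a numeric genes-by-samples
#' matrix of log-scale expression values with unique gene and sample
#' identifiers carried as dimnames.
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   existing rownames).
#' @param sample_ids Character vector of unique sample identifiers (defaults
#'   to existing colnames).
#'
#' @return A numeric matrix of class `ExpressionMatrix` with `gene_ids` as
#'   rownames and `sample_ids` as colnames.
#' @export
#' @examples
#' X <- expression_matrix(matrix(1:6, 3, 2),
#'                        gene_ids = c("g1", "g2", "g3"),
#'                        sample_ids = c("s1", "s2"))
#' n_genes(X)
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x samples)")
  }
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length(gene_ids) must equal nrow(values)")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids are not allowed")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids are not allowed")
  if (!all(is.finite(values))) stop("all expression values must be finite")
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("ExpressionMatrix", class(matrix()))
  values
}

#' Accessors for ExpressionMatrix dimensions and identifiers
#'
#' @param X An `ExpressionMatrix`.
#' @return `gene_ids()` and `sample_ids()` return character vectors;
#'   `n_genes()` and `n_samples()` return integers.
#' @export
gene_ids <- function(X) rownames(X)

#' @rdname gene_ids
#' @export
sample_ids <- function(X) colnames(X)

#' @rdname gene_ids
#' @export
n_genes <- function(X) nrow(X)

#' @rdname gene_ids
#' @export
n_samples <- function(X) ncol(X)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  value range: [%.4g, %.4g]\n", min(x), max(x)))
  cat(sprintf("  genes: %s...\n", paste(utils::head(rownames(x), 4), collapse = ", ")))
  cat(sprintf("  samples: %s...\n", paste(utils::head(colnames(x), 4), collapse = ", ")))
  invisible(x)
}

#' Subset an ExpressionMatrix, preserving the class
#'
#' @param x An `ExpressionMatrix`.
#' @param i,j Row (gene) and column (sample) indices.
#' @param ... Ignored.
#' @param drop Defaults to `FALSE` so single-row/column selections stay
#'   matrices; pass `drop = TRUE` to get a plain vector.
#' @return An `ExpressionMatrix`, or a plain vector when `drop = TRUE`
#'   collapses a dimension.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ..., drop = FALSE) {
  y <- unclass(x)
  out <- if (missing(i) && missing(j)) y[, , drop = drop]
    else if (missing(i)) y[, j, drop = drop]
    else if (missing(j)) y[i, , drop = drop]
    else y[i, j, drop = drop]
  if (is.matrix(out)) class(out) <- c("ExpressionMatrix", class(matrix()))
  out
}

as_plain_matrix <- function(X) {
  class(X) <- class(matrix())
  X
}

stopifnot_aligned <- function(G, G_hat) {
  if (!identical(dim(G), dim(G_hat))) {
    stop("matrices must have identical dimensions")
  }
  if (!identical(rownames(G), rownames(G_hat))) {
    stop("gene_ids must be identical and in the same order")
  }
  if (!identical(colnames(G), colnames(G_hat))) {
    stop("sample_ids must be identical and in the same order")
  }
  invisible(TRUE)
}
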