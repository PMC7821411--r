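#' Read an expression matrix from TSV, CSV, or GCT v1.2
#'
#' On-disk orientation is genes as rows and samples as columns: the first
#' column holds gene identifiers and the header row holds sample identifiers.
#' GCT v1.2 files carry a `#1.2` version line, a dimensions line, and
#' `Name`/`Description` identifier columns.
#'
#' @param path File path.
#' @param format One of `"auto"` (by extension), `"tsv"`, `"csv"`, `"gct"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "gct")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gct = "gct", csv = "csv", "tsv")
  }
  if (format == "gct") return(read_gct(path))
  sep <- if (format == "csv") "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  expression_matrix(vals, gene_ids = ids, sample_ids = colnames(dt)[-1])
}

#' Write an expression matrix to TSV, CSV, or GCT v1.2
#'
#' @param X An `ExpressionMatrix`.
#' @inheritParams read_expression
#' @return `path`, invisibly.
#' @export
write_expression <- function(X, path, format = c("auto", "tsv", "csv", "gct")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gct = "gct", csv = "csv", "tsv")
  }
  if (format == "gct") return(write_gct(X, path))
  sep <- if (format == "csv") "," else "\t"
  dt <- data.table::data.table(gene_id = rownames(X))
  dt <- cbind(dt, data.table::as.data.table(as_plain_matrix(X)))
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

read_gct <- function(path) {
  lines <- readLines(path, n = 2L)
  if (!grepl("^#1\\.2", lines[1])) stop("not a GCT v1.2 file: missing #1.2 header")
  dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
  dt <- data.table::fread(path, sep = "\t", header = TRUE, skip = 2L,
                          data.table = FALSE)
  if (!identical(toupper(colnames(dt)[1:2]), c("NAME", "DESCRIPTION"))) {
    stop("GCT v1.2 requires Name and Description columns")
  }
  vals <- as.matrix(dt[, -(1:2), drop = FALSE])
  if (nrow(vals) != dims[1] || ncol(vals) != dims[2]) {
    stop(sprintf("GCT dimension line says %d x %d but body is %d x %d",
                 dims[1], dims[2], nrow(vals), ncol(vals)))
  }
  expression_matrix(vals, gene_ids = as.character(dt[[1]]),
                    sample_ids = colnames(dt)[-(1:2)])
}

write_gct <- function(X, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(X), ncol(X), sep = "\t")), con)
  header <- paste(c("Name", "Description", colnames(X)), collapse = "\t")
  writeLines(header, con)
  body <- cbind(rownames(X), "na",
                format(as_plain_matrix(X), trim = TRUE, digits = 15,
                       scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read or write a ranked gene list (one identifier per line)
#'
#' The plain-text exchange format for landmark sets: one gene identifier per
#' line, in rank order.
#'
#' @param path File path.
#' @return `read_gene_list()` returns a character vector in file order.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' @rdname read_gene_list
#' @param ids Character vector of gene identifiers, already in rank order, or
#'   a `LandmarkSet`.
#' @export
write_gene_list <- function(ids, path) {
  if (inherits(ids, "LandmarkSet")) ids <- ids$gene_ids
  writeLines(as.character(ids), path)
  invisible(path)
}
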