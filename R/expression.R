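#' Construct an expression matrix object
#'
#' Wraps a numeric genes-by-samples matrix of log-scale expression values
#' together with a flag recording whether gene rows have been mean-centered.
#' Values are assumed to be already log-transformed; no transformation is
#' applied here.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty row and column names.
#' @param centered Logical; `TRUE` if every gene row already has zero mean.
#' @return An object of class `optica_expr` with elements `values` and
#'   `centered`.
#' @export
expression_matrix <- function(values, centered = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must have gene row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifier", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifier", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite value in expression matrix", call. = FALSE)
  structure(list(values = values, centered = isTRUE(centered)),
            class = "optica_expr")
}

#' @export
print.optica_expr <- function(x, ...) {
  cat(sprintf("<optica_expr> %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (x$centered) ", gene-centered" else ""))
  invisible(x)
}

#' @export
dim.optica_expr <- function(x) dim(x$values)

#' @export
as.matrix.optica_expr <- function(x, ...) x$values

guess_delimiter <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene expression matrix from delimited text
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers.  The values must be finite numbers (log-scale expression);
#' any `NA`, non-numeric cell, or duplicated identifier is an error.  The
#' delimiter is inferred from the file extension (`.csv` comma, otherwise
#' tab) unless given explicitly.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects from the
#'   extension.
#' @return An [expression_matrix()] object (`centered = FALSE`).
#' @export
read_expression <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delimiter <- delimiter %||% guess_delimiter(path)
  df <- read.delim(path, sep = delimiter, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene id column plus samples", call. = FALSE)
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifier", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-finite value: expression cells must be numeric", call. = FALSE)
  if (!all(is.finite(m))) stop("non-finite value in expression matrix", call. = FALSE)
  rownames(m) <- gene_ids
  expression_matrix(m)
}

#' Write an expression matrix to delimited text
#'
#' Values are written at full double precision so that
#' `read_expression(write_expression(x))` round-trips bit-identically.
#'
#' @param x An [expression_matrix()] object.
#' @param path Output file path.
#' @param delimiter Field delimiter; `NULL` auto-detects from the extension.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delimiter = NULL) {
  stopifnot(inherits(x, "optica_expr"))
  delimiter <- delimiter %||% guess_delimiter(path)
  write_labeled_matrix(x$values, path, delimiter, id_col = "gene_id")
  invisible(path)
}

## Full-precision labeled matrix writer shared by all matrix artifacts.
write_labeled_matrix <- function(m, path, delimiter = ",", id_col = "id") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- paste(c(id_col, colnames(m)), collapse = delimiter)
  writeLines(header, con)
  if (nrow(m) > 0L) {
    body <- vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = delimiter)
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

read_labeled_matrix <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = delimiter, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(df) == 0L) m <- matrix(numeric(0), 0L, ncol(df) - 1L,
                                  dimnames = list(NULL, colnames(df)[-1L]))
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Mean-center each gene across samples
#'
#' Subtracts the row (gene) mean from every value so each gene has zero mean
#' across samples; the operation is idempotent and preserves gene and sample
#' order.  Centering is required before ICA so that the PCA whitening step
#' behaves; correlation- and cosine-based metrics downstream are unaffected
#' by the removed offset.
#'
#' @param x An [expression_matrix()] object.
#' @return The centered [expression_matrix()] with `centered = TRUE`.
#' @export
center_genes <- function(x) {
  stopifnot(inherits(x, "optica_expr"))
  v <- x$values - rowMeans(x$values)
  expression_matrix(v, centered = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
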