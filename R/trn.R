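#' Construct a regulon database
#'
#' A regulon database maps each transcriptional regulator to its set of
#' target genes, over a fixed gene universe.  Regulon genes outside the
#' universe are dropped; regulators left with no gene in the universe are
#' removed with a warning.
#'
#' @param regulons Named list of character vectors (regulator -> gene ids).
#' @param universe Character vector of all gene ids under consideration.
#' @return An object of class `optica_regulons` with elements `regulons`
#'   (named list of unique gene-id vectors) and `universe`.
#' @export
regulon_db <- function(regulons, universe) {
  stopifnot(is.list(regulons), length(names(regulons)) == length(regulons))
  universe <- unique(as.character(universe))
  regulons <- lapply(regulons, function(g) unique(as.character(g)))
  kept <- lapply(regulons, function(g) intersect(g, universe))
  empty <- lengths(kept) == 0L
  if (any(empty)) {
    warning("dropping regulators with no genes in universe: ",
            paste(names(kept)[empty], collapse = ", "), call. = FALSE)
    kept <- kept[!empty]
  }
  if (length(kept) == 0L) stop("no regulon has genes in the universe", call. = FALSE)
  structure(list(regulons = kept, universe = universe), class = "optica_regulons")
}

#' @export
print.optica_regulons <- function(x, ...) {
  cat(sprintf("<optica_regulons> %d regulons over %d genes (sizes %d-%d)\n",
              length(x$regulons), length(x$universe),
              min(lengths(x$regulons)), max(lengths(x$regulons))))
  invisible(x)
}

#' Read a transcriptional regulatory network
#'
#' Accepts either a two-column delimited table with a header (regulator,
#' gene) or a GMT gene-set file (set name, description, genes...).  GMT is
#' assumed when the file extension is `.gmt`.
#'
#' @param path Path to the TRN file.
#' @param universe Character vector of gene ids; regulon membership is
#'   restricted to this universe.
#' @param delimiter Delimiter for the two-column format; `NULL` auto-detects
#'   from the extension.
#' @return An [regulon_db()] object.
#' @export
read_trn <- function(path, universe, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty TRN file", call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(fields) < 3L
    if (any(bad)) stop("unparseable GMT line: ", which(bad)[1L], call. = FALSE)
    regs <- lapply(fields, function(f) f[-(1:2)])
    names(regs) <- vapply(fields, `[[`, character(1), 1L)
  } else {
    delimiter <- delimiter %||% guess_delimiter(path)
    df <- read.delim(path, sep = delimiter, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("empty TRN file", call. = FALSE)
    if (ncol(df) < 2L) stop("TRN table needs regulator and gene columns", call. = FALSE)
    regs <- split(as.character(df[[2L]]), as.character(df[[1L]]))
  }
  regulon_db(regs, universe)
}

#' Write a regulon database as a two-column regulator-gene table
#'
#' @param db An [regulon_db()] object.
#' @param path Output path.
#' @param delimiter Field delimiter; `NULL` auto-detects from the extension.
#' @return `path`, invisibly.
#' @export
write_trn <- function(db, path, delimiter = NULL) {
  stopifnot(inherits(db, "optica_regulons"))
  delimiter <- delimiter %||% guess_delimiter(path)
  df <- tibble::tibble(
    regulator = rep(names(db$regulons), lengths(db$regulons)),
    gene = unlist(db$regulons, use.names = FALSE)
  )
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}
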