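#' Run the full decomposition-and-selection pipeline
#'
#' Chains the whole workflow: read (or accept) an expression compendium,
#' mean-center genes, scan a grid of ICA dimensionalities with robust
#' multi-restart decompositions, build the dimensionality tree, profile
#' conservation against the largest decomposition, classify components,
#' and apply the three dimensionality-selection rules.  All randomness
#' derives from `cfg$base_seed`, so re-running with an identical
#' configuration reproduces every output file bit-identically.  A regulon
#' database is optional: without one the regulatory columns are absent
#' and the OptICA dimension is still reported, since the selection needs
#' no prior knowledge of the true regulatory network.
#'
#' @param x An [expression_matrix()] or a path to a delimited expression
#'   file.
#' @param out_dir Output directory; receives `summary.csv`, `tree.json`,
#'   `conservation.csv`, `enrichments.csv` (when a TRN is given),
#'   `selection.json`, and `config.json`.  `NULL` writes nothing.
#' @param db Optional [regulon_db()] or path to a TRN file.
#' @param cfg An [optica_config()].
#' @param step,min_dim,max_dim_offset Grid parameters (see [make_grid()]).
#' @param cache_dir Optional per-dimension cache directory.
#' @return An object of class `optica_pipeline`: the `scan`, `summaries`,
#'   `tree`, `selection`, and `cfg`, invisibly when writing to disk.
#' @export
run_pipeline <- function(x, out_dir = NULL, db = NULL, cfg = optica_config(),
                         step = 5L, min_dim = 2L, max_dim_offset = 2L,
                         cache_dir = NULL) {
  if (is.character(x)) x <- read_expression(x)
  stopifnot(inherits(x, "optica_expr"))
  if (is.character(db)) db <- read_trn(db, rownames(x$values))
  grid <- make_grid(ncol(x$values), step = step, min_dim = min_dim,
                    max_dim_offset = max_dim_offset)
  message(sprintf("scanning %d dimensions: %s", length(grid$dims),
                  paste(range(grid$dims), collapse = "..")))
  scan <- run_scan(x, grid, cfg, mode = "conserved", cache_dir = cache_dir)
  summaries <- summarize_scan(scan, db = db)
  tree <- build_tree(scan, threshold = cfg$adjacency_threshold)
  selection <- select_dimensions(summaries, scan$expr, cfg)
  res <- structure(list(scan = scan, summaries = summaries, tree = tree,
                        selection = selection, cfg = cfg),
                   class = "optica_pipeline")
  if (!is.null(out_dir)) {
    write_pipeline(res, out_dir)
    return(invisible(res))
  }
  res
}

#' Write every pipeline artifact to a directory
#'
#' @param res An `optica_pipeline` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(res, out_dir) {
  stopifnot(inherits(res, "optica_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_summary_csv(res$summaries, file.path(out_dir, "summary.csv"))
  write_tree_json(res$tree, file.path(out_dir, "tree.json"))
  cons <- conservation_table(attr(res$summaries, "profile"))
  utils::write.table(
    dplyr::mutate(cons, best_correlation = sprintf("%.17g", .data$best_correlation)),
    file.path(out_dir, "conservation.csv"),
    sep = ",", quote = FALSE, row.names = FALSE)
  comps <- attr(res$summaries, "components")
  if (!is.null(comps) && "q_value" %in% names(comps)) {
    num <- intersect(c("p_value", "q_value", "precision", "recall", "f1",
                       "stability"), names(comps))
    comps_out <- dplyr::mutate(comps, dplyr::across(dplyr::all_of(num),
                                                    ~ sprintf("%.17g", .x)))
    utils::write.table(comps_out, file.path(out_dir, "enrichments.csv"),
                       sep = ",", quote = FALSE, row.names = FALSE)
  }
  sel <- res$selection
  jsonlite::write_json(
    list(optica_dim = sel$optica_dim,
         pcva_dim = sel$pcva_dim,
         mstd_dim = if (is.na(sel$mstd_dim)) NULL else sel$mstd_dim,
         conserved_threshold = sel$threshold,
         curves = sel$curves),
    file.path(out_dir, "selection.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(unclass(res$cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

write_summary_csv <- function(summaries, path) {
  cols <- c("dimension", "n_robust", "n_single_gene", "n_non_single_gene",
            "n_regulatory", "n_conserved", "mean_f1", "sd_f1", "stable_fraction")
  s <- dplyr::select(tibble::as_tibble(summaries), dplyr::any_of(cols))
  s <- dplyr::mutate(s, dplyr::across(dplyr::where(is.double),
                                      ~ ifelse(is.na(.x), NA, sprintf("%.17g", .x))))
  utils::write.table(s, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.optica_pipeline <- function(x, ...) {
  print(x$scan)
  print(x$selection)
  invisible(x)
}
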