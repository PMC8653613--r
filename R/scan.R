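#' Pipeline configuration
#'
#' Collects every tunable of the decomposition pipeline with defaults at
#' the published operating point: 100 FastICA restarts at tolerance 1e-7,
#' DBSCAN epsilon 0.1 with a minimum cluster seed of half the restarts,
#' a 0.3 tree-adjacency threshold, enrichment FDR 1e-5, and a 99%
#' cumulative-variance target for the PCA baseline.
#'
#' @param n_runs Number of FastICA restarts per dimension.
#' @param tol FastICA convergence tolerance.
#' @param max_iter Maximum FastICA iterations per restart.
#' @param dbscan_eps DBSCAN neighbourhood radius on the `1 - |rho|` distance.
#' @param min_cluster_frac Minimum cluster seed size as a fraction of
#'   `n_runs` (ceiling applied), so reduced-restart configurations keep the
#'   published 50-of-100 proportion.
#' @param adjacency_threshold Minimum absolute-cosine correlation for a
#'   dimensionality-tree edge.
#' @param fdr FDR cutoff for calling a component regulatory.
#' @param kmeans_k Number of 1-D k-means clusters for significant-gene
#'   extraction (top two clusters are kept).
#' @param pcva_target Cumulative explained-variance target for the PCA
#'   baseline selector.
#' @param mstd_stability_cutoff Per-component stability above which a
#'   robust component counts as stable.
#' @param mstd_drop_cutoff Stable-component fraction below which a
#'   dimension counts as unstable.
#' @param base_seed Integer seed; all randomness derives from it.
#' @param center Logical; mean-center genes before ICA.
#' @return A named list of class `optica_config`.
#' @export
optica_config <- function(n_runs = 100L, tol = 1e-7, max_iter = 200L,
                          dbscan_eps = 0.1, min_cluster_frac = 0.5,
                          adjacency_threshold = 0.3, fdr = 1e-5,
                          kmeans_k = 3L, pcva_target = 0.99,
                          mstd_stability_cutoff = 0.8, mstd_drop_cutoff = 0.5,
                          base_seed = 42L, center = TRUE) {
  cfg <- list(n_runs = as.integer(n_runs), tol = tol, max_iter = as.integer(max_iter),
              dbscan_eps = dbscan_eps, min_cluster_frac = min_cluster_frac,
              adjacency_threshold = adjacency_threshold, fdr = fdr,
              kmeans_k = as.integer(kmeans_k), pcva_target = pcva_target,
              mstd_stability_cutoff = mstd_stability_cutoff,
              mstd_drop_cutoff = mstd_drop_cutoff,
              base_seed = as.integer(base_seed), center = isTRUE(center))
  stopifnot(cfg$n_runs >= 1L, cfg$tol > 0, cfg$dbscan_eps > 0,
            cfg$min_cluster_frac > 0, cfg$min_cluster_frac <= 1)
  class(cfg) <- "optica_config"
  cfg
}

#' Build the dimensionality grid for a scan
#'
#' Dimensions run from `min_dim` up to `n_samples - max_dim_offset` in
#' steps of `step`; the final (near-full) dimension is always included
#' even when it is off-step, because conserved-component classification is
#' defined relative to the largest decomposition.
#'
#' @param n_samples Number of samples in the compendium (>= 4).
#' @param step Grid spacing (default 1).
#' @param min_dim Smallest dimension (default 2).
#' @param max_dim_offset Offset below `n_samples` for the final dimension
#'   (default 2).
#' @return An object of class `optica_grid` with elements `dims`, `step`,
#'   `max_dim`.
#' @export
make_grid <- function(n_samples, step = 1L, min_dim = 2L, max_dim_offset = 2L) {
  n_samples <- as.integer(n_samples)
  step <- as.integer(step)
  min_dim <- as.integer(min_dim)
  if (n_samples < 4L) stop("need at least 4 samples", call. = FALSE)
  if (step <= 0L) stop("step must be positive", call. = FALSE)
  if (min_dim < 2L) stop("min_dim must be at least 2", call. = FALSE)
  final <- n_samples - as.integer(max_dim_offset)
  if (min_dim >= n_samples || min_dim > final) {
    stop("min_dim too large for the sample count", call. = FALSE)
  }
  dims <- seq.int(min_dim, final, by = step)
  if (dims[length(dims)] != final) dims <- c(dims, final)
  structure(list(dims = as.integer(dims), step = step, max_dim = final),
            class = "optica_grid")
}

config_fingerprint <- function(cfg, x, dimension) {
  paste(format(c(cfg$n_runs, cfg$tol, cfg$max_iter, cfg$dbscan_eps,
                 cfg$min_cluster_frac, cfg$base_seed, dimension,
                 nrow(x$values), ncol(x$values), sum(x$values)),
               digits = 17), collapse = "|")
}

scan_one_dimension <- function(x, dimension, cfg, svd, cache_dir) {
  if (!is.null(cache_dir)) {
    dir <- file.path(cache_dir, sprintf("dim_%d", dimension))
    fp_file <- file.path(dir, "fingerprint.txt")
    fp <- config_fingerprint(cfg, x, dimension)
    if (file.exists(fp_file) && identical(readLines(fp_file, warn = FALSE)[1L], fp)) {
      return(read_decomposition(dir))
    }
    d <- robust_decomposition(x, dimension, cfg, svd = svd)
    write_decomposition(d, dir)
    writeLines(fp, fp_file)
    return(d)
  }
  robust_decomposition(x, dimension, cfg, svd = svd)
}

#' Scan a grid of ICA dimensionalities
#'
#' Computes a robust decomposition at every grid dimension, in ascending
#' order.  In `"conserved"` mode (default) the final grid dimension is
#' decomposed first, since conserved components are defined against the
#' largest decomposition; in `"online"` mode conservation is assessed
#' against the highest dimension computed so far.  An optional `stop_rule`
#' callback receives the running per-dimension summary tibble after each
#' ascending dimension and can halt the scan early by returning `TRUE`;
#' early stopping never changes results at completed dimensions.
#'
#' Completed dimensions can be cached on disk (`cache_dir`); a cached
#' decomposition is reused only when the configuration and data
#' fingerprint match, so cached and fresh scans are bit-identical.
#'
#' @param x An [expression_matrix()]; centered automatically unless
#'   `cfg$center` is `FALSE`.
#' @param grid An [make_grid()] grid.
#' @param cfg An [optica_config()].
#' @param mode `"conserved"` or `"online"`.
#' @param stop_rule Optional `function(summaries) -> logical(1)`.
#' @param cache_dir Optional directory for per-dimension caching.
#' @param db Optional [regulon_db()] used when `stop_rule` needs
#'   regulatory classification.
#' @return An object of class `optica_scan`: named list `decompositions`
#'   (by dimension), the `grid`, `cfg`, the (possibly centered) expression
#'   matrix `expr`, and `completed` dimensions in computation order.
#' @export
run_scan <- function(x, grid, cfg = optica_config(),
                     mode = c("conserved", "online"),
                     stop_rule = NULL, cache_dir = NULL, db = NULL) {
  stopifnot(inherits(x, "optica_expr"), inherits(grid, "optica_grid"))
  mode <- match.arg(mode)
  if (cfg$center && !x$centered) x <- center_genes(x)
  if (grid$max_dim > min(dim(x$values))) {
    stop("grid exceeds min(genes, samples)", call. = FALSE)
  }
  sv <- whiten_svd(x$values)
  dims <- grid$dims
  final <- dims[length(dims)]
  decomps <- list()
  completed <- integer(0)

  if (mode == "conserved") {
    decomps[[as.character(final)]] <- scan_one_dimension(x, final, cfg, sv, cache_dir)
    completed <- final
  }
  for (d in dims) {
    key <- as.character(d)
    if (!is.null(decomps[[key]])) next
    decomps[[key]] <- scan_one_dimension(x, d, cfg, sv, cache_dir)
    completed <- c(completed, d)
    if (!is.null(stop_rule)) {
      scan_now <- new_scan(decomps, grid, cfg, x)
      summaries <- summarize_scan(scan_now, db = db)
      if (isTRUE(stop_rule(summaries))) break
    }
  }
  new_scan(decomps, grid, cfg, x, completed)
}

new_scan <- function(decomps, grid, cfg, x, completed = NULL) {
  ord <- order(as.integer(names(decomps)))
  structure(list(decompositions = decomps[ord], grid = grid, cfg = cfg,
                 expr = x, completed = completed),
            class = "optica_scan")
}

#' @export
print.optica_scan <- function(x, ...) {
  dims <- as.integer(names(x$decompositions))
  cat(sprintf("<optica_scan> %d dimensions (%d..%d), %s robust components\n",
              length(dims), min(dims), max(dims),
              paste(vapply(x$decompositions, function(d) ncol(d$M), integer(1)),
                    collapse = "/")))
  invisible(x)
}

scan_dims <- function(scan) as.integer(names(scan$decompositions))
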