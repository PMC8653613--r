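#' Sign-invariant distance between two components
#'
#' Distance `d = 1 - |rho|`, where `rho` is the Pearson correlation between
#' the two gene-weight vectors.  The absolute value makes the metric
#' invariant to the arbitrary sign of ICA components: a component and its
#' negation are at distance 0.
#'
#' @param x,y Numeric gene-weight vectors of equal length (>= 2), neither
#'   constant.
#' @return A value in `[0, 1]`.
#' @export
component_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: constant vector", call. = FALSE)
  max(0, min(1, 1 - abs(cor(x, y))))
}

## Pairwise 1 - |cor| distance matrix for component rows.
component_distance_matrix <- function(rows) {
  D <- 1 - abs(cor(t(rows)))
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

## DBSCAN on a precomputed distance matrix.  Neighbourhoods include the
## point itself (scikit-learn convention), so a point is core when at
## least min_pts points lie within eps.  Border points join the first
## cluster that reaches them; noise points get label 0.
dbscan_precomputed <- function(D, eps, min_pts) {
  n <- nrow(D)
  if (n == 0L) return(integer(0))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    stack <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(stack) > 0L) {
      p <- stack[[1L]]
      stack <- stack[-1L]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) labels[q] <- cl
        if (core[q] && !visited[q]) {
          visited[q] <- TRUE
          stack <- c(stack, q)
        }
      }
    }
  }
  labels
}

#' Density-cluster raw ICA components into reproducible groups
#'
#' Clusters the pooled components of all restarts with DBSCAN on the
#' sign-invariant `1 - |Pearson|` distance matrix.  Components that recur
#' in at least `min_cluster` restarts form a dense cluster; everything
#' else is noise and discarded.
#'
#' @param raw An `optica_raw_components` object from [run_multistart_ica()].
#' @param eps DBSCAN neighbourhood radius on the distance (default 0.1).
#' @param min_cluster Minimum neighbourhood size for a core point
#'   (default: half of the restarts that produced `raw`, rounded up).
#' @return A list of integer vectors (row indices into `raw$components`),
#'   ordered by decreasing cluster size (ties: smaller first row index).
#' @export
cluster_robust_components <- function(raw, eps = 0.1,
                                      min_cluster = ceiling(0.5 * raw$n_runs)) {
  stopifnot(inherits(raw, "optica_raw_components"))
  if (nrow(raw$components) == 0L) return(list())
  D <- component_distance_matrix(raw$components)
  labels <- dbscan_precomputed(D, eps, min_cluster)
  if (all(labels == 0L)) return(list())
  clusters <- split(seq_along(labels)[labels > 0L], labels[labels > 0L])
  ord <- order(-lengths(clusters), vapply(clusters, min, integer(1)))
  unname(clusters[ord])
}

#' Cluster centroid with sign alignment
#'
#' The first member (stable row order) defines the canonical direction;
#' every member with negative Pearson correlation to it is flipped before
#' taking the element-wise mean, so identical components of opposite sign
#' reinforce rather than cancel.
#'
#' @param rows Numeric matrix whose rows are the cluster's member
#'   components (at least one row).
#' @return The centroid gene-weight vector.
#' @export
centroid_with_sign_alignment <- function(rows) {
  if (is.vector(rows)) rows <- matrix(rows, nrow = 1L)
  stopifnot(nrow(rows) >= 1L)
  canonical <- rows[1L, ]
  if (nrow(rows) > 1L) {
    flip <- as.vector(cor(canonical, t(rows))) < 0
    flip[is.na(flip)] <- FALSE
    rows[flip, ] <- -rows[flip, , drop = FALSE]
  }
  colMeans(rows)
}

## Moore-Penrose pseudoinverse via SVD.
pinv <- function(M, tol = NULL) {
  if (length(M) == 0L) return(matrix(numeric(0), ncol(M), nrow(M)))
  s <- svd(M)
  tol <- tol %||% (max(dim(M)) * max(s$d) * .Machine$double.eps)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Robust ICA decomposition at one dimensionality
#'
#' Runs multi-restart FastICA, clusters the pooled components with DBSCAN
#' on the sign-invariant correlation distance, and defines the robust
#' components as the sign-aligned centroids of the clusters.  Activities
#' are recovered by least-squares projection `A = pinv(M) X` onto the
#' centered data.  The whole procedure is deterministic given `base_seed`.
#'
#' @param x A gene-centered [expression_matrix()] (uncentered input is
#'   centered on the fly with a message).
#' @param dimension Requested number of components.
#' @param cfg An [optica_config()] list of tunables.
#' @param svd Optional precomputed `whiten_svd` result (shared in scans).
#' @return An object of class `optica_decomposition` with elements
#'   `dimension` (requested), `M` (genes x k_robust centroid weights), `A`
#'   (k_robust x samples activities), `cluster_sizes`, `stability` (mean
#'   `|cor|` of members to their centroid), `sample_offsets` (per-sample
#'   gene means removed by whitening; the model is
#'   `X ~ M A + 1 sample_offsets'`), and restart bookkeeping.
#' @export
robust_decomposition <- function(x, dimension, cfg = optica_config(), svd = NULL) {
  stopifnot(inherits(x, "optica_expr"))
  if (!x$centered) {
    message("centering genes before ICA")
    x <- center_genes(x)
  }
  raw <- run_multistart_ica(x, dimension,
                            n_runs = cfg$n_runs, tol = cfg$tol,
                            base_seed = cfg$base_seed, max_iter = cfg$max_iter,
                            svd = svd)
  min_cluster <- ceiling(cfg$min_cluster_frac * cfg$n_runs)
  clusters <- cluster_robust_components(raw, eps = cfg$dbscan_eps,
                                        min_cluster = min_cluster)
  if (length(clusters) > dimension) {
    warning(sprintf("more clusters (%d) than requested dimension (%d); keeping the largest",
                    length(clusters), dimension), call. = FALSE)
    clusters <- clusters[seq_len(dimension)]
  }
  k <- length(clusters)
  n_genes <- nrow(x$values)
  M <- matrix(numeric(0), n_genes, 0L)
  stability <- numeric(0)
  if (k > 0L) {
    cents <- lapply(clusters, function(idx) {
      centroid_with_sign_alignment(raw$components[idx, , drop = FALSE])
    })
    M <- do.call(cbind, cents)
    stability <- vapply(seq_len(k), function(j) {
      mean(abs(cor(cents[[j]], t(raw$components[clusters[[j]], , drop = FALSE]))))
    }, numeric(1))
  }
  rownames(M) <- rownames(x$values)
  colnames(M) <- sprintf("comp_%03d", seq_len(k) - 1L)
  A <- pinv(M) %*% x$values
  rownames(A) <- colnames(M)
  colnames(A) <- colnames(x$values)
  structure(list(dimension = as.integer(dimension),
                 M = M, A = A,
                 cluster_sizes = lengths(clusters),
                 stability = stability,
                 sample_offsets = colMeans(x$values),
                 n_runs = raw$n_runs,
                 n_runs_converged = raw$n_runs_converged),
            class = "optica_decomposition")
}

#' @export
print.optica_decomposition <- function(x, ...) {
  cat(sprintf("<optica_decomposition> dimension %d: %d robust components (%d/%d restarts converged)\n",
              x$dimension, ncol(x$M), x$n_runs_converged, x$n_runs))
  invisible(x)
}

#' Write a decomposition to a directory
#'
#' Writes `M.csv` (genes x components) and `A.csv` (components x samples)
#' plus a small `meta.json`, at full double precision so the matching
#' reader round-trips bit-identically.
#'
#' @param d An `optica_decomposition`.
#' @param out_dir Directory to create/write into.
#' @return `out_dir`, invisibly.
#' @export
write_decomposition <- function(d, out_dir) {
  stopifnot(inherits(d, "optica_decomposition"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_labeled_matrix(d$M, file.path(out_dir, "M.csv"), ",", id_col = "gene_id")
  write_labeled_matrix(d$A, file.path(out_dir, "A.csv"), ",", id_col = "component")
  meta <- list(dimension = d$dimension,
               cluster_sizes = as.integer(d$cluster_sizes),
               stability = d$stability,
               sample_offsets = as.list(d$sample_offsets),
               n_runs = d$n_runs,
               n_runs_converged = d$n_runs_converged)
  jsonlite::write_json(meta, file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a decomposition written by [write_decomposition()]
#'
#' @param out_dir Directory containing `M.csv`, `A.csv` and `meta.json`.
#' @return An `optica_decomposition`.
#' @export
read_decomposition <- function(out_dir) {
  M <- read_labeled_matrix(file.path(out_dir, "M.csv"), ",")
  A <- read_labeled_matrix(file.path(out_dir, "A.csv"), ",")
  meta <- jsonlite::read_json(file.path(out_dir, "meta.json"), simplifyVector = TRUE)
  structure(list(dimension = as.integer(meta$dimension),
                 M = M, A = A,
                 cluster_sizes = as.integer(meta$cluster_sizes),
                 stability = as.numeric(meta$stability),
                 sample_offsets = unlist(meta$sample_offsets),
                 n_runs = as.integer(meta$n_runs),
                 n_runs_converged = as.integer(meta$n_runs_converged)),
            class = "optica_decomposition")
}
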