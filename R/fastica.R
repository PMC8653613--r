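## Symmetric (parallel-extraction) FastICA with the logcosh contrast.
##
## The decomposition convention follows the iModulon literature: the data
## matrix X (genes x samples) is modelled as X = M A, where columns of M
## (genes x k) are independent gene-weight sources and A (k x samples)
## holds condition-dependent activities.  Genes play the role of
## observations, samples the role of variables; the sources are the
## non-Gaussian distributions of gene weights.

## PCA-whitening of the samples dimension.  Columns of the returned Z
## (genes x dim) are zero-mean with identity covariance (1/n scaling).
## The SVD depends only on the data, so it is computed once per matrix
## and shared across restarts and dimensionalities.
whiten_svd <- function(values) {
  xc <- sweep(values, 2L, colMeans(values))
  svd(xc, nv = 0L)
}

whitened_components <- function(sv, dimension, n_genes) {
  d <- sv$d[seq_len(dimension)]
  rel <- d / max(sv$d[1L], .Machine$double.xmin)
  if (any(rel < 1e-12)) {
    stop("requested dimension exceeds the numerical rank of the matrix",
         call. = FALSE)
  }
  sv$u[, seq_len(dimension), drop = FALSE] * sqrt(n_genes)
}

## W <- W (W'W)^{-1/2}
sym_decorrelate <- function(W) {
  e <- eigen(crossprod(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  W %*% (e$vectors %*% (t(e$vectors) / sqrt(vals)))
}

## One FastICA run on whitened data Z (n x k).  Returns the orthogonal
## unmixing matrix and a convergence flag; convergence is measured as
## max_i | |<w_i^new, w_i^old>| - 1 | < tol.
fastica_run <- function(Z, seed, tol = 1e-7, max_iter = 1000L) {
  n <- nrow(Z)
  k <- ncol(Z)
  W <- with_seed(seed, matrix(rnorm(k * k), k, k))
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    S <- Z %*% W
    G <- tanh(S)
    gp <- colMeans(1 - G * G)
    W1 <- crossprod(Z, G) / n - sweep(W, 2L, gp, `*`)
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(colSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(W = W, converged = converged, iterations = it)
}

#' Multi-restart FastICA component extraction
#'
#' Runs symmetric FastICA (logcosh contrast, PCA whitening) `n_runs` times
#' with seeds derived deterministically from `base_seed`, at a single
#' requested dimensionality.  Each run contributes `dimension` gene-weight
#' components (rows).  Restarts that fail to converge within `max_iter`
#' iterations are retried once with a fresh derived seed; if the retry
#' also fails, its components are kept anyway with a warning and counted
#' in `n_runs_unconverged`.  Beyond the true model order the whitened
#' space contains near-Gaussian directions on which the symmetric update
#' cannot formally converge, yet the non-Gaussian source directions in
#' such runs are still well estimated — discarding whole runs there would
#' empty exactly the over-decomposed dimensions whose component census the
#' dimensionality selection needs.
#'
#' @param x A gene-centered [expression_matrix()].
#' @param dimension Number of components to extract (2 to
#'   `min(genes, samples)`).
#' @param n_runs Number of random restarts (default 100).
#' @param tol Convergence tolerance on the unmixing update (default 1e-7).
#' @param base_seed Integer seed from which all per-run seeds are derived.
#' @param max_iter Maximum FastICA iterations per restart (default 200).
#' @param svd Optional precomputed `whiten_svd(x$values)` result, reused
#'   across dimensions in a scan.
#' @return A list of class `optica_raw_components`: `components` (rows =
#'   components, columns = genes), `run_ids` (restart index per row),
#'   `dimension`, `n_runs_converged`.
#' @export
run_multistart_ica <- function(x, dimension, n_runs = 100L, tol = 1e-7,
                               base_seed = 42L, max_iter = 200L, svd = NULL) {
  stopifnot(inherits(x, "optica_expr"))
  if (!x$centered) stop("expression matrix must be gene-centered before ICA", call. = FALSE)
  n_genes <- nrow(x$values)
  n_samples <- ncol(x$values)
  dimension <- as.integer(dimension)
  if (dimension < 2L) stop("dimension must be at least 2", call. = FALSE)
  if (dimension > min(n_genes, n_samples)) {
    stop("dimension exceeds min(genes, samples)", call. = FALSE)
  }
  sv <- svd %||% whiten_svd(x$values)
  Z <- whitened_components(sv, dimension, n_genes)

  rows <- vector("list", n_runs)
  run_ids <- vector("list", n_runs)
  n_conv <- 0L
  for (r in seq_len(n_runs)) {
    fit <- fastica_run(Z, derive_seed(base_seed, dimension, r, 1L), tol, max_iter)
    if (!fit$converged) {
      fit <- fastica_run(Z, derive_seed(base_seed, dimension, r, 2L), tol, max_iter)
    }
    if (fit$converged) {
      n_conv <- n_conv + 1L
    } else {
      warning(sprintf("restart %d at dimension %d did not converge; keeping its components",
                      r, dimension), call. = FALSE)
    }
    rows[[r]] <- t(Z %*% fit$W)
    run_ids[[r]] <- rep(r, dimension)
  }
  comp <- do.call(rbind, rows)
  if (is.null(comp)) comp <- matrix(numeric(0), 0L, n_genes)
  colnames(comp) <- rownames(x$values)
  structure(list(components = comp,
                 run_ids = unlist(run_ids) %||% integer(0),
                 dimension = dimension,
                 n_runs = n_runs,
                 n_runs_converged = n_conv),
            class = "optica_raw_components")
}
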