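#' Absolute-cosine correlation between components
#'
#' Components computed at different dimensionalities are compared by the
#' absolute cosine similarity of their full gene-weight vectors,
#' `|u . v| / (||u|| ||v||)` — referred to throughout as the correlation.
#' The absolute value makes the measure invariant to the arbitrary sign of
#' ICA components, consistent with the `1 - |rho|` clustering distance.
#'
#' @param u,v Numeric gene-weight vectors of equal length, both non-zero.
#' @param signed If `TRUE`, return the signed cosine similarity instead
#'   (ablation flag).
#' @return A value in `[0, 1]` (or `[-1, 1]` when `signed`).
#' @export
component_correlation <- function(u, v, signed = FALSE) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) stop("zero vector has no direction", call. = FALSE)
  cs <- sum(u * v) / (nu * nv)
  cs <- max(-1, min(1, cs))
  if (signed) cs else abs(cs)
}

## All-pairs |cosine| between columns of two weight matrices.
cosine_matrix <- function(M1, M2) {
  n1 <- sqrt(colSums(M1 * M1))
  n2 <- sqrt(colSums(M2 * M2))
  cc <- abs(crossprod(M1, M2)) / outer(n1, n2)
  cc[cc > 1] <- 1
  cc
}

#' Build the dimensionality tree
#'
#' Links components of each grid dimension to components of the next
#' (adjacent) grid dimension wherever their absolute-cosine correlation
#' strictly exceeds the adjacency threshold.  Child nodes with no parent
#' edge are newly discovered components; a parent with two or more child
#' edges marks component splitting.
#'
#' @param scan An `optica_scan` with at least two completed dimensions.
#' @param threshold Adjacency threshold on the correlation (default 0.3).
#' @return An object of class `optica_tree`: tibbles `nodes`
#'   (`dim`, `idx`, `component`) and `edges` (`parent_dim`, `parent_idx`,
#'   `child_dim`, `child_idx`, `corr`).
#' @export
build_tree <- function(scan, threshold = scan$cfg$adjacency_threshold %||% 0.3) {
  stopifnot(inherits(scan, "optica_scan"))
  dims <- scan_dims(scan)
  if (length(dims) < 2L) stop("need at least two completed dimensions", call. = FALSE)
  nodes <- purrr::map_dfr(dims, function(d) {
    k <- ncol(scan$decompositions[[as.character(d)]]$M)
    if (k == 0L) return(tibble::tibble(dim = integer(0), idx = integer(0),
                                       component = character(0)))
    tibble::tibble(dim = d, idx = seq_len(k) - 1L,
                   component = sprintf("comp_%03d", seq_len(k) - 1L))
  })
  edges <- purrr::map_dfr(seq_len(length(dims) - 1L), function(i) {
    Mp <- scan$decompositions[[as.character(dims[i])]]$M
    Mc <- scan$decompositions[[as.character(dims[i + 1L])]]$M
    if (ncol(Mp) == 0L || ncol(Mc) == 0L) {
      return(tibble::tibble(parent_dim = integer(0), parent_idx = integer(0),
                            child_dim = integer(0), child_idx = integer(0),
                            corr = numeric(0)))
    }
    cc <- cosine_matrix(Mp, Mc)
    hit <- which(cc > threshold, arr.ind = TRUE)
    tibble::tibble(parent_dim = dims[i], parent_idx = unname(hit[, 1L]) - 1L,
                   child_dim = dims[i + 1L], child_idx = unname(hit[, 2L]) - 1L,
                   corr = unname(cc[hit])) |>
      dplyr::arrange(.data$parent_idx, .data$child_idx)
  })
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "optica_tree")
}

#' @export
print.optica_tree <- function(x, ...) {
  cat(sprintf("<optica_tree> %d nodes, %d edges (adjacency > %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Export a dimensionality tree as JSON
#'
#' @param tree An `optica_tree`.
#' @param path Output path (`tree.json`).
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "optica_tree"))
  obj <- list(
    threshold = tree$threshold,
    nodes = purrr::pmap(tree$nodes[c("dim", "idx")], function(dim, idx) {
      list(dim = dim, idx = idx)
    }),
    edges = purrr::pmap(tree$edges, function(parent_dim, parent_idx,
                                             child_dim, child_idx, corr) {
      list(parent = list(dim = parent_dim, idx = parent_idx),
           child = list(dim = child_dim, idx = child_idx),
           corr = corr)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Best correlation of final-dimension components at every dimension
#'
#' For each component of the final (largest) decomposition and each
#' completed dimension, records the highest absolute-cosine correlation
#' against any component at that dimension.  The final dimension itself is
#' included (each component matches itself at correlation 1).
#'
#' @param scan An `optica_scan`.
#' @param final_dim Dimension treated as final (default: the largest
#'   completed one).
#' @return An object of class `optica_conservation`: matrix
#'   `best_correlation` (dimensions x final components), `final_dim`, and
#'   `dims`.
#' @export
conservation_profile <- function(scan, final_dim = max(scan_dims(scan))) {
  stopifnot(inherits(scan, "optica_scan"))
  dims <- scan_dims(scan)
  if (!final_dim %in% dims) stop("final_dim not completed in this scan", call. = FALSE)
  Mf <- scan$decompositions[[as.character(final_dim)]]$M
  kf <- ncol(Mf)
  best <- matrix(0, length(dims), kf,
                 dimnames = list(dims, colnames(Mf)))
  for (i in seq_along(dims)) {
    Md <- scan$decompositions[[as.character(dims[i])]]$M
    if (ncol(Md) == 0L || kf == 0L) next
    cc <- cosine_matrix(Md, Mf)
    best[i, ] <- apply(cc, 2L, max)
  }
  structure(list(best_correlation = best, final_dim = final_dim, dims = dims),
            class = "optica_conservation")
}

## Kneedle knee of a descending-sorted curve: normalize both axes to
## [0, 1], take the chord from the first to the last point, and return the
## index with the maximum difference above the chord (concave/decreasing
## orientation, sensitivity 1).  Ties within 1e-12 of the maximum resolve
## to the middle tied index, so an exactly linear curve knees at its
## midpoint.
kneedle_knee_index <- function(y_sorted) {
  n <- length(y_sorted)
  x <- (seq_len(n) - 1) / (n - 1)
  yn <- (y_sorted - min(y_sorted)) / (max(y_sorted) - min(y_sorted))
  chord <- yn[1L] + (yn[n] - yn[1L]) * x
  diff <- yn - chord
  ties <- which(diff >= max(diff) - 1e-12)
  ties[ceiling(length(ties) / 2)]
}

#' Knee-point threshold for conserved components
#'
#' Pools the best correlations of every final component at every strictly
#' preceding dimension, sorts them in descending order, and places the
#' threshold at the Kneedle knee of the sorted curve — the point of
#' maximum distance to the chord joining its endpoints, after axis
#' normalization.  The result is clamped to `[0.3, 0.99]`.  With fewer
#' than 10 pooled values (or a degenerate flat curve) a fixed 0.7 fallback
#' is used with a warning.
#'
#' @param profile An `optica_conservation` from [conservation_profile()],
#'   or a numeric vector of pooled best correlations.
#' @return The threshold correlation, a scalar in `[0.3, 0.99]`.
#' @export
conserved_threshold <- function(profile) {
  if (inherits(profile, "optica_conservation")) {
    pre <- profile$dims != profile$final_dim
    values <- as.vector(profile$best_correlation[pre, , drop = FALSE])
  } else {
    values <- as.numeric(profile)
  }
  clamp <- function(v) max(0.3, min(0.99, v))
  if (length(values) < 10L) {
    warning("fewer than 10 pooled correlations; falling back to threshold 0.7",
            call. = FALSE)
    return(0.7)
  }
  if (max(values) - min(values) < 1e-12) {
    warning("flat correlation distribution has no knee; clamping its value",
            call. = FALSE)
    return(clamp(values[1L]))
  }
  y <- sort(values, decreasing = TRUE)
  clamp(y[kneedle_knee_index(y)])
}

#' Count conserved components per dimension
#'
#' A final-dimension component is conserved at dimension `d` when its best
#' correlation against the components of `d` strictly exceeds the
#' threshold.
#'
#' @param profile An `optica_conservation`.
#' @param threshold Correlation threshold, typically from
#'   [conserved_threshold()].
#' @return A tibble with columns `dimension` and `n_conserved`; the
#'   boolean conservation matrix (dimensions x final components) is
#'   attached as attribute `"flags"` for heat-map export.
#' @export
classify_conserved <- function(profile, threshold) {
  stopifnot(inherits(profile, "optica_conservation"))
  flags <- profile$best_correlation > threshold
  out <- tibble::tibble(dimension = profile$dims,
                        n_conserved = as.integer(rowSums(flags)))
  attr(out, "flags") <- flags
  out
}

#' Conservation profile as a tidy tibble
#'
#' @param profile An `optica_conservation`.
#' @return A tibble with columns `dimension`, `component`,
#'   `best_correlation`.
#' @export
conservation_table <- function(profile) {
  stopifnot(inherits(profile, "optica_conservation"))
  m <- profile$best_correlation
  if (ncol(m) == 0L) {
    return(tibble::tibble(dimension = integer(0), component = character(0),
                          best_correlation = numeric(0)))
  }
  tibble::as_tibble(m, rownames = "dimension") |>
    dplyr::mutate(dimension = as.integer(.data$dimension)) |>
    tidyr::pivot_longer(-"dimension", names_to = "component",
                        values_to = "best_correlation")
}
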