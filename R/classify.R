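#' Single-gene component test
#'
#' A component is "single gene" — the over-decomposition signature — when
#' its highest absolute gene weight is strictly more than twice the next
#' highest.
#'
#' @param weights Numeric gene-weight vector (length >= 2).
#' @return Logical scalar.
#' @export
is_single_gene <- function(weights) {
  stopifnot(length(weights) >= 2L)
  a <- sort(abs(weights), decreasing = TRUE)[1:2]
  if (a[1L] == 0) {
    warning("all-zero component has no dominant gene", call. = FALSE)
    return(FALSE)
  }
  a[1L] > 2 * a[2L]
}

## Exact 1-D k-means by dynamic programming.  Optimal clusters of 1-D
## points are contiguous on the sorted values, so the WSS-minimal
## partition is found exactly; the op is deterministic, unlike Lloyd
## iterations from random starts.  Returns cluster labels (1 = smallest
## values) in the original order.
kmeans_1d_exact <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs * xs)
  seg_cost <- function(i, j) {
    # vectorized over i; interval [i, j] on sorted values
    s <- cs[j] - c(0, cs)[i]
    s2 <- cs2[j] - c(0, cs2)[i]
    pmax(0, s2 - s * s / (j - i + 1))
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  D[1L, ] <- pmax(0, cs2 - cs * cs / seq_len(n))
  for (kk in 2:k) {
    for (j in kk:n) {
      i <- kk:j
      cand <- D[kk - 1L, i - 1L] + seg_cost(i, j)
      best <- which.min(cand)
      D[kk, j] <- cand[best]
      B[kk, j] <- i[best]
    }
  }
  labels_sorted <- integer(n)
  j <- n
  for (kk in k:1) {
    i <- if (kk == 1L) 1L else B[kk, j]
    labels_sorted[i:j] <- kk
    j <- i - 1L
  }
  labels <- integer(n)
  labels[ord] <- labels_sorted
  labels
}

#' Extract the significant genes of a component (its iModulon)
#'
#' Clusters the absolute gene weights with exact 1-D k-means
#' (`k_clusters` groups; default 3: background, intermediate, high) and
#' returns the union of the top two clusters by centroid magnitude.  With
#' fewer distinct weight magnitudes than clusters, `k` is reduced to the
#' number of distinct values (floor 2, in which case only the top cluster
#' is kept); a fully degenerate component (all magnitudes equal) returns
#' every gene with a warning.
#'
#' @param weights Named numeric gene-weight vector.
#' @param k_clusters Number of 1-D clusters (default 3, must be >= 3 on
#'   the non-degenerate path).
#' @return Character vector of significant gene ids (the iModulon).
#' @export
significant_genes <- function(weights, k_clusters = 3L) {
  stopifnot(k_clusters >= 3L, length(weights) >= 2L)
  if (is.null(names(weights))) names(weights) <- as.character(seq_along(weights))
  aw <- abs(weights)
  n_distinct <- length(unique(aw))
  if (n_distinct == 1L) {
    warning("all gene weights have equal magnitude; returning all genes",
            call. = FALSE)
    return(names(weights))
  }
  k <- min(k_clusters, n_distinct, length(aw))
  top <- 2L
  if (k == 2L) top <- 1L
  labels <- kmeans_1d_exact(aw, k)
  centroids <- vapply(seq_len(k), function(cl) mean(aw[labels == cl]), numeric(1))
  keep <- order(centroids, decreasing = TRUE)[seq_len(top)]
  names(weights)[labels %in% keep]
}

#' Two-sided Fisher's exact p-value from 2x2 table margins
#'
#' Exact two-sided p for overlap between two gene sets drawn from a
#' common universe, computed from the hypergeometric null: the sum of the
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table (relative tie
#' tolerance 1e-7, the conventional choice for floating-point tied
#' tables).
#'
#' @param overlap Observed overlap between the two sets.
#' @param size1,size2 Sizes of the two sets.
#' @param universe_size Size of the gene universe.
#' @return The two-sided p-value in `[0, 1]`.
#' @export
fisher_pvalue <- function(overlap, size1, size2, universe_size) {
  stopifnot(universe_size >= 1L, size1 <= universe_size, size2 <= universe_size,
            overlap <= min(size1, size2), overlap >= max(0L, size1 + size2 - universe_size))
  support <- max(0L, size1 + size2 - universe_size):min(size1, size2)
  probs <- dhyper(support, size1, universe_size - size1, size2)
  p_obs <- probs[support == overlap]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher enrichment of an iModulon in a regulon
#'
#' @param imodulon_genes,regulon_genes Character vectors of gene ids,
#'   both subsets of `universe`.
#' @param universe Character vector of all gene ids (length >= 4).
#' @return The two-sided Fisher's exact p-value.
#' @export
fisher_enrichment <- function(imodulon_genes, regulon_genes, universe) {
  if (length(imodulon_genes) == 0L || length(regulon_genes) == 0L) {
    warning("empty gene set: enrichment p set to 1", call. = FALSE)
    return(1)
  }
  imodulon_genes <- unique(imodulon_genes)
  regulon_genes <- unique(regulon_genes)
  universe <- unique(universe)
  stopifnot(length(universe) >= 4L,
            all(imodulon_genes %in% universe), all(regulon_genes %in% universe))
  fisher_pvalue(length(intersect(imodulon_genes, regulon_genes)),
                length(imodulon_genes), length(regulon_genes), length(universe))
}

set_f1 <- function(imodulon_genes, regulon_genes) {
  tp <- length(intersect(imodulon_genes, regulon_genes))
  precision <- if (length(imodulon_genes) > 0L) tp / length(imodulon_genes) else 0
  recall <- if (length(regulon_genes) > 0L) tp / length(regulon_genes) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Regulon enrichment for a set of iModulons
#'
#' Tests every iModulon against every regulon with the two-sided Fisher's
#' exact test and adjusts p-values by Benjamini-Hochberg across all
#' component-by-regulon tests of the call (the within-dimension pool).
#'
#' @param imodulons Named list of gene-id character vectors, one per
#'   component.
#' @param db An [regulon_db()].
#' @return A tibble with one row per component x regulator: `component`,
#'   `regulator`, `p_value`, `q_value`, `precision`, `recall`, `f1`.
#' @export
enrich_imodulons <- function(imodulons, db) {
  stopifnot(inherits(db, "optica_regulons"))
  if (length(imodulons) == 0L) {
    return(tibble::tibble(component = character(0), regulator = character(0),
                          p_value = numeric(0), q_value = numeric(0),
                          precision = numeric(0), recall = numeric(0),
                          f1 = numeric(0)))
  }
  grid <- tidyr::expand_grid(component = names(imodulons),
                             regulator = names(db$regulons))
  stats <- purrr::pmap_dfr(grid, function(component, regulator) {
    im <- imodulons[[component]]
    rg <- db$regulons[[regulator]]
    m <- set_f1(im, rg)
    tibble::tibble(p_value = fisher_enrichment(im, rg, db$universe),
                   precision = m[["precision"]], recall = m[["recall"]],
                   f1 = m[["f1"]])
  })
  dplyr::bind_cols(grid, stats) |>
    dplyr::mutate(q_value = p.adjust(.data$p_value, method = "BH"),
                  .after = "p_value")
}

#' Best enrichment per component
#'
#' Reduces an [enrich_imodulons()] table to the best regulator per
#' component: lowest q-value, ties broken by highest F1, then by
#' regulator name (so the result is invariant to regulon ordering in the
#' database).  A component is regulatory when its best q-value is below
#' `fdr`.
#'
#' @param enrichments Tibble from [enrich_imodulons()].
#' @param fdr FDR cutoff (default 1e-5).
#' @return A tibble with one row per component, adding `is_regulatory`.
#' @export
best_enrichment <- function(enrichments, fdr = 1e-5) {
  if (nrow(enrichments) == 0L) {
    return(dplyr::mutate(enrichments, is_regulatory = logical(0)))
  }
  enrichments |>
    dplyr::arrange(.data$component, .data$q_value, dplyr::desc(.data$f1),
                   .data$regulator) |>
    dplyr::distinct(.data$component, .keep_all = TRUE) |>
    dplyr::mutate(is_regulatory = .data$q_value < fdr)
}

#' Enrich a single component against a regulon database
#'
#' Convenience wrapper around [enrich_imodulons()] + [best_enrichment()]
#' for one iModulon; the FDR adjustment here pools only this component's
#' regulon tests (pipeline summaries pool across all components of a
#' dimension instead).
#'
#' @param imodulon_genes Character vector of gene ids.
#' @param db An [regulon_db()].
#' @param fdr FDR cutoff.
#' @return One-row tibble, or a zero-row tibble when no regulon was
#'   testable.
#' @export
enrich_component <- function(imodulon_genes, db, fdr = 1e-5) {
  best_enrichment(enrich_imodulons(list(component = imodulon_genes), db), fdr)
}

#' Classify and summarize one decomposition
#'
#' Applies the single-gene rule and (when a regulon database is supplied)
#' regulon enrichment to every robust component, and rolls the results up
#' into one summary row.  `mean_f1`/`sd_f1` average over regulatory
#' components only; without a database the regulatory columns are `NA`
#' (absent), not zero.
#'
#' @param d An `optica_decomposition`.
#' @param db Optional [regulon_db()].
#' @param conserved_count Number of conserved components at this
#'   dimension (`NA` when unknown).
#' @param cfg An [optica_config()].
#' @return A one-row tibble with columns `dimension`, `n_robust`,
#'   `n_single_gene`, `n_non_single_gene`, `n_regulatory`, `n_conserved`,
#'   `mean_f1`, `sd_f1`, `stable_fraction`; the per-component record
#'   tibble is attached as attribute `"components"`.
#' @export
summarize_dimension <- function(d, db = NULL, conserved_count = NA_integer_,
                                cfg = optica_config()) {
  stopifnot(inherits(d, "optica_decomposition"))
  k <- ncol(d$M)
  comps <- tibble::tibble(component = colnames(d$M) %||% character(0))
  if (k > 0L) {
    comps$is_single_gene <- vapply(seq_len(k), function(j) is_single_gene(d$M[, j]),
                                   logical(1))
    comps$stability <- d$stability
    comps$cluster_size <- as.integer(d$cluster_sizes)
  } else {
    comps$is_single_gene <- logical(0)
    comps$stability <- numeric(0)
    comps$cluster_size <- integer(0)
  }
  best <- NULL
  if (!is.null(db) && k > 0L) {
    imods <- lapply(seq_len(k), function(j) significant_genes(d$M[, j], cfg$kmeans_k))
    names(imods) <- comps$component
    best <- best_enrichment(enrich_imodulons(imods, db), cfg$fdr)
    comps <- dplyr::left_join(comps, best, by = "component")
    comps$n_genes <- lengths(imods)[comps$component]
  }
  n_sg <- sum(comps$is_single_gene)
  reg <- if (!is.null(best)) {
    f1s <- comps$f1[which(comps$is_regulatory)]
    list(n = sum(comps$is_regulatory, na.rm = TRUE),
         mean = if (length(f1s)) mean(f1s) else NA_real_,
         sd = if (length(f1s) > 1L) sd(f1s) else NA_real_)
  } else {
    list(n = NA_integer_, mean = NA_real_, sd = NA_real_)
  }
  out <- tibble::tibble(
    dimension = d$dimension,
    n_robust = k,
    n_single_gene = as.integer(n_sg),
    n_non_single_gene = as.integer(k - n_sg),
    n_regulatory = as.integer(reg$n),
    n_conserved = as.integer(conserved_count),
    mean_f1 = reg$mean,
    sd_f1 = reg$sd,
    stable_fraction = if (d$dimension > 0L) {
      sum(d$stability > cfg$mstd_stability_cutoff) / d$dimension
    } else NA_real_
  )
  attr(out, "components") <- comps
  out
}

#' Summarize every dimension of a scan
#'
#' Computes the conservation profile against the largest completed
#' dimension, derives the knee-point conserved threshold, classifies each
#' decomposition, and binds the per-dimension summaries into one tibble.
#'
#' @param scan An `optica_scan`.
#' @param db Optional [regulon_db()].
#' @return A tibble of class `optica_summary`, one row per dimension,
#'   with attributes `threshold` (conserved-correlation threshold),
#'   `profile` (the `optica_conservation` object), and `components` (the
#'   per-component records bound across dimensions).
#' @export
summarize_scan <- function(scan, db = NULL) {
  stopifnot(inherits(scan, "optica_scan"))
  dims <- scan_dims(scan)
  profile <- conservation_profile(scan)
  threshold <- if (length(dims) >= 2L) {
    conserved_threshold(profile)
  } else {
    suppressWarnings(conserved_threshold(numeric(0)))
  }
  conserved <- classify_conserved(profile, threshold)
  Mf <- scan$decompositions[[as.character(profile$final_dim)]]$M
  rows <- purrr::map(dims, function(dd) {
    cc <- conserved$n_conserved[conserved$dimension == dd]
    summarize_dimension(scan$decompositions[[as.character(dd)]], db = db,
                        conserved_count = cc, cfg = scan$cfg)
  })
  comp_records <- purrr::map2_dfr(rows, dims, function(r, dd) {
    comps <- attr(r, "components")
    Md <- scan$decompositions[[as.character(dd)]]$M
    comps$is_conserved <- if (ncol(Md) > 0L && ncol(Mf) > 0L) {
      apply(cosine_matrix(Md, Mf), 1L, max) > threshold
    } else {
      logical(nrow(comps))
    }
    dplyr::mutate(comps, dimension = dd, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold") <- threshold
  attr(out, "profile") <- profile
  attr(out, "components") <- comp_records
  class(out) <- c("optica_summary", class(out))
  out
}
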