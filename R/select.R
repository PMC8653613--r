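#' OptICA dimensionality: crossing of the two counting curves
#'
#' Selects the dimension where the number of non-single-gene components
#' equals the number of conserved components: the smallest grid dimension
#' at which the rising conserved-component curve reaches (touches or
#' crosses) the non-single-gene curve.  The first meeting point is used
#' because the conserved count at the final dimension equals its robust
#' count by construction (every final component matches itself), so the
#' curves always re-meet trivially next to the end of the grid.  If the
#' curves never meet, the dimension minimizing the absolute gap is
#' returned (ties: smaller dimension) with a warning.
#'
#' @param summaries A per-dimension summary tibble (from
#'   [summarize_scan()]) with columns `dimension`, `n_non_single_gene`,
#'   `n_conserved`, covering at least 3 dimensions.
#' @return The selected dimension (integer).
#' @export
optica_dimension <- function(summaries) {
  stopifnot(all(c("dimension", "n_non_single_gene", "n_conserved") %in% names(summaries)))
  s <- dplyr::arrange(summaries, .data$dimension)
  if (nrow(s) < 3L) stop("need at least 3 summarized dimensions", call. = FALSE)
  if (any(is.na(s$n_conserved))) stop("conserved counts absent", call. = FALSE)
  nsg <- s$n_non_single_gene
  cons <- s$n_conserved
  meet <- which(cons >= nsg)
  if (length(meet) > 0L) return(s$dimension[meet[1L]])
  warning("counting curves never cross; returning the closest-gap dimension",
          call. = FALSE)
  s$dimension[which.min(abs(nsg - cons))]
}

#' PC-VA dimensionality: cumulative explained variance of PCA
#'
#' Number of principal components needed to reach the cumulative
#' explained-variance target (default 99%).
#'
#' @param x An [expression_matrix()]; gene-centered automatically.
#' @param variance_target Fraction in (0, 1] (default 0.99).
#' @return The smallest component count whose cumulative explained
#'   variance fraction reaches the target.
#' @export
pcva_dimension <- function(x, variance_target = 0.99) {
  stopifnot(inherits(x, "optica_expr"),
            variance_target > 0, variance_target <= 1)
  if (!x$centered) x <- center_genes(x)
  d2 <- svd(x$values, nu = 0L, nv = 0L)$d^2
  cum <- cumsum(d2) / sum(d2)
  as.integer(which(cum >= variance_target - 1e-12)[1L])
}

#' MSTD dimensionality: stability inflection baseline
#'
#' Approximate reimplementation of the maximally stable transcriptome
#' dimension used as a comparison baseline: per dimension, the fraction
#' of the requested components that came back as robust components with
#' stability (mean `|cor|` of cluster members to their centroid) above
#' `stability_cutoff`; MSTD is the largest dimension before this fraction
#' first drops below `drop_cutoff`.  When the fraction never drops the
#' method does not converge on a dimension and `NA` is returned — a valid
#' outcome.
#'
#' @param summaries Tibble with columns `dimension` and `stable_fraction`
#'   (from [summarize_scan()]).
#' @param stability_cutoff Stability above which a component is stable
#'   (default 0.8).
#' @param drop_cutoff Stable fraction below which a dimension is unstable
#'   (default 0.5).
#' @return The MSTD dimension, or `NA` when it does not converge.
#' @export
mstd_dimension <- function(summaries, stability_cutoff = 0.8, drop_cutoff = 0.5) {
  stopifnot(all(c("dimension", "stable_fraction") %in% names(summaries)))
  s <- dplyr::arrange(summaries, .data$dimension)
  drop <- which(s$stable_fraction < drop_cutoff)
  if (length(drop) == 0L) return(NA_integer_)
  s$dimension[max(drop[1L] - 1L, 1L)]
}

#' Apply all three dimensionality-selection rules to a scan
#'
#' @param summaries An `optica_summary` from [summarize_scan()].
#' @param x The [expression_matrix()] that was scanned (for the PCA
#'   baseline).
#' @param cfg An [optica_config()].
#' @return An object of class `optica_selection`: `optica_dim`,
#'   `pcva_dim`, `mstd_dim`, the conserved `threshold`, and the `curves`
#'   tibble the rules consumed.
#' @export
select_dimensions <- function(summaries, x, cfg = optica_config()) {
  curves <- dplyr::select(tibble::as_tibble(summaries),
                          dplyr::any_of(c("dimension", "n_robust",
                                          "n_single_gene", "n_non_single_gene",
                                          "n_regulatory", "n_conserved",
                                          "mean_f1", "stable_fraction")))
  structure(list(
    optica_dim = optica_dimension(summaries),
    pcva_dim = pcva_dimension(x, cfg$pcva_target),
    mstd_dim = mstd_dimension(summaries, cfg$mstd_stability_cutoff,
                              cfg$mstd_drop_cutoff),
    threshold = attr(summaries, "threshold"),
    curves = curves
  ), class = "optica_selection")
}

#' @export
print.optica_selection <- function(x, ...) {
  cat(sprintf("<optica_selection> OptICA %d | PC-VA %d | MSTD %s\n",
              x$optica_dim, x$pcva_dim,
              if (is.na(x$mstd_dim)) "not converged" else x$mstd_dim))
  invisible(x)
}
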