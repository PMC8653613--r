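#' Tidy a robust decomposition
#'
#' @param x An `optica_decomposition`.
#' @param ... Unused.
#' @return A tibble with one row per robust component: `component`,
#'   `cluster_size`, `stability`, `max_weight`, `is_single_gene`.
#' @method tidy optica_decomposition
#' @export
tidy.optica_decomposition <- function(x, ...) {
  k <- ncol(x$M)
  tibble::tibble(
    component = colnames(x$M) %||% character(0),
    cluster_size = as.integer(x$cluster_sizes),
    stability = x$stability,
    max_weight = if (k > 0L) apply(abs(x$M), 2L, max) else numeric(0),
    is_single_gene = if (k > 0L) {
      vapply(seq_len(k), function(j) is_single_gene(x$M[, j]), logical(1))
    } else logical(0)
  )
}

#' Glance at a robust decomposition
#'
#' @param x An `optica_decomposition`.
#' @param ... Unused.
#' @return A one-row tibble: `dimension`, `k_robust`, `n_runs_converged`,
#'   `n_runs`.
#' @method glance optica_decomposition
#' @export
glance.optica_decomposition <- function(x, ...) {
  tibble::tibble(dimension = x$dimension, k_robust = ncol(x$M),
                 n_runs_converged = x$n_runs_converged, n_runs = x$n_runs)
}

#' Tidy a selection result into its per-dimension curves
#'
#' @param x An `optica_selection`.
#' @param ... Unused.
#' @return A long tibble with columns `dimension`, `curve`, `value`.
#' @method tidy optica_selection
#' @export
tidy.optica_selection <- function(x, ...) {
  tidyr::pivot_longer(x$curves, -"dimension", names_to = "curve",
                      values_to = "value")
}

#' Glance at a selection result
#'
#' @param x An `optica_selection`.
#' @param ... Unused.
#' @return A one-row tibble: `optica_dim`, `pcva_dim`, `mstd_dim`,
#'   `conserved_threshold`.
#' @method glance optica_selection
#' @export
glance.optica_selection <- function(x, ...) {
  tibble::tibble(optica_dim = x$optica_dim, pcva_dim = x$pcva_dim,
                 mstd_dim = x$mstd_dim, conserved_threshold = x$threshold)
}

#' Plot the component-classification curves of a scan
#'
#' Displays the per-dimension counts (robust, single-gene,
#' non-single-gene, regulatory, conserved components) whose crossing
#' defines the OptICA dimension.
#'
#' @param object An `optica_summary` from [summarize_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot optica_summary
#' @export
autoplot.optica_summary <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select(dplyr::any_of(c("dimension", "n_robust", "n_single_gene",
                                  "n_non_single_gene", "n_regulatory",
                                  "n_conserved"))) |>
    tidyr::pivot_longer(-"dimension", names_to = "class", values_to = "count") |>
    dplyr::filter(!is.na(.data$count))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dimension, y = .data$count,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "ICA dimensionality", y = "components",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a conservation heat map
#'
#' Best absolute-cosine correlation of each final-dimension component at
#' every scanned dimension; once discovered, components stay near 1.
#'
#' @param profile An `optica_conservation` from [conservation_profile()].
#' @param threshold Optional threshold to dichotomize at.
#' @return A ggplot object.
#' @export
plot_conservation <- function(profile, threshold = NULL) {
  long <- conservation_table(profile)
  if (!is.null(threshold)) {
    long$best_correlation <- as.numeric(long$best_correlation > threshold)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dimension, y = .data$component,
                                     fill = .data$best_correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "correlation") +
    ggplot2::labs(x = "ICA dimensionality", y = "final component") +
    ggplot2::theme_minimal()
}
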