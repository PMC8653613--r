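#' Generate a ground-truthed synthetic expression compendium
#'
#' Emulates the linear-mixture model that ICA assumes for a transcriptomic
#' compendium: `X = M A + noise`, where the columns of `M` are `k_true`
#' sparse, statistically independent gene-weight sources (Laplace-distributed
#' nonzero weights on a random support, so sources are super-Gaussian and
#' ICA-identifiable), `A` holds i.i.d. standard-normal condition
#' activities, and the noise is i.i.d. Gaussian.  Each source's support
#' doubles as a ground-truth regulon, so regulatory enrichment, iModulon
#' recovery, and both over- and under-decomposition are all testable
#' without external data.  Optionally the first `n_single_gene_sources`
#' sources get a single-gene support, planting the over-decomposition
#' signature.
#'
#' The model deliberately omits RNA-seq count statistics, library-size
#' effects and batch structure; it is the linear-mixture abstraction, not
#' a sequencing simulator.
#'
#' Member-gene weights have magnitude `min_effect + Exponential(1)` with
#' random sign — a Laplace tail shifted away from zero — so that every
#' gene a source regulates has a detectable effect, as membership in a
#' regulon implies.  Because sample correlation between sources (e.g.,
#' from a shared high-weight gene in overlapping supports) bounds how
#' well any decorrelating method can recover them, sources are redrawn
#' until all pairwise absolute Pearson correlations are below
#' `max_source_cor`, keeping the generated sources as independent as the
#' mixture model claims.
#'
#' @param n_genes,n_samples Matrix size (default 500 x 150).
#' @param k_true Number of planted sources (default 20).
#' @param support_size_range Two integers: uniform range of support sizes
#'   (default `c(5, 25)`).
#' @param noise_sigma Gaussian noise standard deviation (default 0.1).
#' @param n_single_gene_sources Number of sources with exactly one
#'   nonzero gene (default 0).
#' @param min_effect Minimum absolute weight of a member gene (default 0.5).
#' @param max_source_cor Cap on pairwise absolute correlation between
#'   sources (default 0.15).
#' @param seed Integer seed; the output is fully seed-deterministic.
#' @return A list with `expr` (an uncentered [expression_matrix()]) and
#'   `truth` (class `optica_truth`: `M_true`, `A_true`, `regulons` an
#'   [regulon_db()], `noise_sigma`, `planted_single_gene`).
#' @export
generate_compendium <- function(n_genes = 500L, n_samples = 150L, k_true = 20L,
                                support_size_range = c(5L, 25L),
                                noise_sigma = 0.1, n_single_gene_sources = 0L,
                                min_effect = 0.5, max_source_cor = 0.15,
                                seed = 1L) {
  stopifnot(k_true <= min(n_genes, n_samples),
            support_size_range[1L] >= 1L,
            support_size_range[2L] <= n_genes,
            n_single_gene_sources <= k_true)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  sample_ids <- sprintf("sample_%03d", seq_len(n_samples))
  out <- with_seed(seed, {
    M <- matrix(0, n_genes, k_true)
    supports <- vector("list", k_true)
    for (j in seq_len(k_true)) {
      for (attempt in 1:100) {
        size <- if (j <= n_single_gene_sources) 1L else {
          sample(seq.int(support_size_range[1L], support_size_range[2L]), 1L)
        }
        sup <- sample.int(n_genes, size)
        w <- numeric(n_genes)
        w[sup] <- sample(c(-1, 1), size, replace = TRUE) * (min_effect + rexp(size))
        if (j == 1L || max(abs(cor(w, M[, seq_len(j - 1L), drop = FALSE]))) < max_source_cor) {
          break
        }
      }
      supports[[j]] <- sup
      M[, j] <- w
    }
    A <- matrix(rnorm(k_true * n_samples), k_true, n_samples)
    X <- M %*% A
    if (noise_sigma > 0) X <- X + matrix(rnorm(n_genes * n_samples, sd = noise_sigma),
                                         n_genes, n_samples)
    list(M = M, A = A, X = X, supports = supports)
  })
  dimnames(out$X) <- list(gene_ids, sample_ids)
  rownames(out$M) <- gene_ids
  colnames(out$M) <- sprintf("source_%02d", seq_len(k_true))
  rownames(out$A) <- colnames(out$M)
  colnames(out$A) <- sample_ids
  regulons <- lapply(out$supports, function(s) gene_ids[s])
  names(regulons) <- colnames(out$M)
  truth <- structure(list(M_true = out$M, A_true = out$A,
                          regulons = regulon_db(regulons, gene_ids),
                          noise_sigma = noise_sigma,
                          planted_single_gene = as.integer(n_single_gene_sources)),
                     class = "optica_truth")
  list(expr = expression_matrix(out$X), truth = truth)
}

#' Score a decomposition against the planted truth
#'
#' Greedily matches planted sources to robust components one-to-one by
#' descending absolute-cosine correlation, then reports per source the
#' matched component, the correlation, and the F1 between the component's
#' iModulon (significant genes) and the source's true regulon.
#'
#' @param d An `optica_decomposition` over the same gene universe as
#'   `truth`.
#' @param truth An `optica_truth` from [generate_compendium()].
#' @param kmeans_k Cluster count for [significant_genes()] (default 3).
#' @return A tibble with columns `source`, `component`, `correlation`,
#'   `f1` (`NA` component for unmatched sources), with attributes
#'   `recovery_rate` (fraction of sources with correlation > 0.7) and
#'   `mean_f1` (over matched sources).
#' @export
score_against_truth <- function(d, truth, kmeans_k = 3L) {
  stopifnot(inherits(d, "optica_decomposition"), inherits(truth, "optica_truth"))
  stopifnot(identical(rownames(d$M), rownames(truth$M_true)))
  k_true <- ncol(truth$M_true)
  k_rob <- ncol(d$M)
  corr <- rep(0, k_true)
  match_comp <- rep(NA_character_, k_true)
  f1 <- rep(NA_real_, k_true)
  if (k_rob > 0L) {
    cc <- cosine_matrix(truth$M_true, d$M)
    for (step in seq_len(min(k_true, k_rob))) {
      best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
      i <- best[[1L]]; j <- best[[2L]]
      corr[i] <- cc[i, j]
      match_comp[i] <- colnames(d$M)[j]
      im <- significant_genes(d$M[, j], kmeans_k)
      f1[i] <- set_f1(im, truth$regulons$regulons[[i]])[["f1"]]
      cc[i, ] <- -1
      cc[, j] <- -1
    }
  }
  out <- tibble::tibble(source = colnames(truth$M_true),
                        component = match_comp,
                        correlation = corr, f1 = f1)
  attr(out, "recovery_rate") <- mean(corr > 0.7)
  attr(out, "mean_f1") <- if (any(!is.na(f1))) mean(f1, na.rm = TRUE) else NA_real_
  out
}

#' Write a synthetic compendium to disk
#'
#' Writes `expr.tsv`, `trn.tsv`, and the ground-truth matrices under
#' `truth/` in the same delimited formats the pipeline reads.
#'
#' @param compendium A list from [generate_compendium()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_compendium <- function(compendium, out_dir) {
  dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_expression(compendium$expr, file.path(out_dir, "expr.tsv"))
  write_trn(compendium$truth$regulons, file.path(out_dir, "trn.tsv"))
  write_labeled_matrix(compendium$truth$M_true,
                       file.path(out_dir, "truth", "M_true.csv"), ",", "gene_id")
  write_labeled_matrix(compendium$truth$A_true,
                       file.path(out_dir, "truth", "A_true.csv"), ",", "source")
  invisible(out_dir)
}
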