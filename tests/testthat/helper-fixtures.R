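# Fixture builders: small matrices and hand-assembled scan objects.

make_expr <- function(values, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assemble an optica_decomposition directly from a weight matrix.
fake_decomposition <- function(M, dimension = ncol(M), gene_ids = NULL) {
  gene_ids <- gene_ids %||% (rownames(M) %||% sprintf("g%d", seq_len(nrow(M))))
  rownames(M) <- gene_ids
  colnames(M) <- sprintf("comp_%03d", seq_len(ncol(M)) - 1L)
  structure(list(dimension = as.integer(dimension), M = M,
                 A = matrix(0, ncol(M), 0L),
                 cluster_sizes = rep(1L, ncol(M)),
                 stability = rep(1, ncol(M)),
                 n_runs = 1L, n_runs_converged = 1L),
            class = "optica_decomposition")
}

# Assemble an optica_scan from a named list dim -> weight matrix.
fake_scan <- function(M_by_dim, cfg = optica_config(n_runs = 2L)) {
  decomps <- lapply(names(M_by_dim), function(d) {
    fake_decomposition(M_by_dim[[d]], dimension = as.integer(d))
  })
  names(decomps) <- names(M_by_dim)
  dims <- sort(as.integer(names(M_by_dim)))
  grid <- structure(list(dims = dims, step = 1L, max_dim = max(dims)),
                    class = "optica_grid")
  structure(list(decompositions = decomps[order(as.integer(names(decomps)))],
                 grid = grid, cfg = cfg, expr = NULL, completed = dims),
            class = "optica_scan")
}

# Orthogonal sparse sources on disjoint supports: a genes x k matrix.
disjoint_sources <- function(n_genes, k, support = 5L) {
  M <- matrix(0, n_genes, k)
  for (j in seq_len(k)) {
    idx <- ((j - 1L) * support + 1L):(j * support)
    M[idx, j] <- seq(1, 2, length.out = support)
  }
  rownames(M) <- sprintf("g%d", seq_len(n_genes))
  M
}
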