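test_that("generated compendia honour the linear-mixture construction", {
  comp <- generate_compendium(n_genes = 500, n_samples = 150, k_true = 20,
                              support_size_range = c(5, 25), noise_sigma = 0,
                              seed = 6)
  expect_identical(qr(comp$expr$values)$rank, 20L)
  expect_identical(dim(comp$expr$values), c(500L, 150L))
  expect_equal(comp$expr$values,
               comp$truth$M_true %*% comp$truth$A_true, ignore_attr = TRUE)

  # regulons are exactly the source supports
  for (j in seq_len(20)) {
    expect_setequal(comp$truth$regulons$regulons[[j]],
                    rownames(comp$truth$M_true)[comp$truth$M_true[, j] != 0])
  }

  # planted single-gene sources have singleton regulons
  sg <- generate_compendium(n_genes = 100, n_samples = 40, k_true = 5,
                            n_single_gene_sources = 3, noise_sigma = 0, seed = 2)
  expect_identical(sum(lengths(sg$truth$regulons$regulons) == 1L), 3L)

  # seed determinism
  a <- generate_compendium(n_genes = 80, n_samples = 30, k_true = 4, seed = 9)
  b <- generate_compendium(n_genes = 80, n_samples = 30, k_true = 4, seed = 9)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth$M_true, b$truth$M_true)

  # sources are kept near-uncorrelated so the mixture is identifiable
  cm <- abs(cor(comp$truth$M_true))
  diag(cm) <- 0
  expect_lt(max(cm), 0.15)

  expect_error(generate_compendium(n_genes = 10, n_samples = 5, k_true = 8),
               "k_true")
})

test_that("scoring against truth is exact on the truth itself and near zero on noise", {
  comp <- generate_compendium(n_genes = 200, n_samples = 60, k_true = 6,
                              noise_sigma = 0, seed = 17)
  # well-separated truth: disjoint supports, weights bounded away from both
  # zero and each other, so significant-gene extraction is exact
  M_sep <- disjoint_sources(200, 6, support = 8L)
  regs <- lapply(seq_len(6), function(j) rownames(M_sep)[M_sep[, j] != 0])
  names(regs) <- sprintf("source_%02d", 1:6)
  truth_sep <- structure(list(M_true = M_sep,
                              A_true = comp$truth$A_true,
                              regulons = regulon_db(regs, rownames(M_sep)),
                              noise_sigma = 0, planted_single_gene = 0L),
                         class = "optica_truth")
  d_true <- fake_decomposition(M_sep, dimension = 6)
  sc <- score_against_truth(d_true, truth_sep)
  expect_equal(attr(sc, "recovery_rate"), 1)
  expect_equal(attr(sc, "mean_f1"), 1)
  expect_true(all(sc$correlation > 1 - 1e-12))

  # random gaussian components recover nothing in high dimension
  set.seed(40)
  d_rand <- fake_decomposition(matrix(rnorm(200 * 6), 200, 6), dimension = 6,
                               gene_ids = rownames(comp$truth$M_true))
  sc_r <- suppressWarnings(score_against_truth(d_rand, comp$truth))
  expect_lt(attr(sc_r, "recovery_rate"), 0.2)

  # fewer robust components than sources bounds the recovery rate
  d_half <- fake_decomposition(comp$truth$M_true[, 1:3], dimension = 3)
  sc_h <- score_against_truth(d_half, comp$truth)
  expect_lte(attr(sc_h, "recovery_rate"), 3 / 6)
})

test_that("recovery degrades monotonically with noise on average", {
  rates <- vapply(c(0, 0.5, 2), function(sigma) {
    mean(vapply(1:3, function(s) {
      comp <- generate_compendium(n_genes = 80, n_samples = 30, k_true = 4,
                                  support_size_range = c(4, 8),
                                  noise_sigma = sigma, seed = s)
      d <- suppressWarnings(robust_decomposition(
        center_genes(comp$expr), 4,
        optica_config(n_runs = 5, base_seed = 50 + s)))
      attr(score_against_truth(d, comp$truth), "recovery_rate")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_equal(rates[1], 1)
})

test_that("compendium files round-trip through the pipeline readers", {
  comp <- generate_compendium(n_genes = 50, n_samples = 20, k_true = 3, seed = 77)
  dir <- tempfile()
  write_compendium(comp, dir)
  x <- read_expression(file.path(dir, "expr.tsv"))
  expect_identical(x$values, comp$expr$values)
  db <- read_trn(file.path(dir, "trn.tsv"), rownames(x$values))
  expect_identical(db$regulons[sort(names(db$regulons))],
                   comp$truth$regulons$regulons[sort(names(comp$truth$regulons$regulons))])
})
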