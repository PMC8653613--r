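test_that("the single-gene rule is strict about 'more than twice the next highest'", {
  expect_true(is_single_gene(c(5, 2, 1, 0.5)))
  expect_false(is_single_gene(c(5, 3)))
  expect_false(is_single_gene(c(4, 2)))          # boundary: 4 == 2*2
  expect_true(is_single_gene(c(-5, 2, 1)))       # magnitudes, sign-agnostic
  expect_warning(res <- is_single_gene(c(0, 0, 0)), "no dominant gene")
  expect_false(res)
})

test_that("significant genes are the top two exact 1-D clusters of |weights|", {
  set.seed(71)
  w <- c(rnorm(90, 0, 0.01), rnorm(5, 5, 0.05), rnorm(5, 10, 0.05))
  names(w) <- sprintf("g%03d", seq_along(w))
  im <- significant_genes(w, 3)
  expect_setequal(im, names(w)[91:100])

  # exactly three distinct magnitudes cluster uniquely
  w3 <- setNames(c(rep(0, 5), rep(1, 3), rep(2, 2)), sprintf("h%d", 1:10))
  expect_setequal(significant_genes(w3, 3), sprintf("h%d", 6:10))

  # degenerate: all magnitudes equal
  wf <- setNames(rep(2, 6), sprintf("e%d", 1:6))
  expect_warning(all_genes <- significant_genes(wf, 3), "equal")
  expect_setequal(all_genes, names(wf))

  # two distinct values: k reduced to 2, only the top cluster kept
  w2 <- setNames(c(rep(0, 8), rep(3, 2)), sprintf("d%d", 1:10))
  expect_setequal(significant_genes(w2, 3), c("d9", "d10"))
})

test_that("exact 1-D k-means agrees with exhaustive breakpoint enumeration", {
  set.seed(90)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    x <- abs(rnorm(n)) * sample(c(1, 10), n, replace = TRUE)
    got <- optica:::kmeans_1d_exact(x, 3)
    ref <- oracle_kmeans3(x)
    # same partition up to label permutation: compare sorted memberships
    expect_identical(split(order(x), got[order(x)]) |> unname(),
                     split(order(x), ref[order(x)]) |> unname())
  }
})

test_that("fisher p-values match the exact test and behave at the margins", {
  # identical 10-gene sets in a universe of 1000: compare against both the
  # enumeration oracle and stats::fisher.test
  p <- fisher_pvalue(10, 10, 10, 1000)
  expect_equal(p, oracle_fisher_p(10, 10, 10, 1000), tolerance = 1e-12)
  tab <- matrix(c(10, 0, 0, 980), 2)
  expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-8)

  # disjoint 2-gene sets in a universe of 4
  p2 <- fisher_pvalue(0, 2, 2, 4)
  expect_equal(p2, oracle_fisher_p(0, 2, 2, 4), tolerance = 1e-12)
  expect_equal(p2, stats::fisher.test(matrix(c(0, 2, 2, 0), 2))$p.value,
               tolerance = 1e-8)

  # iModulon equal to the whole universe carries no information
  expect_equal(fisher_enrichment(letters[1:6], letters[1:3], letters[1:6]), 1)

  expect_warning(p3 <- fisher_enrichment(character(0), "a", letters[1:4]), "empty")
  expect_equal(p3, 1)

  # random spot-check against stats::fisher.test
  set.seed(14)
  for (i in 1:50) {
    N <- sample(10:200, 1)
    m <- sample.int(N, 1)
    k <- sample.int(N, 1)
    lo <- max(0, m + k - N); hi <- min(m, k)
    x <- if (lo == hi) lo else sample(lo:hi, 1)
    tab <- matrix(c(x, k - x, m - x, N - m - k + x), 2)
    expect_equal(fisher_pvalue(x, m, k, N), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("enrichment reports precision, recall and F1 of the best regulon", {
  db <- regulon_db(list(R1 = c("c", "d", "e"), R2 = c("x", "y")),
                   universe = c(letters[1:10], "x", "y"))
  res <- enrich_component(c("a", "b", "c", "d"), db, fdr = 0.5)
  expect_identical(res$regulator, "R1")
  expect_equal(res$precision, 0.5)
  expect_equal(res$recall, 2 / 3)
  expect_equal(res$f1, 4 / 7, tolerance = 1e-12)

  # exact match scores 1 across the board and is regulatory at tight FDR
  db2 <- regulon_db(list(R1 = letters[1:5]), universe = letters[1:26])
  res2 <- enrich_component(letters[1:5], db2, fdr = 1e-2)
  expect_equal(res2$precision, 1)
  expect_equal(res2$recall, 1)
  expect_equal(res2$f1, 1)
  expect_true(res2$is_regulatory)
  expect_gte(res2$q_value, res2$p_value)
})

test_that("regulatory calls are invariant to regulon ordering", {
  universe <- sprintf("g%03d", 1:60)
  regs <- list(A = universe[1:10], B = universe[11:15], C = universe[30:40])
  im <- list(comp_000 = universe[11:15], comp_001 = universe[c(1:8, 50)])
  e1 <- best_enrichment(enrich_imodulons(im, regulon_db(regs, universe)), fdr = 1e-3)
  e2 <- best_enrichment(enrich_imodulons(im, regulon_db(rev(regs), universe)), fdr = 1e-3)
  expect_identical(e1[order(e1$component), ], e2[order(e2$component), ])
})

test_that("dimension summaries count classifications and respect absence of a TRN", {
  set.seed(812)
  universe <- sprintf("g%03d", 1:80)
  M <- matrix(0.01 * rnorm(80 * 3), 80, 3, dimnames = list(universe, NULL))
  M[5, 1] <- 10                       # single-gene component
  M[11:20, 2] <- 6 + seq(0, 1, length.out = 10)  # matches regulon exactly
  # third column: low-level noise only
  d <- fake_decomposition(M, dimension = 3)
  db <- regulon_db(list(R1 = universe[11:20]), universe)
  s <- summarize_dimension(d, db = db, conserved_count = 2L,
                           cfg = optica_config(n_runs = 2))
  expect_identical(s$n_robust, 3L)
  expect_identical(s$n_single_gene, 1L)
  expect_identical(s$n_non_single_gene, 2L)
  expect_identical(s$n_regulatory, 1L)
  expect_identical(s$n_conserved, 2L)
  expect_equal(s$mean_f1, 1)

  comps <- attr(s, "components")
  expect_identical(nrow(comps), 3L)
  expect_identical(s$n_single_gene + s$n_non_single_gene, s$n_robust)

  # no TRN: regulatory columns are absent (NA), not zero
  s0 <- summarize_dimension(d, db = NULL, cfg = optica_config(n_runs = 2))
  expect_true(is.na(s0$n_regulatory))
  expect_true(is.na(s0$mean_f1))

  # degenerate empty decomposition
  d0 <- d
  d0$M <- M[, 0, drop = FALSE]
  d0$cluster_sizes <- integer(0)
  d0$stability <- numeric(0)
  s00 <- summarize_dimension(d0, db = db, cfg = optica_config(n_runs = 2))
  expect_identical(s00$n_robust, 0L)
  expect_true(is.na(s00$mean_f1))
})
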