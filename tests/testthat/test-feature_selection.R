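test_that("spearman_rho matches hand cases and the brute-force rank oracle", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(8, 6, 4, 2)), -1)
  # tied case, expected value frozen from the explicit-sorting rank oracle
  expect_equal(oracle_spearman(c(1, 2, 2, 4), c(3, 1, 4, 5)), 0.6324555,
               tolerance = 1e-6)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(3, 1, 4, 5)),
               oracle_spearman(c(1, 2, 2, 4), c(3, 1, 4, 5)),
               tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("spearman_rho is symmetric and monotone-transform invariant", {
  set.seed(11)
  for (i in 1:20) {
    x <- sample(1:8, 10, replace = TRUE)
    y <- rnorm(10)
    expect_equal(spearman_rho(x, y), spearman_rho(y, x))
    expect_equal(spearman_rho(exp(x), y), spearman_rho(x, y))
    expect_equal(spearman_rho(x, y^3 + 5 * y), spearman_rho(x, y))
  }
})

test_that("top-k selection orders genes by |rho| with deterministic ties", {
  set.seed(3)
  n <- 40
  p <- runif(n)
  vals <- cbind(exact = p,                      # |rho| = 1, must rank first
                inv = 1 - p + rnorm(n, sd = 0.05),
                weak = p + rnorm(n, sd = 2),
                noise1 = rnorm(n), noise2 = rnorm(n))
  m <- expression_matrix(abs(vals), colnames(vals), sprintf("c%d", 1:n))
  sel <- select_top_correlated(m, p, 3)
  expect_identical(sel$genes[1], "exact")
  expect_equal(abs(sel$rho[["exact"]]), 1)
  expect_length(sel$genes, 3)
  expect_identical(sel$mode, "correlation")
  # full ordering agrees with brute-force |rho| recomputation via the oracle
  rho_or <- apply(unclass(m), 2, oracle_spearman, y = p)
  full <- select_top_correlated(m, p, 5)
  expect_identical(full$genes,
                   colnames(vals)[order(-abs(rho_or), seq_along(rho_or))])
  expect_error(select_top_correlated(m, p, 6), "between 1 and")
})

test_that("gene-pair ranking is exhaustive, oracle-ordered, and bounded", {
  set.seed(5)
  n <- 30
  base <- rnorm(n)
  vals <- abs(cbind(a = base, b = base + rnorm(n, sd = 0.1),
                    c = rnorm(n), d = rnorm(n)))
  m <- expression_matrix(vals, colnames(vals), sprintf("c%d", 1:n))
  fs <- feature_set(colnames(vals), mode = "correlation")
  all_pairs <- rank_gene_pairs(m, fs, 6)
  expect_length(all_pairs$cross_pairs, 6)  # C(4,2) exhausted
  expect_identical(all_pairs$cross_pairs[[1]], c("a", "b"))
  # ordering equals the brute-force pairwise |rho| oracle
  combos <- combn(colnames(vals), 2, simplify = FALSE)
  rr <- vapply(combos, function(p)
    abs(oracle_spearman(vals[, p[1]], vals[, p[2]])), numeric(1))
  expect_identical(all_pairs$cross_pairs, combos[order(-rr, seq_along(rr))])
  expect_error(rank_gene_pairs(m, fs, 7), "too few genes")
})

test_that("pathway feature set carries the 32-gene list and regulatory pairs", {
  fs <- pathway_feature_set()
  expect_length(fs$genes, 32)
  expect_identical(fs$genes[1], "APAF1")
  expect_identical(fs$genes[32], "XIAP")
  expect_identical(fs$mode, "pathway")
  expect_length(fs$cross_pairs, 6)
  expect_true(any(vapply(fs$cross_pairs, function(p)
    setequal(p, c("TP53", "MDM2")), logical(1))))
  expect_true(all(unlist(fs$cross_pairs) %in% fs$genes))
  # empty pair list is allowed; foreign pair members are not
  expect_length(pathway_feature_set(regulatory_pairs = list())$cross_pairs, 0)
  expect_error(pathway_feature_set(regulatory_pairs = list(c("TP53", "FOO"))),
               "not in")
})
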