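make_toy_fit <- function(coefs, genes = paste0("g", seq_len(length(coefs) - 1)),
                         degree = 1, cross_pairs = list()) {
  sp <- poly_spec(genes, degree = degree, cross_pairs = cross_pairs)
  structure(list(spec = sp, coefficients = coefs, rank = length(coefs),
                 fitted.values = numeric(), residuals = numeric(),
                 sigma = 0, n_obs = 0L), class = "fatepoly")
}

test_that("stability points stay inside observed ranges and are seeded", {
  m <- toy_matrix(n_cells = 50, genes = c("g1", "g2"))
  pts <- sample_stability_points(m, c("g1", "g2"), n_points = 500, seed = 2)
  expect_identical(dim(pts), c(500L, 2L))
  for (g in c("g1", "g2")) {
    expect_gte(min(pts[, g]), min(unclass(m)[, g]))
    expect_lte(max(pts[, g]), max(unclass(m)[, g]))
  }
  expect_identical(pts, sample_stability_points(m, c("g1", "g2"),
                                                n_points = 500, seed = 2))
  # a constant gene gives a degenerate dimension, with a warning
  mc <- expression_matrix(cbind(g1 = 1:5, flat = rep(2, 5)),
                          c("g1", "flat"), paste0("c", 1:5))
  expect_warning(pc <- sample_stability_points(mc, c("g1", "flat"), 100, 1),
                 "degenerate")
  expect_true(all(pc[, "flat"] == 2))
})

test_that("point variances follow the sample-variance definition", {
  pts <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("g1", "g2")))
  same <- replicate(100, make_toy_fit(c(0.2, 0.1, -0.3)), simplify = FALSE)
  expect_equal(point_prediction_variances(same, pts), rep(0, 10))

  # two models predicting 0 and 1 everywhere: sample variance 0.5
  m0 <- make_toy_fit(c(0, 0, 0))
  m1 <- make_toy_fit(c(1, 0, 0))
  expect_equal(point_prediction_variances(list(m0, m1), pts), rep(0.5, 10))

  set.seed(4)
  mods <- replicate(5, make_toy_fit(rnorm(3)), simplify = FALSE)
  v1 <- point_prediction_variances(mods, pts)
  v2 <- point_prediction_variances(rev(mods), pts)
  expect_equal(v1, v2)  # permutation symmetry
  expect_true(all(v1 >= 0))
  expect_error(point_prediction_variances(list(m0), pts), "at least two")
})

test_that("MVAV is the arithmetic mean with domain checks", {
  expect_equal(compute_mvav(rep(0, 5)), 0)
  expect_equal(compute_mvav(c(0.2, 0.4)), 0.3)
  set.seed(5)
  v <- rexp(50)
  expect_gte(compute_mvav(v), 0)
  expect_lte(compute_mvav(v), max(v))
  expect_error(compute_mvav(c(0.1, -0.2)), "non-negative")
  expect_error(compute_mvav(numeric()), "empty")
})

test_that("parameter ranges report min/max/width per position", {
  a <- make_toy_fit(c(0.1, 0.5, -0.2))
  b <- make_toy_fit(c(0.3, 0.4, -0.1))
  pr <- parameter_range_report(list(a, b))
  expect_equal(pr$min[1], 0.1)
  expect_equal(pr$max[1], 0.3)
  expect_equal(pr$width[1], 0.2)
  expect_true(all(pr$width >= 0))
  expect_equal(parameter_range_report(list(b, a))$width, pr$width)
  expect_equal(parameter_range_report(list(a, a))$width, rep(0, 3))
  expect_error(parameter_range_report(list(a, make_toy_fit(c(0, 1)))),
               "differing")
})

test_that("gamma fitting recovers known shapes and flags good fits", {
  set.seed(31)
  v <- rgamma(10000, shape = 2, scale = 1)
  gf <- fit_variance_distribution(v)
  expect_gt(gf$shape, 1.8); expect_lt(gf$shape, 2.2)
  expect_true(gf$pass)
  # exponential is the shape-1 special case
  ve <- rexp(10000)
  gfe <- fit_variance_distribution(ve)
  expect_gt(gfe$shape, 0.9); expect_lt(gfe$shape, 1.1)
  expect_error(fit_variance_distribution(c(v[1:100], -1)), "non-negative")
  expect_error(fit_variance_distribution(rexp(30)), "insufficient")
  # zeros are excluded and counted
  gfz <- fit_variance_distribution(c(rep(0, 7), v[1:200]))
  expect_identical(gfz$n_zero, 7L)
  expect_identical(gfz$n_used, 200L)
})

test_that("stability report combines ranges, variances, MVAV and gamma fit", {
  ds <- simulate_dataset(simulation_config(n_cells = 120, n_genes = 13,
                                           n_informative = 4, seed = 9))
  lab <- compute_death_probability(ds$matrix)
  pred <- log_transform(exclude_marker_genes(ds$matrix))
  fs <- feature_set(ds$truth$informative_genes, mode = "pathway")
  cv <- run_repeated_cv(pred, lab, cv_config(4, 2, seed = 2, degree = 1,
                                             mode = "pathway",
                                             feature_set = fs))
  pts <- sample_stability_points(pred, fs$genes, 300, seed = 1)
  rep1 <- stability_report(cv$models, pts)
  expect_s3_class(rep1, "stability_report")
  expect_identical(rep1$n_models, 8L)
  expect_equal(rep1$mvav, mean(rep1$point_variances))
  expect_identical(nrow(rep1$param_ranges), 5L)
  expect_output(print(rep1), "MVAV")
})
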