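test_that("design matrix has the specified column structure and counts", {
  m <- toy_matrix(genes = c("gA", "gB"))
  # 1 gene, degree 3: intercept, x, x^2, x^3
  X <- build_design_matrix(m, poly_spec("gA", degree = 3))
  expect_identical(colnames(X), c("(Intercept)", "gA", "gA^2", "gA^3"))
  expect_equal(X[, "gA^3"], unclass(m)[, "gA"]^3, ignore_attr = TRUE)
  expect_equal(X[, 1], rep(1, nrow(m)), ignore_attr = TRUE)

  # power blocks come before cross terms; pairs are plain products
  sp <- poly_spec(c("gA", "gB"), degree = 2,
                  cross_pairs = list(c("gA", "gB")))
  X2 <- build_design_matrix(m, sp)
  expect_identical(colnames(X2),
                   c("(Intercept)", "gA", "gB", "gA^2", "gB^2", "gA:gB"))
  expect_equal(X2[, "gA:gB"], unclass(m)[, "gA"] * unclass(m)[, "gB"],
               ignore_attr = TRUE)
  expect_error(build_design_matrix(m, poly_spec("gZ")), "absent")
})

test_that("n_params follows 1 + l*degree + M for all small specs", {
  genes <- paste0("g", 1:5)
  m <- toy_matrix(genes = genes)
  for (l in 1:5) for (d in 1:3) {
    pairs_all <- if (l >= 2) combn(genes[1:l], 2, simplify = FALSE) else list()
    for (M in 0:length(pairs_all)) {
      sp <- poly_spec(genes[1:l], degree = d,
                      cross_pairs = pairs_all[seq_len(M)])
      expect_identical(n_params(sp), 1L + l * d + M)
      expect_identical(ncol(build_design_matrix(m, sp)), n_params(sp))
    }
  }
})

test_that("least squares reproduces exact generating coefficients", {
  m <- toy_matrix(n_cells = 25, genes = c("x1", "x2"))
  v <- unclass(m)
  p <- 0.1 + 0.3 * v[, "x1"] - 0.2 * v[, "x2"]
  fit <- fate_polyfit(m, p, degree = 1)
  expect_equal(unname(coef(fit)), c(0.1, 0.3, -0.2), tolerance = 1e-10)
  expect_equal(predict(fit, m), p, tolerance = 1e-10, ignore_attr = TRUE)

  # constant response: intercept only
  fitc <- fate_polyfit(m, rep(0.42, nrow(m)), degree = 1)
  expect_equal(unname(coef(fitc)), c(0.42, 0, 0), tolerance = 1e-10)
})

test_that("solver matches the normal-equations elimination oracle", {
  set.seed(21)
  for (i in 1:25) {
    X <- cbind(1, matrix(rnorm(8 * 2), 8, 2))
    y <- rnorm(8)
    ls <- fit_least_squares(X, y)
    expect_equal(unname(ls$coefficients), oracle_ols(X, y), tolerance = 1e-8)
    # residual orthogonality to every design column
    expect_lt(max(abs(crossprod(X, ls$residuals))), 1e-6)
  }
})

test_that("rank deficiency yields a warned minimum-norm solution", {
  X <- cbind(1, 1:6, 2 * (1:6))  # third column is twice the second
  y <- c(1, 2, 2, 3, 4, 4)
  expect_warning(ls <- fit_least_squares(X, y), "rank-deficient")
  expect_identical(ls$rank, 2L)
  # the fit still satisfies the normal equations (a least-squares solution)
  expect_lt(max(abs(crossprod(X, ls$residuals))), 1e-8)
  # minimum-norm: smaller 2-norm than any equivalent perturbed solution
  null_vec <- c(0, -2, 1) / sqrt(5)
  expect_lt(sum(ls$coefficients^2),
            sum((ls$coefficients + 0.1 * null_vec)^2))
  # an under-determined system warns about both shape and rank
  expect_warning(
    expect_warning(fit_least_squares(matrix(rnorm(6), 2, 3), rnorm(2)),
                   "under-determined"),
    "rank-deficient")
})

test_that("adding a column never increases training RSS", {
  set.seed(8)
  m <- toy_matrix(n_cells = 30, genes = paste0("g", 1:3))
  p <- runif(30)
  rss <- sapply(1:3, function(d) {
    f <- fate_polyfit(m, p, degree = d)
    sum(residuals(f)^2)
  })
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("prediction follows the fitted polynomial, unclipped", {
  sp <- poly_spec(c("x1", "x2"), degree = 1)
  fit <- structure(list(spec = sp,
                        coefficients = c(`(Intercept)` = 0.1, x1 = 0.3,
                                         x2 = -0.2),
                        rank = 3L, fitted.values = numeric(), residuals = numeric(),
                        sigma = 0, n_obs = 0L), class = "fatepoly")
  newm <- expression_matrix(cbind(x1 = c(1, 0, 10), x2 = c(2, 0, 0)),
                            c("x1", "x2"), c("a", "b", "c"))
  pr <- predict(fit, newm)
  expect_equal(unname(pr), c(0.1 + 0.3 - 0.4, 0.1, 3.1))  # hand dot products
  expect_gt(max(pr), 1)  # no clipping
})

test_that("fatepoly methods are consistent", {
  m <- toy_matrix(n_cells = 40, genes = paste0("g", 1:2))
  set.seed(2)
  p <- pmin(1, pmax(0, 0.3 + 0.1 * unclass(m)[, 1] + rnorm(40, sd = 0.05)))
  fit <- fate_polyfit(m, p, degree = 2)
  expect_s3_class(fit, "fatepoly")
  expect_equal(fitted(fit) + residuals(fit), p, ignore_attr = TRUE)
  expect_length(coef(fit), n_params(fit))
  sm <- summary(fit)
  expect_gte(sm$r.squared, 0)
  expect_output(print(fit), "Polynomial cell-fate model")
  set.seed(9)
  sims <- simulate(fit, nsim = 3)
  expect_identical(dim(sims), c(40L, 3L))
  expect_equal(unname(colMeans(sims)), rep(mean(fitted(fit)), 3),
               tolerance = 0.1)
})
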