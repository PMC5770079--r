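test_that("simulation is seed-reproducible with the advertised structure", {
  cfg <- simulation_config(n_cells = 200, n_genes = 20, n_informative = 5,
                           seed = 17)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(unclass(d1$matrix), unclass(d2$matrix))
  expect_identical(d1$labels_truth, d2$labels_truth)

  expect_identical(dim(d1$matrix), c(200L, 20L))
  expect_true(all(default_marker_genes() %in% gene_ids(d1$matrix)))
  expect_true(all(unclass(d1$matrix) >= 0))
  expect_true(all(d1$labels_truth >= 0 & d1$labels_truth <= 1))
  # marker sum encodes the latent probability exactly
  combined <- rowSums(unclass(d1$matrix)[, default_marker_genes()])
  expect_equal(combined, d1$labels_truth * cfg$marker_scale,
               ignore_attr = TRUE)
})

test_that("labeling a simulated dataset recovers the latent probabilities", {
  cfg <- simulation_config(n_cells = 300, n_genes = 23, n_informative = 6,
                           noise_sd = 0, seed = 23)
  ds <- simulate_dataset(cfg)
  lab <- compute_death_probability(ds$matrix)
  expect_equal(max(lab$p_death), 1)
  expect_equal(lab$p_death, ds$labels_truth / max(ds$labels_truth),
               tolerance = 1e-12)
})

test_that("noiseless unclipped data returns the generating coefficients", {
  cfg <- simulation_config(n_cells = 500, n_genes = 15, n_informative = 3,
                           noise_sd = 0, seed = 31)
  ds <- simulate_dataset(cfg)
  expect_identical(ds$truth$n_clipped_low + ds$truth$n_clipped_high, 0L)
  z <- log_transform(ds$matrix[, ds$truth$informative_genes])
  fit <- fate_polyfit(z, ds$labels_truth, degree = 1)
  expect_equal(unname(coef(fit)), cfg$true_coefficients, tolerance = 1e-8)
})

test_that("group shift moves the disease markers in the reported direction", {
  cfg0 <- simulation_config(n_cells = 400, n_genes = 13, n_informative = 4,
                            group_shift = 0, seed = 41)
  # under the null the marker t-test should usually not reject
  hits <- sapply(1:40, function(s) {
    cfg <- simulation_config(n_cells = 400, n_genes = 13, n_informative = 4,
                             group_shift = 0, seed = 1000 + s)
    ds <- simulate_dataset(cfg)
    cmp <- compare_groups(ds$matrix, group_a = "healthy", group_b = "T2D")
    cmp$significant[cmp$label == "combined"]
  })
  expect_lte(mean(hits), 0.15)

  ds_shift <- simulate_dataset(
    simulation_config(n_cells = 400, n_genes = 13, n_informative = 4,
                      group_shift = 0.2, seed = 41))
  cmp <- compare_groups(ds_shift$matrix, group_a = "healthy", group_b = "T2D")
  expect_lt(cmp$mean_a[cmp$label == "combined"],
            cmp$mean_b[cmp$label == "combined"])
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(n_genes = 10, n_informative = 8), "room")
  expect_error(simulation_config(noise_sd = -1), "non-negative")
  expect_error(simulation_config(group_fraction = 1.4), "0, 1")
  expect_error(simulation_config(true_coefficients = c(1, 2)), "length")
})

test_that("recovery experiment recovers coefficients and selects truth", {
  rec <- recovery_experiment(simulation_config(n_cells = 800, n_genes = 30,
                                               n_informative = 6, seed = 52),
                             n_repeats = 2, n_folds = 5)
  expect_true(rec$all_informative_selected)
  big <- abs(rec$coef_table$truth) >= 0.1
  expect_true(all(rec$coef_table$rel_error[big] < 0.1))
  expect_gt(rec$cv_accuracy, 0.9)
})
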