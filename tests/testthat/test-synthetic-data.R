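small_cfg <- function(...) {
  simulation_config(n_per_group = c(AD = 2L, HC = 2L), n_batches = 1L,
                    n_compounds = 4L, flag_compounds = 0L,
                    batch_offsets = 0, n_replicates = 1L, ...)
}

test_that("invalid configurations are rejected up front", {
  expect_error(simulation_config(n_per_group = c(3, 3)), "named")
  expect_error(simulation_config(t_half = c(HC = 13.15)), "every group")
  expect_error(simulation_config(n_compounds = 2000), "1024")
  expect_error(simulation_config(flag_compounds = 200, n_compounds = 96),
               "more flag")
  expect_error(simulation_config(n_batches = 1L, batch_offsets = c(1, 2)),
               "per batch")
  # offsets that drive half-lives negative are caught before emission
  cfg <- simulation_config(n_per_group = c(AD = 2L, HC = 2L), n_batches = 1L,
                           n_compounds = 4L, flag_compounds = 0L,
                           n_replicates = 1L, batch_offsets = -50)
  expect_error(simulate_experiment(cfg, seed = 1), "non-positive")
  expect_error(simulate_feature_matrix(cfg, seed = 1), "non-positive")
})

test_that("the same seed reproduces the experiment byte for byte", {
  cfg <- simulation_config(n_per_group = c(AD = 2L, HC = 2L), n_batches = 2L,
                           n_compounds = 4L, flag_compounds = 1L,
                           n_replicates = 2L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_experiment(cfg, seed = 31, dir = d1)
  simulate_experiment(cfg, seed = 31, dir = d2)
  for (f in c("plate.csv", "metadata.csv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  f1 <- simulate_feature_matrix(cfg, seed = 31)
  f2 <- simulate_feature_matrix(cfg, seed = 31)
  expect_identical(f1$features$values, f2$features$values)
  f3 <- simulate_feature_matrix(cfg, seed = 32)
  expect_false(identical(f1$features$values, f3$features$values))
})

test_that("a degenerate config yields exactly the group baselines", {
  cfg <- small_cfg(sigma_log = 0, trace_noise = 0)
  ex <- simulate_experiment(cfg, seed = 1)
  fits <- fit_plate(ex$records)
  fits$expected <- cfg$t_half[ex$metadata$group[
    match(fits$sample_id, ex$metadata$sample_id)]]
  expect_true(all(fits$converged))
  expect_lt(max(abs(fits$half_life - fits$expected) / fits$expected), 1e-6)
  scores <- screen_compounds(fits, ex$metadata, panel_size = 2)$scores
  expect_equal(unname(scores), rep(1, 4), tolerance = 1e-6)
})

test_that("feature and trace paths coincide in the zero-noise limit", {
  cfg <- simulation_config(n_per_group = c(AD = 2L, HC = 2L), n_batches = 2L,
                           n_compounds = 5L, flag_compounds = 2L,
                           sigma_log = 0, trace_noise = 0, n_replicates = 1L)
  sim <- simulate_feature_matrix(cfg, seed = 9)
  ex <- simulate_experiment(cfg, seed = 9)
  X <- suppressWarnings(assemble_features(fit_plate(ex$records), ex$metadata))
  expect_identical(dim(X$values), dim(sim$features$values))
  common <- rownames(sim$features$values)
  rel <- abs(X$values[common, ] - sim$features$values[common, ]) /
    sim$features$values[common, ]
  expect_lt(max(rel), 1e-6)
})

test_that("planted batch offsets surface exactly in the balanced noiseless case", {
  cfg <- simulation_config(n_per_group = c(AD = 4L, HC = 4L), n_batches = 2L,
                           n_compounds = 3L, flag_compounds = 0L,
                           t_half = c(HC = 13.15, AD = 13.15),
                           group_delta = c(HC = 1, AD = -1),
                           batch_offsets = c(3, -3), sigma_log = 0)
  sim <- simulate_feature_matrix(cfg, seed = 5)
  model <- estimate_batch_baselines(sim$features)
  for (b in c("b01", "b02"))
    expect_equal(unname(model$mu[b, ]),
                 rep(13.15 + sim$truth$batch_offsets[[b]], 3))
  Z <- correct_batches(sim$features, model)
  expect_equal(unname(Z$values[, 1L]),
               unname(ifelse(Z$group == "HC", 1, -1)))
})

test_that("log-feature dispersion matches the configured noise SD", {
  cfg <- simulation_config(n_per_group = c(HC = 1000L, AD = 2L),
                           n_batches = 1L, n_compounds = 1L,
                           flag_compounds = 0L, batch_offsets = 0,
                           sigma_log = 0.05)
  sim <- simulate_feature_matrix(cfg, seed = 17)
  hc <- sim$features$values[sim$features$group == "HC", 1L]
  expect_equal(sd(log(hc)), 0.05, tolerance = 0.1)
})

test_that("rescaling every amplitude leaves fitted half-lives unchanged", {
  cfg <- small_cfg(sigma_log = 0.05, trace_noise = 0.02)
  ex <- simulate_experiment(cfg, seed = 23)
  scaled <- ex$records
  for (i in seq_along(scaled)) scaled[[i]]$intensities <-
      scaled[[i]]$intensities * 7.5
  f0 <- fit_plate(ex$records)
  f1 <- fit_plate(scaled)
  expect_equal(f1$half_life, f0$half_life, tolerance = 1e-8)
  expect_equal(f1$amplitude, f0$amplitude * 7.5, tolerance = 1e-6)
})

test_that("balanced flag effects split symmetrically in log space", {
  cfg <- simulation_config(n_per_group = c(AD = 1L, HC = 1L), n_batches = 1L,
                           n_compounds = 2L, flag_compounds = 1L,
                           flag_effect = 4, balanced_flags = TRUE,
                           t_half = c(HC = 10, AD = 10),
                           batch_offsets = 0, sigma_log = 0)
  sim <- simulate_feature_matrix(cfg, seed = 1)
  v <- sim$features$values
  g <- sim$features$group
  # log effects: +log(2) for AD, -log(2) for HC, summing to zero
  expect_equal(unname(v[g == "AD", "C0001"]), 20)
  expect_equal(unname(v[g == "HC", "C0001"]), 5)
  expect_equal(unname(v[, "C0002"]), c(10, 10))
})

test_that("a short pipeline run recovers planted flags across seeds", {
  cfg <- simulation_config(n_per_group = c(AD = 3L, HC = 3L), n_batches = 1L,
                           n_compounds = 12L, flag_compounds = 3L,
                           batch_offsets = 0, sigma_log = 0.05)
  hits <- 0L
  for (s in 1:5) {
    ex <- simulate_experiment(cfg, seed = 400 + s)
    res <- screen_compounds(fit_plate(ex$records), ex$metadata,
                            panel_size = 3)
    if (setequal(res$panel$compounds, cfg$flag_compounds)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
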