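test_that("network signals are deterministic, unit-variance and weakly correlated", {
  s1 <- simulate_network_signals(2, 200, seed = 1)
  s2 <- simulate_network_signals(2, 200, seed = 1)
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate_network_signals(2, 200, seed = 2)))
  expect_equal(dim(s1), c(2L, 200L), ignore_attr = TRUE)
  for (seed in 1:10) {
    s <- simulate_network_signals(3, 500, seed = seed)
    expect_equal(apply(s, 1, sd), rep(1, 3), tolerance = 1e-8)
    cc <- cor(t(s))
    expect_lt(max(abs(cc[upper.tri(cc)])), 0.3)
  }
  expect_error(simulate_network_signals(1, 100), ">= 2")
  expect_error(simulate_network_signals(2, 1), ">= 2")
})

test_that("planted gradient construction ties ROI voxels to their network", {
  sc <- gradient_scenario(roi_shape = c(5, 5, 5), axis = c(0, 0, 1),
                          noise_sd = 0, T_len = 150, target_block = 20,
                          seed = 4)
  sim <- simulate_gradient_bold(sc)
  expect_equal(nrow(sim$truth), ncol(sim$roi$series))
  expect_true(all(sim$truth$s >= 0 & sim$truth$s <= 1))
  # voxel at s = 0 carries network 1 only; s = 1 carries network 2 only
  v0 <- which(sim$truth$s == 0)[1]
  v1 <- which(sim$truth$s == 1)[1]
  tgt1 <- sim$target$series[, 1]                      # a network-1 voxel
  tgt2 <- sim$target$series[, ncol(sim$target$series)] # a network-2 voxel
  expect_gt(cor(sim$roi$series[, v0], tgt1), 0.999)
  expect_lt(abs(cor(sim$roi$series[, v0], tgt2)), 0.3)
  expect_gt(cor(sim$roi$series[, v1], tgt2), 0.999)
  # ROI and target masks are disjoint
  expect_length(intersect(which(sim$roi$mask), which(sim$target$mask)), 0)
})

test_that("gradient simulation is seed-deterministic", {
  sc <- gradient_scenario(roi_shape = c(4, 4, 4), T_len = 80, seed = 9,
                          target_block = 12)
  a <- simulate_gradient_bold(sc)
  b <- simulate_gradient_bold(sc)
  expect_identical(a$roi$series, b$roi$series)
  expect_identical(a$target$series, b$target$series)
  expect_identical(a$truth, b$truth)
})

test_that("degenerate scenarios are rejected", {
  expect_error(gradient_scenario(axis = c(1, 0, 0) * 2), "unit")
  expect_error(gradient_scenario(K = 1), ">= 2")
  expect_error(gradient_scenario(noise_sd = -1), ">= 0")
  sc <- gradient_scenario(roi_shape = c(2, 6, 6), axis = c(1, 0, 0))
  expect_error(simulate_gradient_bold(sc), "span")
})

test_that("artifact subjects reduce to clean subjects at n_outliers = 0", {
  sc <- gradient_scenario(roi_shape = c(4, 4, 4), T_len = 80, seed = 2,
                          target_block = 12)
  clean <- simulate_gradient_bold(sc)
  art0 <- simulate_artifact_subject(sc, n_outliers = 0)
  expect_identical(art0$roi$series, clean$roi$series)
  expect_error(simulate_artifact_subject(sc, n_outliers = 64), "V_roi")
  art <- simulate_artifact_subject(sc, n_outliers = 3, seed = 2)
  expect_equal(sum(art$truth$outlier), 3)
  changed <- which(colSums(abs(art$roi$series - clean$roi$series)) > 0)
  expect_identical(changed, which(art$truth$outlier))
})

test_that("cohort tables carry all columns and the planted couplings", {
  co <- cohort_scenario(n_subjects = 4, seed = 3)
  sim <- simulate_cohort(co)
  expect_equal(nrow(sim$table), 4)
  expect_true(all(c("subject", "age", "sex", "education", "apoe4", "ptau",
                    "immediate_memory", tsm_parameter_names(3),
                    "var_explained") %in% names(sim$table)))
  expect_equal(nrow(sim$truth), 4)

  # strong coupling: biomarker correlates with the latent score as planted
  co2 <- cohort_scenario(n_subjects = 300, effect_biomarker = 0.6, seed = 8)
  sim2 <- simulate_cohort(co2)
  r <- cor(sim2$table$ptau, sim2$truth$latent)
  expect_equal(r, 0.6, tolerance = 0.12)
  # carriers have higher latent pathology scores
  expect_gt(mean(sim2$truth$latent[sim2$table$apoe4 == 1]),
            mean(sim2$truth$latent[sim2$table$apoe4 == 0]))
})

test_that("null cohorts yield uniform downstream p-values", {
  pz <- vapply(1:200, function(s) {
    co <- cohort_scenario(n_subjects = 40, effect_biomarker = 0,
                          effect_group = 0, seed = s)
    sim <- simulate_cohort(co, gradient = gradient_scenario(
      profile = "logistic", axis = c(0, 0, 1), roi_shape = c(6, 6, 6)))
    partial_spearman(sim$table$z, sim$table$ptau,
                     sim$table[, c("age", "sex")])$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pz, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort volumes mode generates per-subject BOLD data", {
  co <- cohort_scenario(n_subjects = 4, seed = 5)
  sim <- simulate_cohort(co, gradient = gradient_scenario(
    profile = "logistic", axis = c(0, 0, 1), roi_shape = c(4, 4, 4),
    T_len = 60, target_block = 12), volumes = TRUE)
  expect_length(sim$volumes, 4)
  expect_s3_class(sim$volumes[[1]]$roi, "bold_data")
})
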