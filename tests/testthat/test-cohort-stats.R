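test_that("partial Spearman reduces to ordinary Spearman and matches its oracle", {
  set.seed(21)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  ps <- partial_spearman(x, y)
  expect_equal(ps$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  # monotone transform of x correlates perfectly with x
  expect_equal(partial_spearman(x, exp(x))$rho, 1)

  # n = 30 toy with one covariate vs the independent brute-force oracle
  for (s in 1:5) {
    set.seed(s)
    z <- matrix(rnorm(30), 30, 1)
    x <- 0.4 * z[, 1] + rnorm(30)
    y <- 0.3 * z[, 1] - 0.2 * x + rnorm(30)
    got <- partial_spearman(x, y, z)
    want <- oracle_partial_spearman(x, y, z)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
  expect_error(partial_spearman(rep(1, 20), rnorm(20)), "constant")
})

test_that("rank statistics are invariant to monotone outcome and affine covariate transforms", {
  set.seed(31)
  z <- matrix(rnorm(60), 60, 2)
  x <- rnorm(60); y <- 0.4 * x + z[, 1] + rnorm(60)
  base <- partial_spearman(x, y, z)
  warped <- partial_spearman(x, y^3 + 5 * y, 10 * z + 3)
  expect_equal(warped$rho, base$rho, tolerance = 1e-12)

  g <- rep(c("a", "b"), 30)
  v <- rnorm(60) + (g == "a")
  m1 <- adjusted_mannwhitney(v, g, z)
  m2 <- adjusted_mannwhitney(v, g, 2 * z - 7)
  expect_equal(m1$U, m2$U)
  expect_equal(m1$p, m2$p, tolerance = 1e-12)
})

test_that("Mann-Whitney U satisfies the complement identity and exact enumeration", {
  set.seed(5)
  v <- rnorm(14)
  g <- rep(c("a", "b"), 7)
  u_a <- adjusted_mannwhitney(v, factor(g, levels = c("a", "b")))$U
  u_b <- adjusted_mannwhitney(v, factor(g, levels = c("b", "a")))$U
  expect_equal(u_a + u_b, 49)

  r <- adjusted_mannwhitney(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)   # 2 of the 20 assignments are as extreme
  expect_equal(r$method, "exact")

  # normal approximation agrees with the standard implementation
  set.seed(8)
  v2 <- rnorm(40); g2 <- rep(c("x", "y"), 20)
  got <- adjusted_mannwhitney(v2, g2, exact = FALSE)
  ref <- wilcox.test(v2[g2 == "x"], v2[g2 == "y"], exact = FALSE,
                     correct = FALSE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_error(adjusted_mannwhitney(v2, rep("x", 40)), "2 levels")
})

test_that("covariates that explain the group difference flatten the test", {
  keep <- vapply(1:200, function(s) {
    set.seed(s)
    grp <- rep(0:1, each = 50)
    covar <- rnorm(100) + 1.5 * grp       # covariate carries the group shift
    vals <- 0.8 * covar + rnorm(100, 0, 0.5)  # outcome depends only on covariate
    adjusted_mannwhitney(vals, grp, matrix(covar))$p > 0.05
  }, logical(1))
  expect_gte(mean(keep), 0.9)
})

test_that("BH adjustment matches the hand rule and an independent step-up oracle", {
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    q <- fdr_bh(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("run_analysis applies the family test with listwise deletion", {
  co <- cohort_scenario(n_subjects = 60, effect_biomarker = 0.6, seed = 13)
  sim <- simulate_cohort(co)
  tab <- sim$table
  tab$ptau[1] <- NA
  res <- run_analysis(tab, analysis_spec("ptau", covariates = c("age", "sex")))
  expect_equal(nrow(res), 9)
  expect_true(all(res$n == 59))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_setequal(res$parameter, tsm_parameter_names(3))

  grp <- run_analysis(sim$table,
                      analysis_spec("apoe4", covariates = c("age", "sex"),
                                    test = "adjusted-mannwhitney"))
  expect_equal(nrow(grp), 9)
  expect_error(run_analysis(sim$table, analysis_spec("missing_col")),
               "absent")
})

test_that("conventional connectivity matches constructed examples", {
  # two voxels with known correlation
  set.seed(17)
  a <- rnorm(400)
  b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(400)
  r <- cor(a, b)
  fc <- conventional_fc(toy_bold(v = 2, t_len = 400, series = cbind(a, b)))
  expect_equal(fc, atanh(r), tolerance = 1e-12)

  # identical noiseless signals: clipped, not infinite
  expect_warning(
    fc1 <- conventional_fc(toy_bold(v = 3, t_len = 50,
                                    series = matrix(rep(sin(1:50), 3), 50))),
    "clipped")
  expect_equal(fc1, atanh(1 - 1e-7))

  # independent noise: intrinsic connectivity near zero
  vals <- vapply(1:20, function(s) {
    conventional_fc(toy_bold(v = 10, t_len = 500, seed = s, shape = c(4, 4, 4)))
  }, numeric(1))
  expect_true(all(abs(vals) < 0.05))

  # whole-brain mode on a planted subject: ROI-to-target coupling present
  sc <- gradient_scenario(roi_shape = c(4, 4, 4), T_len = 100,
                          target_block = 12, seed = 3)
  sim <- simulate_gradient_bold(sc)
  wb <- conventional_fc(sim$roi, sim$target, mode = "wholebrain")
  expect_gt(wb, 0.1)
  expect_error(conventional_fc(toy_bold(v = 2), mode = "wholebrain"),
               "bold_data")
})
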