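test_that("eta-squared matches hand-computed values and is a bounded symmetric measure", {
  expect_equal(eta_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  # pair means (0.5, 0.5), grand mean 0.5 => numerator equals denominator
  expect_equal(eta_squared(c(0, 1), c(1, 0)), 0)
  set.seed(1)
  for (i in 1:200) {
    a <- rnorm(8); b <- rnorm(8)
    e <- eta_squared(a, b)
    expect_true(e >= 0 && e <= 1)
    expect_equal(e, eta_squared(b, a))
  }
  expect_error(eta_squared(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("similarity from SVD fingerprints equals the raw-fingerprint oracle", {
  roi <- toy_bold(v = 20, t_len = 40, seed = 7)
  tgt <- toy_bold(v = 20, t_len = 40, seed = 8)
  fp <- compute_fingerprints(roi, tgt, variance_kept = 1)
  S_svd <- similarity_matrix(fp)
  # oracle: raw fingerprints = correlation with every target voxel
  Fraw <- cor(roi$series, tgt$series)
  S_raw <- matrix(1, 20, 20)
  for (i in 1:19) for (j in (i + 1):20) {
    S_raw[i, j] <- S_raw[j, i] <- eta_squared(Fraw[i, ], Fraw[j, ])
  }
  expect_lt(max(abs(S_svd - S_raw)), 1e-6)
})

test_that("fingerprint SVD retains the numerical rank and flags rank-2 targets", {
  sig <- simulate_network_signals(2, 60, seed = 1)
  tgt <- toy_bold(v = 10, t_len = 60, series = t(sig[rep(1:2, each = 5), ]))
  roi <- toy_bold(v = 4, t_len = 60, seed = 2)
  fp <- compute_fingerprints(roi, tgt, variance_kept = 1)
  expect_equal(ncol(fp$matrix), 2)
  # an ROI voxel equal to a network signal has a fingerprint proportional
  # to that network's similarity profile
  roi2 <- toy_bold(v = 4, t_len = 60,
                   series = cbind(sig[1, ], sig[2, ], sig[1, ] + 0.01 * rnorm(60),
                                  rnorm(60)))
  fp2 <- compute_fingerprints(roi2, tgt)
  S <- similarity_matrix(fp2)
  expect_gt(S[1, 3], 0.99)   # same network => nearly identical profiles
  expect_lt(S[1, 2], S[1, 3]) # different networks are less similar
  expect_error(compute_fingerprints(toy_bold(v = 4, t_len = 30), tgt),
               "timepoints")
})

test_that("similarity matrices are validated on construction", {
  S <- similarity_matrix(matrix(rnorm(50), 10, 5))
  expect_true(isSymmetric(S))
  expect_equal(diag(S), rep(1, 10))
  expect_true(all(S >= 0 & S <= 1))
})

test_that("kNN graph reproduces chain structure and escalates to connectivity", {
  # chain-structured similarity: strong only between spatial neighbours
  v <- 6
  S <- diag(v)
  for (i in 1:(v - 1)) S[i, i + 1] <- S[i + 1, i] <- 0.9
  S[S == 0] <- 0.05
  W <- build_graph(S, k_neighbors = 1, sharpen = 1)
  expect_equal(unname(W > 0), unname(S == 0.9))
  expect_equal(max(W), 0.9)

  # two tight cliques joined weakly: k = 1 is disconnected, escalation fixes it
  S2 <- matrix(0.02, 6, 6)
  S2[1:3, 1:3] <- 0.95; S2[4:6, 4:6] <- 0.95
  S2[3, 4] <- S2[4, 3] <- 0.4
  diag(S2) <- 1
  expect_message(W2 <- build_graph(S2, k_neighbors = 1, sharpen = 1),
                 "escalated")
  g <- igraph::graph_from_adjacency_matrix(W2 > 0, mode = "undirected")
  expect_true(igraph::is_connected(g))
  expect_gte(attr(W2, "k_used"), 2)

  # triangle at k = 1 stays connected
  S3 <- matrix(0.9, 3, 3); diag(S3) <- 1
  W3 <- build_graph(S3, k_neighbors = 1, sharpen = 1)
  g3 <- igraph::graph_from_adjacency_matrix(W3 > 0, mode = "undirected")
  expect_true(igraph::is_connected(g3))
})

test_that("eigenmaps match a dense generalized-eigensolver oracle", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    # random connected weighted graph: ring + random extra edges
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      W[i, j] <- W[j, i] <- runif(1, 0.5, 1)
    }
    extra <- matrix(sample(n, 20, replace = TRUE), ncol = 2)
    for (r in seq_len(nrow(extra))) {
      i <- extra[r, 1]; j <- extra[r, 2]
      if (i != j) W[i, j] <- W[j, i] <- runif(1, 0.1, 1)
    }
    maps <- laplacian_eigenmaps(W, n_gradients = 2)
    # oracle: dense non-symmetric solve of D^{-1} L v = lambda v
    D <- diag(rowSums(W))
    eo <- eigen(solve(D) %*% (D - W))
    ord <- order(Re(eo$values))
    for (k in 1:2) {
      lam <- Re(eo$values[ord[k + 1]])
      v <- Re(eo$vectors[, ord[k + 1]])
      v <- (v - min(v)) / diff(range(v))
      expect_equal(maps[[k]]$eigenvalue, lam, tolerance = 1e-8)
      err <- min(max(abs(maps[[k]]$values - v)),
                 max(abs(maps[[k]]$values - (1 - v))))
      expect_lt(err, 1e-6)
    }
  }
})

test_that("path-graph dominant gradient is monotone and normalised", {
  W <- matrix(0, 10, 10)
  for (i in 1:9) W[i, i + 1] <- W[i + 1, i] <- 1
  g <- laplacian_eigenmaps(W, 1)[[1]]
  d <- diff(g$values)
  expect_true(all(d > 0) || all(d < 0))
  expect_equal(range(g$values), c(0, 1))
})

test_that("eigenmaps are invariant to global weight scaling and flag degeneracy", {
  W <- matrix(0, 12, 12)
  for (i in 1:11) W[i, i + 1] <- W[i + 1, i] <- runif(1, 0.5, 1)
  g1 <- laplacian_eigenmaps(W, 1)[[1]]
  g10 <- laplacian_eigenmaps(10 * W, 1)[[1]]
  expect_equal(g1$values, g10$values, tolerance = 1e-10)
  expect_equal(g10$eigenvalue, g1$eigenvalue, tolerance = 1e-10)

  K <- matrix(1, 8, 8); diag(K) <- 0  # complete graph: all non-zero ties equal
  expect_message(laplacian_eigenmaps(K, 2), "not unique")
  # disconnected graph is refused
  B <- matrix(0, 6, 6)
  B[1:3, 1:3] <- 1; B[4:6, 4:6] <- 1; diag(B) <- 0
  expect_error(laplacian_eigenmaps(B, 1), "disconnected|isolated")
})

test_that("sign alignment is idempotent and fixes inverted gradients", {
  g <- gradient_map(runif(30), normalize = TRUE)
  expect_equal(align_sign(g, g)$values, g$values)
  flipped <- gradient_map(1 - g$values, normalize = FALSE)
  back <- align_sign(flipped, g)
  expect_gt(cor(back$values, g$values), 0.999)
  set.seed(2)
  for (i in 1:20) {
    a <- gradient_map(runif(15))
    b <- gradient_map(runif(15))
    expect_gte(cor(align_sign(a, b)$values, b$values), 0)
  }
  constant <- gradient_map(rep(0.5, 15), normalize = FALSE)
  expect_error(align_sign(constant, gradient_map(runif(15))), "zero-variance")
})

test_that("group gradient averages aligned maps and beats individuals", {
  base <- gradient_map(seq(0, 1, length.out = 40), normalize = FALSE)
  expect_equal(group_gradient(list(base, base))$values, base$values)
  flip <- gradient_map(1 - base$values, normalize = FALSE)
  expect_equal(group_gradient(list(base, flip))$values, base$values)

  set.seed(5)
  truth <- seq(0, 1, length.out = 60)
  noisy <- lapply(1:20, function(i) {
    v <- truth + rnorm(60, 0, 0.35)
    if (i %% 2 == 0) v <- 1 - v  # random sign flips
    gradient_map(v)
  })
  grp <- group_gradient(noisy)
  r_grp <- abs(cor(grp$values, truth))
  r_ind <- vapply(noisy, function(g) abs(cor(g$values, truth)), numeric(1))
  expect_gt(r_grp, median(r_ind))
})

test_that("pipeline is invariant to network relabeling and BOLD amplitude", {
  sc <- gradient_scenario(roi_shape = c(5, 5, 5), T_len = 120,
                          target_block = 16, seed = 11)
  sim <- simulate_gradient_bold(sc)
  g1 <- suppressMessages(connectopic_gradients(sim$roi, sim$target)[[1]])

  # relabel networks: permute target voxel order
  set.seed(1)
  perm <- sample(ncol(sim$target$series))
  tgt_perm <- sim$target
  tgt_perm$series <- tgt_perm$series[, perm]
  g2 <- suppressMessages(connectopic_gradients(sim$roi, tgt_perm)[[1]])
  expect_equal(g1$values, g2$values, tolerance = 1e-6)

  # global amplitude scaling of the BOLD signal
  roi_sc <- sim$roi; roi_sc$series <- 7.3 * roi_sc$series
  tgt_sc <- sim$target; tgt_sc$series <- 7.3 * tgt_sc$series
  g3 <- suppressMessages(connectopic_gradients(roi_sc, tgt_sc)[[1]])
  expect_equal(g1$values, g3$values, tolerance = 1e-6)
})

test_that("gradient volumes round-trip with NaN outside the ROI", {
  sc <- gradient_scenario(roi_shape = c(4, 4, 4), T_len = 80,
                          target_block = 12, seed = 6)
  sim <- simulate_gradient_bold(sc)
  g <- suppressMessages(connectopic_gradients(sim$roi, sim$target)[[1]])
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(g, f)
  img <- as.array(RNifti::readNifti(f))
  expect_equal(img[which(sim$roi$mask)], g$values, tolerance = 1e-6)
  expect_true(all(is.nan(img[which(!sim$roi$mask)])))
})
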