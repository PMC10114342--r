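# Small in-code fixtures shared across test files.

# A toy bold_data with `v` voxels on a small grid.
toy_bold <- function(v = 20, t_len = 40, seed = 1, shape = c(3, 3, 3),
                     series = NULL) {
  stopifnot(v <= prod(shape))
  mask <- array(FALSE, shape)
  mask[seq_len(v)] <- TRUE
  if (is.null(series)) {
    set.seed(seed)
    series <- matrix(rnorm(t_len * v), t_len, v)
  }
  bold_data(volume_grid(shape), mask, series)
}

# Run the full per-subject pipeline and return gradient + truth + model.
pipeline_subject <- function(seed, artifact = FALSE, n_outliers = 3) {
  sc <- gradient_scenario(seed = seed)
  sim <- if (artifact) {
    simulate_artifact_subject(sc, n_outliers = n_outliers, seed = seed)
  } else {
    simulate_gradient_bold(sc)
  }
  g <- suppressMessages(connectopic_gradients(sim$roi, sim$target)[[1]])
  model <- fit_tsm(g, make_basis(g$coords, 3))
  list(gradient = g, truth = sim$truth, model = model)
}

# Independent brute-force partial Spearman built from the definition:
# rank everything, residualise ranked x and y on ranked covariates via
# explicit normal equations, Pearson-correlate the residuals.
oracle_partial_spearman <- function(x, y, Z = NULL) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  k <- if (is.null(Z)) 0 else ncol(Z)
  if (k > 0) {
    RZ <- cbind(1, apply(Z, 2, rank))
    H <- RZ %*% solve(t(RZ) %*% RZ) %*% t(RZ)
    rx <- rx - H %*% rx
    ry <- ry - H %*% ry
  }
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  df <- n - 2 - k
  tval <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tval), df))
}

# Independent BH step-up oracle.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}
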