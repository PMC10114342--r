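# Run `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards, so the generators are deterministic
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate smooth, weakly correlated network signals
#'
#' Resting-state-like "network" time courses: Gaussian noise smoothed by
#' a moving-average filter (band-limited, no task structure), then
#' mutually orthogonalised and standardised to unit variance.
#'
#' @param K number of networks (>= 2).
#' @param T_len number of timepoints (>= 2).
#' @param seed RNG seed.
#' @param smooth moving-average window length (timepoints).
#' @return `K x T_len` matrix, one unit-variance signal per row.
#' @export
simulate_network_signals <- function(K, T_len, seed = 1, smooth = 5) {
  if (K < 2) stop("`K` must be >= 2")
  if (T_len < 2) stop("`T_len` must be >= 2")
  smooth <- max(1L, min(as.integer(smooth), T_len))
  with_seed(seed, {
    Z <- matrix(stats::rnorm((T_len + smooth) * K), T_len + smooth, K)
    Zf <- apply(Z, 2, function(z) {
      as.numeric(stats::filter(z, rep(1 / smooth, smooth), sides = 1))[-seq_len(smooth)]
    })
    Zf <- scale(Zf, scale = FALSE)
    Q <- qr.Q(qr(Zf))[, seq_len(K), drop = FALSE]
    t(scale(Q))  # K x T, mean 0, unit variance
  })
}

#' Scenario for a planted connectivity gradient
#'
#' Describes a synthetic subject: an ROI whose voxel time series mix
#' `K` network signals with weights that vary smoothly along one
#' spatial axis (the planted gradient), and a disjoint target volume of
#' voxel blocks each carrying one network signal.
#'
#' The `"linear"` profile (`w = (1 - s, s)` for `K = 2`) models constant
#' stepwise connectivity change along the gradient; the `"logistic"`
#' profile models a more clustered organisation, with `steepness`
#' controlling how abruptly and `midpoint` where (as a fraction of the
#' axis) the connectivity profile switches between networks.
#'
#' @param roi_shape 3-vector of ROI voxel counts.
#' @param K number of networks (>= 2; the logistic profile requires 2).
#' @param axis unit 3-vector, the planted gradient direction in voxel
#'   space. The default is oblique to the voxel lattice so that the
#'   planted position varies quasi-continuously across voxels (a
#'   lattice-aligned axis on a small ROI collapses it onto a handful of
#'   tied slices, which no real anatomical gradient does).
#' @param profile `"linear"` or `"logistic"` mixing profile.
#' @param steepness logistic slope (only used for `profile = "logistic"`).
#' @param midpoint logistic midpoint in `[0, 1]` along the axis.
#' @param noise_sd voxel noise standard deviation relative to the
#'   voxel's clean signal standard deviation.
#' @param T_len number of timepoints.
#' @param target_block voxels per target network block.
#' @param voxel_size voxel edge length (mm) of the default affine.
#' @param seed RNG seed.
#' @return An object of class `gradient_scenario`.
#' @export
gradient_scenario <- function(roi_shape = c(8, 8, 8), K = 2,
                              axis = c(1, 2, 9) / sqrt(86),
                              profile = c("linear", "logistic"),
                              steepness = 10, midpoint = 0.5,
                              noise_sd = 0.5, T_len = 300,
                              target_block = 48, voxel_size = 2, seed = 1) {
  profile <- match.arg(profile)
  axis <- as.numeric(axis)
  if (length(axis) != 3L || abs(sqrt(sum(axis^2)) - 1) > 1e-8) {
    stop("`axis` must be a unit 3-vector")
  }
  if (K < 2) stop("`K` must be >= 2")
  if (profile == "logistic" && K != 2) stop("logistic profile requires K = 2")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(roi_shape = as.integer(roi_shape), K = as.integer(K),
                 axis = axis, profile = profile, steepness = steepness,
                 midpoint = midpoint, noise_sd = noise_sd,
                 T_len = as.integer(T_len),
                 target_block = as.integer(target_block),
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "gradient_scenario")
}

# Mixing weights at normalised positions s (vector) -> length(s) x K
mixing_weights <- function(scenario, s) {
  K <- scenario$K
  if (scenario$profile == "logistic") {
    w2 <- stats::plogis(scenario$steepness * (s - scenario$midpoint))
    return(cbind(1 - w2, w2))
  }
  if (K == 2) return(cbind(1 - s, s))
  centers <- seq(0, 1, length.out = K)
  width <- 1 / (K - 1)
  W <- vapply(centers, function(ck) pmax(0, 1 - abs(s - ck) / width),
              numeric(length(s)))
  W / rowSums(W)
}

# Planted normalised position of each ROI voxel along the scenario axis.
planted_positions <- function(scenario, idx) {
  proj <- as.numeric(idx %*% scenario$axis)
  rng <- range(proj)
  if (diff(rng) <= 0) stop("ROI does not span the gradient axis")
  (proj - rng[1]) / diff(rng)
}

#' Simulate a subject with a planted connectivity gradient
#'
#' The ROI and the target live on one grid: the ROI occupies one block
#' of the volume and the target a disjoint block partitioned into `K`
#' network regions. Each target voxel carries one network signal plus
#' noise; each ROI voxel at planted position `s` along the scenario axis
#' carries the mixture `sum_k w_k(s) * signal_k` plus noise scaled to
#' `noise_sd` times the clean series' standard deviation.
#'
#' @param scenario a [gradient_scenario()].
#' @return List with `roi` and `target` ([bold_data()]) and `truth`, a
#'   tibble with one row per ROI voxel: voxel indices, planted position
#'   `s`, and the mixing weights.
#' @export
simulate_gradient_bold <- function(scenario) {
  stopifnot(inherits(scenario, "gradient_scenario"))
  rs <- scenario$roi_shape
  span <- abs(as.numeric((rs - 1) %*% abs(scenario$axis)))
  if (span < 2) stop("ROI too small to span the gradient axis (< 3 voxels)")
  K <- scenario$K
  tb <- scenario$target_block
  # grid: ROI block | 1-voxel gap | target slab holding K blocks stacked in y
  ty <- ceiling(K * tb / rs[3])
  shape <- c(rs[1] + 1L + 2L, max(rs[2], ty), rs[3])
  grid <- volume_grid(shape, voxel_size = scenario$voxel_size)

  roi_mask <- array(FALSE, shape)
  roi_mask[seq_len(rs[1]), seq_len(rs[2]), seq_len(rs[3])] <- TRUE
  tgt_mask <- array(FALSE, shape)
  # fill target slab in canonical voxel order with K*tb voxels
  slab_idx <- as.matrix(expand.grid(i = rs[1] + 1L + seq_len(2L),
                                    j = seq_len(shape[2]), k = seq_len(shape[3])))
  slab_lin <- slab_idx[, 1] + (slab_idx[, 2] - 1) * shape[1] +
    (slab_idx[, 3] - 1) * shape[1] * shape[2]
  slab_lin <- sort(slab_lin)
  if (length(slab_lin) < K * tb) stop("target slab too small")
  tgt_lin <- slab_lin[seq_len(K * tb)]
  tgt_mask[tgt_lin] <- TRUE

  idx_roi <- mask_indices(roi_mask)
  s <- planted_positions(scenario, idx_roi)
  W <- mixing_weights(scenario, s)

  sig <- simulate_network_signals(K, scenario$T_len, seed = scenario$seed)
  clean_roi <- W %*% sig                      # V_roi x T
  block_of <- rep(seq_len(K), each = tb)      # target voxel -> network
  clean_tgt <- sig[block_of, , drop = FALSE]  # V_tgt x T

  out <- with_seed(scenario$seed + 10^6, {
    sd_roi <- apply(clean_roi, 1, stats::sd)
    sd_roi[sd_roi <= 0] <- 1
    roi_series <- clean_roi + scenario$noise_sd * sd_roi *
      matrix(stats::rnorm(length(clean_roi)), nrow(clean_roi))
    tgt_series <- clean_tgt + scenario$noise_sd *
      matrix(stats::rnorm(length(clean_tgt)), nrow(clean_tgt))
    list(roi = t(roi_series), tgt = t(tgt_series))
  })

  truth <- tibble::tibble(i = idx_roi[, 1], j = idx_roi[, 2], k = idx_roi[, 3],
                          s = s)
  for (kk in seq_len(K)) truth[[paste0("w", kk)]] <- W[, kk]
  list(roi = bold_data(grid, roi_mask, out$roi),
       target = bold_data(grid, tgt_mask, out$tgt),
       truth = truth)
}

#' Simulate a subject whose gradient is driven by outlier voxels
#'
#' As [simulate_gradient_bold()], but `n_outliers` ROI voxels are
#' replaced by a high-amplitude artifact: a common artifact time course
#' shared by the affected voxels plus a small independent component, the
#' signature of a localized scanner or vascular artifact. These voxels
#' carry no network signal, so their connectivity fingerprints are
#' unrelated to every other voxel's while being nearly identical to each
#' other; the dominant eigenmap then isolates them — a large uniform
#' cluster at one end of the gradient scale with the outliers at the
#' other — which a smooth trend surface cannot describe. These subjects
#' are the artifact class the explained-variance quality gate rejects.
#'
#' @param scenario a [gradient_scenario()].
#' @param n_outliers number of ROI voxels to corrupt
#'   (`0 <= n_outliers < V_roi`; 0 reproduces [simulate_gradient_bold()]
#'   exactly).
#' @param amplitude artifact amplitude (in units of the network-signal
#'   standard deviation).
#' @param coherence fraction of the outlier series shared across the
#'   affected voxels; the remainder is voxel-specific noise.
#' @param seed RNG seed for outlier placement and noise; defaults to
#'   `scenario$seed`.
#' @return Same structure as [simulate_gradient_bold()], plus a logical
#'   `outlier` column in `truth`.
#' @export
simulate_artifact_subject <- function(scenario, n_outliers = 3,
                                      amplitude = 8, coherence = 0.95,
                                      seed = scenario$seed) {
  stopifnot(inherits(scenario, "gradient_scenario"))
  sim <- simulate_gradient_bold(scenario)
  v <- ncol(sim$roi$series)
  if (n_outliers < 0 || n_outliers >= v) {
    stop("`n_outliers` must be in [0, V_roi)")
  }
  sim$truth$outlier <- FALSE
  if (n_outliers == 0) return(sim)
  with_seed(seed + 2 * 10^6, {
    pick <- sample.int(v, n_outliers)
    tt <- nrow(sim$roi$series)
    shared <- stats::rnorm(tt)
    sim$roi$series[, pick] <- amplitude *
      (coherence * shared +
         (1 - coherence) * matrix(stats::rnorm(tt * n_outliers), tt))
    sim$truth$outlier[pick] <- TRUE
  })
  sim
}

#' Scenario for a simulated cohort
#'
#' Cohort-level ground truth: each subject carries a latent pathology
#' score that displaces the boundary of their connectivity gradient
#' (the logistic midpoint) toward the superior end, expanding the
#' inferior-connected cluster — the spatial signature of a more
#' clustered functional organisation. Biomarker, genotype and memory
#' columns are coupled to that latent score with stated effect sizes;
#' demographic covariates are drawn independently. Defaults follow the
#' demographics of a preclinical-AD observational cohort (age ~ 63,
#' ~70% female, ~15 years of education, ~38% ApoE e4 carriers).
#'
#' @param n_subjects number of subjects (>= 4).
#' @param effect_biomarker correlation between the latent pathology
#'   score and the biomarker column (0 = null cohort).
#' @param effect_group shift (in SD of the latent score) added for
#'   genotype-carrier subjects.
#' @param effect_memory correlation (sign included) between the latent
#'   score and the immediate-memory column.
#' @param carrier_prob probability of carrier status.
#' @param age_mean,age_sd,edu_mean,edu_sd,female_prob covariate
#'   distributions.
#' @param biomarker_mean,biomarker_sd,memory_mean,memory_sd outcome scales.
#' @param seed RNG seed.
#' @return An object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n_subjects = 100, effect_biomarker = 0.5,
                            effect_group = 0.8, effect_memory = 0,
                            carrier_prob = 0.38,
                            age_mean = 63.25, age_sd = 4.97,
                            edu_mean = 15.49, edu_sd = 3.45,
                            female_prob = 0.70,
                            biomarker_mean = 48.39, biomarker_sd = 18.12,
                            memory_mean = 103.06, memory_sd = 11.07,
                            seed = 1) {
  if (n_subjects < 4) stop("`n_subjects` must be >= 4")
  stopifnot(is.finite(effect_biomarker), is.finite(effect_group),
            is.finite(effect_memory),
            abs(effect_biomarker) <= 1, abs(effect_memory) <= 1)
  structure(as.list(environment()), class = "cohort_scenario")
}

#' Simulate a cohort table with planted biomarker couplings
#'
#' For each subject a planted gradient is built on the ROI grid of
#' `gradient`: the logistic mixing profile evaluated at each voxel's
#' planted position, with the midpoint displaced by the subject's
#' latent pathology score, plus voxelwise measurement noise. An
#' order-`fit_order` trend surface is fit to it, and the spatial
#' coefficients enter the cohort table next to the simulated
#' covariates, biomarker, genotype and memory columns. With
#' `volumes = TRUE` the full 4D BOLD data of every subject are also
#' generated (slow; intended for small cohorts).
#'
#' @param cohort a [cohort_scenario()].
#' @param gradient a [gradient_scenario()] describing the ROI geometry
#'   and the baseline profile (its `midpoint` is the healthy value).
#'   The default plants the gradient along the pure z (inferior to
#'   superior) axis, so only z-family coefficients carry the coupling
#'   and the x/y families act as built-in negative controls.
#' @param fit_order trend-surface order for the coefficient columns.
#' @param gradient_noise_sd voxelwise measurement noise added to the
#'   planted gradient before fitting.
#' @param midpoint_shift maximum midpoint displacement (axis fraction)
#'   reached at the upper extreme of the latent score.
#' @param volumes also generate per-subject BOLD volumes.
#' @return List with `table` (tibble: one row per subject with
#'   covariates, outcomes, coefficient columns and `var_explained`),
#'   `truth` (tibble of the latent scores and planted midpoints), and
#'   `volumes` (list of per-subject simulations, or `NULL`).
#' @export
simulate_cohort <- function(cohort,
                            gradient = gradient_scenario(profile = "logistic",
                                                         axis = c(0, 0, 1)),
                            fit_order = 3, gradient_noise_sd = 0.05,
                            midpoint_shift = 0.3, volumes = FALSE) {
  stopifnot(inherits(cohort, "cohort_scenario"),
            inherits(gradient, "gradient_scenario"))
  n <- cohort$n_subjects
  roi_mask <- array(TRUE, gradient$roi_shape)
  grid <- volume_grid(gradient$roi_shape, voxel_size = gradient$voxel_size)
  idx <- mask_indices(roi_mask)
  s <- planted_positions(gradient, idx)
  coords <- world_coords(grid, roi_mask)
  basis <- make_basis(coords, order = fit_order)

  draws <- with_seed(cohort$seed, {
    carrier <- stats::rbinom(n, 1, cohort$carrier_prob)
    z <- stats::rnorm(n) + cohort$effect_group * carrier
    z_std <- (z - mean(z)) / stats::sd(z)
    mix <- function(r) r * z_std + sqrt(1 - r^2) * stats::rnorm(n)
    list(
      carrier = carrier, z = z, z_std = z_std,
      biomarker = cohort$biomarker_mean +
        cohort$biomarker_sd * mix(cohort$effect_biomarker),
      memory = cohort$memory_mean +
        cohort$memory_sd * mix(-abs(cohort$effect_memory)),  # declines with pathology
      age = stats::rnorm(n, cohort$age_mean, cohort$age_sd),
      edu = stats::rnorm(n, cohort$edu_mean, cohort$edu_sd),
      sex = stats::rbinom(n, 1, cohort$female_prob),
      gnoise = matrix(stats::rnorm(n * length(s), 0, gradient_noise_sd),
                      length(s), n)
    )
  })
  midpoints <- gradient$midpoint + midpoint_shift * stats::pnorm(draws$z_std)

  par_names <- tsm_parameter_names(fit_order)
  coefs <- matrix(NA_real_, n, length(par_names),
                  dimnames = list(NULL, par_names))
  ve <- numeric(n)
  for (i in seq_len(n)) {
    sc_i <- gradient
    sc_i$profile <- "logistic"
    sc_i$midpoint <- midpoints[i]
    g <- mixing_weights(sc_i, s)[, 2] + draws$gnoise[, i]
    g <- (g - min(g)) / (max(g) - min(g))
    m <- fit_tsm(g, basis)
    coefs[i, ] <- m$coefficients
    ve[i] <- m$var_explained
  }

  tab <- tibble::tibble(
    subject = sprintf("sub-%03d", seq_len(n)),
    age = draws$age, sex = draws$sex, education = draws$edu,
    apoe4 = draws$carrier, ptau = draws$biomarker,
    immediate_memory = draws$memory
  )
  tab <- cbind(tab, tibble::as_tibble(coefs))
  tab$var_explained <- ve
  tab <- tibble::as_tibble(tab)

  truth <- tibble::tibble(subject = tab$subject, latent = draws$z_std,
                          midpoint = midpoints,
                          effect_biomarker = cohort$effect_biomarker,
                          effect_group = cohort$effect_group,
                          effect_memory = cohort$effect_memory)

  vols <- NULL
  if (volumes) {
    vols <- lapply(seq_len(n), function(i) {
      sc_i <- gradient
      sc_i$profile <- "logistic"
      sc_i$midpoint <- midpoints[i]
      sc_i$seed <- gradient$seed + i
      simulate_gradient_bold(sc_i)
    })
  }
  list(table = tab, truth = truth, volumes = vols)
}
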