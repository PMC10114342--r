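#' Partial Spearman rank correlation
#'
#' Rank-transforms `x`, `y`, and the covariates, residualises the ranked
#' `x` and `y` on the ranked covariates (with intercept) by least
#' squares, and correlates the residuals. Without covariates this is
#' the ordinary Spearman correlation. The p-value uses the t
#' approximation with `df = n - 2 - n_covariates`.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix / data frame of covariates.
#' @return List with `rho`, `p`, `n`, `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  if (!is.null(Z) && nrow(Z) != length(x)) stop("covariate rows differ from n")
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(Z)) ok <- ok & apply(Z, 1, function(r) all(is.finite(r)))
  x <- x[ok]; y <- y[ok]
  if (!is.null(Z)) Z <- Z[ok, , drop = FALSE]
  k <- if (is.null(Z)) 0L else ncol(Z)
  n <- length(x)
  if (n < k + 3L) stop("need at least ", k + 3L, " complete observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant variable after ranking")
  }
  if (k > 0L) {
    RZ <- cbind(1, apply(Z, 2, rank))
    rx <- stats::lm.fit(RZ, rx)$residuals
    ry <- stats::lm.fit(RZ, ry)$residuals
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  list(rho = rho, p = min(p, 1), n = n, df = df)
}

#' Covariate-adjusted Mann-Whitney U test
#'
#' "Controlling for" covariates is implemented as linear
#' residualisation: the values are residualised on the covariates (with
#' intercept) across all subjects, then a two-sided Mann-Whitney U test
#' compares the residuals between groups. With both groups of size at
#' most 8 (and `exact` not `FALSE`) the p-value comes from exact
#' enumeration of all group assignments; otherwise from the normal
#' approximation with tie correction (no continuity correction).
#'
#' @param values numeric outcome vector.
#' @param group two-level factor or vector; `U` counts wins of the
#'   first level.
#' @param covariates optional covariate matrix / data frame.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default decides by group sizes.
#' @return List with `U`, `p`, `n1`, `n2`, `method`.
#' @export
adjusted_mannwhitney <- function(values, group, covariates = NULL,
                                 exact = NULL) {
  values <- as.numeric(values)
  g <- factor(group)
  if (nlevels(g) != 2L) stop("`group` must have exactly 2 levels")
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- is.finite(values) & !is.na(g)
  if (!is.null(Z)) ok <- ok & apply(Z, 1, function(r) all(is.finite(r)))
  values <- values[ok]; g <- droplevels(g[ok])
  if (!is.null(Z)) Z <- Z[ok, , drop = FALSE]
  if (nlevels(g) != 2L) stop("a group is empty after listwise deletion")
  k <- if (is.null(Z)) 0L else ncol(Z)
  n <- length(values)
  if (n < k + 4L) stop("need at least ", k + 4L, " complete observations")
  res <- if (k > 0L) stats::lm.fit(cbind(1, Z), values)$residuals else values
  i1 <- g == levels(g)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  if (n1 == 0L || n2 == 0L) stop("a group is empty")
  r <- rank(res)
  U <- sum(r[i1]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (is.null(exact)) exact <- n1 <= 8L && n2 <= 8L
  if (exact) {
    combs <- utils::combn(n, n1)
    Us <- apply(combs, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) stop("all values tied; test undefined")
    z <- (U - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p = min(p, 1), n1 = n1, n2 = n2, method = method)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, clipped at 1).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
fdr_bh <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (!length(pvals)) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Specification of one family of cohort tests
#'
#' @param outcome outcome column name (biomarker, genotype, or memory).
#' @param parameters parameter columns to test, typically the spatial
#'   trend-surface coefficients from [tsm_parameter_names()].
#' @param covariates covariate column names to adjust for.
#' @param test `"partial-spearman"` for continuous outcomes or
#'   `"adjusted-mannwhitney"` for two-group outcomes.
#' @return An object of class `analysis_spec`.
#' @export
analysis_spec <- function(outcome, parameters = tsm_parameter_names(3),
                          covariates = c("age", "sex"),
                          test = c("partial-spearman", "adjusted-mannwhitney")) {
  test <- match.arg(test)
  structure(list(outcome = outcome, parameters = parameters,
                 covariates = covariates, test = test),
            class = "analysis_spec")
}

#' Run one FDR family of covariate-adjusted tests
#'
#' Applies the spec's test to each parameter column against the outcome
#' (listwise deletion of missing values per test), then adjusts the
#' family's p-values by Benjamini-Hochberg. The cohort passed in should
#' already be restricted to QC-included subjects.
#'
#' @param cohort data frame of per-subject rows.
#' @param spec an [analysis_spec()].
#' @return Tibble sorted by `p`: `parameter`, `statistic` (rho or U),
#'   `p`, `q`, `n`.
#' @export
run_analysis <- function(cohort, spec) {
  stopifnot(inherits(spec, "analysis_spec"))
  missing_cols <- setdiff(c(spec$outcome, spec$parameters, spec$covariates),
                          names(cohort))
  if (length(missing_cols)) {
    stop("columns absent from cohort: ", paste(missing_cols, collapse = ", "))
  }
  Z <- if (length(spec$covariates)) {
    as.matrix(as.data.frame(cohort[spec$covariates]))
  } else NULL
  out <- lapply(spec$parameters, function(par) {
    if (spec$test == "partial-spearman") {
      r <- partial_spearman(cohort[[par]], cohort[[spec$outcome]], Z)
      tibble::tibble(parameter = par, statistic = r$rho, p = r$p, n = r$n)
    } else {
      r <- adjusted_mannwhitney(cohort[[par]], cohort[[spec$outcome]], Z)
      tibble::tibble(parameter = par, statistic = r$U, p = r$p,
                     n = r$n1 + r$n2)
    }
  })
  out <- do.call(rbind, out)
  out$q <- fdr_bh(out$p)
  out[order(out$p), c("parameter", "statistic", "p", "q", "n")]
}

#' Conventional connectivity summary measures
#'
#' Baseline scalar measures against which gradient-based parameters can
#' be compared: intrinsic connectivity of a mask (mean Fisher-z of all
#' within-mask pairwise voxel correlations) and whole-brain
#' connectivity of a mask (mean Fisher-z of all mask-to-target voxel
#' correlations). Perfect correlations are clipped at
#' `atanh(1 - 1e-7)` with a warning.
#'
#' @param bold a [bold_data()] for the mask.
#' @param target a [bold_data()] for the target (whole-brain) voxels;
#'   required for `mode = "wholebrain"`.
#' @param mode `"intrinsic"` or `"wholebrain"`.
#' @return Scalar mean Fisher-z connectivity.
#' @export
conventional_fc <- function(bold, target = NULL,
                            mode = c("intrinsic", "wholebrain")) {
  mode <- match.arg(mode)
  stopifnot(is_bold_data(bold))
  clip <- 1 - 1e-7
  if (mode == "intrinsic") {
    if (ncol(bold$series) < 2L) stop("intrinsic mode needs >= 2 mask voxels")
    R <- stats::cor(bold$series)
    r <- R[upper.tri(R)]
  } else {
    stopifnot(is_bold_data(target))
    if (nrow(bold$series) != nrow(target$series)) {
      stop("mask and target timepoints differ")
    }
    r <- as.vector(stats::cor(bold$series, target$series))
  }
  if (any(abs(r) >= clip)) {
    warning("perfect correlations clipped at atanh(1 - 1e-7)", call. = FALSE)
  }
  mean(atanh(pmin(pmax(r, -clip), clip)))
}
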