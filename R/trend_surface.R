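#' Polynomial trend-surface basis over world coordinates
#'
#' Per-axis monomials of the standardized world coordinates up to power
#' `order`, without cross terms: at order 3 the columns are
#' `x, y, z, x2, y2, z2, x3, y3, z3` — nine spatial basis functions over
#' the three axes of (MNI-like) space. Coordinates are z-scored per axis
#' before powering so the design stays well conditioned and coefficients
#' are comparable across subjects sharing a mask. The intercept is
#' handled internally by the fitting routine and is not a basis column.
#'
#' @param coords numeric `V x 3` matrix of world (mm) voxel coordinates.
#' @param order polynomial order `m >= 1`; the basis has `3 * m` columns.
#' @return An object of class `tsm_basis`: list with `X` (the design),
#'   `order`, `centers`, `scales`, and `degenerate` (logical per axis;
#'   a degenerate axis — all voxels sharing one coordinate — has its
#'   columns zeroed and flagged, with a warning).
#' @export
make_basis <- function(coords, order = 3) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("`coords` must have 3 columns")
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be >= 1")
  if (nrow(coords) < 3L * order + 1L) {
    stop("need at least ", 3L * order + 1L, " voxels for order ", order)
  }
  centers <- colMeans(coords)
  scales <- apply(coords, 2, stats::sd)
  degenerate <- scales <= 0
  if (any(degenerate)) {
    warning("degenerate axis (constant coordinate): ",
            paste(c("x", "y", "z")[degenerate], collapse = ", "),
            "; its basis columns are zeroed", call. = FALSE)
    scales[degenerate] <- 1
  }
  Z <- sweep(sweep(coords, 2, centers, "-"), 2, scales, "/")
  Z[, degenerate] <- 0
  axes <- c("x", "y", "z")
  X <- do.call(cbind, lapply(seq_len(order), function(p) Z^p))
  colnames(X) <- unlist(lapply(seq_len(order), function(p) {
    if (p == 1L) axes else paste0(axes, p)
  }))
  structure(list(X = X, order = order, centers = centers, scales = scales,
                 degenerate = degenerate), class = "tsm_basis")
}

#' Names of the spatial coefficients at a given order
#' @param order polynomial order.
#' @return Character vector, e.g. `c("x","y","z","x2",...,"z3")` at order 3.
#' @export
tsm_parameter_names <- function(order = 3) {
  axes <- c("x", "y", "z")
  unlist(lapply(seq_len(order), function(p) {
    if (p == 1L) axes else paste0(axes, p)
  }))
}

# Evidence-maximised Bayesian ridge on a centred design.
# Model: y = X b + e, e ~ N(0, 1/beta), b ~ N(0, I/alpha); alpha and
# beta set by type-II maximum likelihood (fixed-point iteration on the
# effective number of parameters gamma).
ridge_evidence <- function(X, y, max_iter = 500, tol = 1e-10) {
  n <- nrow(X)
  p <- ncol(X)
  sv <- svd(X, nu = min(n, p), nv = p)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, y)
  yty <- sum(y^2)
  beta <- 1 / max(stats::var(y), 1e-12)
  alpha <- 1e-3 * beta * max(d2, 1)
  for (it in seq_len(max_iter)) {
    coef_v <- (beta * sv$d * uty) / (alpha + beta * d2)  # in V-basis
    m2 <- sum(coef_v^2)
    fitted_u <- sv$d * coef_v
    rss <- yty - 2 * sum(uty * fitted_u) + sum(fitted_u^2)
    rss <- max(rss, 1e-300)
    gamma <- sum(beta * d2 / (alpha + beta * d2))
    alpha_new <- gamma / max(m2, 1e-300)
    beta_new <- max(n - gamma, 1e-6) / rss
    if (abs(log(alpha_new / alpha)) < tol && abs(log(beta_new / beta)) < tol) {
      alpha <- alpha_new; beta <- beta_new
      break
    }
    alpha <- alpha_new
    beta <- beta_new
  }
  coef_v <- (beta * sv$d * uty) / (alpha + beta * d2)
  coef <- drop(sv$v %*% coef_v)
  fitted_u <- sv$d * coef_v
  rss <- max(yty - 2 * sum(uty * fitted_u) + sum(fitted_u^2), 0)
  list(coef = coef, alpha = alpha, beta = beta, rss = rss,
       log_evidence = ridge_log_evidence_core(n, p, d2, yty, uty, sv$d,
                                              alpha, beta))
}

ridge_log_evidence_core <- function(n, p, d2, yty, uty, d, alpha, beta) {
  coef_v <- (beta * d * uty) / (alpha + beta * d2)
  fitted_u <- d * coef_v
  rss <- max(yty - 2 * sum(uty * fitted_u) + sum(fitted_u^2), 0)
  m2 <- sum(coef_v^2)
  e_m <- beta / 2 * rss + alpha / 2 * m2
  log_det_a <- sum(log(alpha + beta * d2)) + (p - length(d2)) * log(alpha)
  p / 2 * log(alpha) + n / 2 * log(beta) - e_m - log_det_a / 2 -
    n / 2 * log(2 * pi)
}

#' Log marginal likelihood of a trend-surface fit at given precisions
#'
#' Evaluates the evidence of the Bayesian ridge model for explicit
#' prior precision `alpha` and noise precision `beta`, e.g. to verify
#' that the precisions chosen by [fit_tsm()] maximise it.
#'
#' @param values gradient values (one per voxel) or a [gradient_map()].
#' @param basis a [tsm_basis()] whose rows match the voxels.
#' @param alpha coefficient-prior precision (> 0).
#' @param beta noise precision (> 0).
#' @return Log marginal likelihood (scalar).
#' @export
tsm_log_evidence <- function(values, basis, alpha, beta) {
  stopifnot(inherits(basis, "tsm_basis"), alpha > 0, beta > 0)
  if (inherits(values, "gradient_map")) values <- values$values
  y <- values - mean(values)
  X <- scale(basis$X, scale = FALSE)
  sv <- svd(X, nu = min(dim(X)), nv = ncol(X))
  ridge_log_evidence_core(nrow(X), ncol(X), sv$d^2, sum(y^2),
                          crossprod(sv$u, y), sv$d, alpha, beta)
}

#' Fit a trend-surface model to a gradient
#'
#' Bayesian linear regression of the gradient values on the polynomial
#' spatial basis, with a zero-mean isotropic prior on the spatial
#' coefficients; the prior and noise precisions are set by evidence
#' maximisation (type-II maximum likelihood). The intercept is fit
#' implicitly by centring and is not counted among the spatial
#' parameters. Explained variance is
#' `1 - RSS / TSS` of the gradient values under the posterior-mean
#' coefficients.
#'
#' @param values gradient values (numeric, one per basis row) or a
#'   [gradient_map()].
#' @param basis a [tsm_basis()].
#' @return An object of class `tsm_model`: named `coefficients`
#'   (`3 * order` entries), `intercept`, `alpha`, `beta`,
#'   `var_explained`, `order`, `n`, `log_evidence`.
#' @export
fit_tsm <- function(values, basis) {
  stopifnot(inherits(basis, "tsm_basis"))
  if (inherits(values, "gradient_map")) values <- values$values
  values <- as.numeric(values)
  if (length(values) != nrow(basis$X)) {
    stop("basis rows (", nrow(basis$X), ") do not match gradient voxels (",
         length(values), ")")
  }
  if (length(values) <= ncol(basis$X)) {
    stop("fewer voxels than basis columns")
  }
  xbar <- colMeans(basis$X)
  X <- sweep(basis$X, 2, xbar, "-")
  ybar <- mean(values)
  y <- values - ybar
  fit <- ridge_evidence(X, y)
  tss <- sum(y^2)
  ve <- if (tss > 0) 1 - fit$rss / tss else 0
  coefs <- stats::setNames(fit$coef, colnames(basis$X))
  structure(list(
    coefficients = coefs,
    intercept = ybar - sum(xbar * fit$coef),
    alpha = fit$alpha, beta = fit$beta,
    var_explained = min(max(ve, 0), 1),
    order = basis$order, n = length(values),
    log_evidence = fit$log_evidence
  ), class = "tsm_model")
}

#' @export
print.tsm_model <- function(x, ...) {
  cat("<tsm_model> order ", x$order, ", ", length(x$coefficients),
      " spatial coefficients, var explained ",
      round(x$var_explained, 3), "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Explained variance across model orders
#'
#' Fits a trend-surface model independently at each order `1..max_order`
#' and reports the explained variance of each, to judge where extra
#' polynomial flexibility stops paying off.
#'
#' @param values gradient values or a [gradient_map()].
#' @param coords `V x 3` world coordinates.
#' @param max_order highest order to fit (>= 1).
#' @return Named numeric vector of `var_explained`, one entry per order.
#' @export
variance_profile <- function(values, coords, max_order = 3) {
  if (inherits(values, "gradient_map")) {
    if (is.null(coords) && !is.null(values$coords)) coords <- values$coords
    values <- values$values
  }
  stopifnot(max_order >= 1)
  out <- vapply(seq_len(max_order), function(m) {
    fit_tsm(values, make_basis(coords, order = m))$var_explained
  }, numeric(1))
  stats::setNames(out, paste0("order", seq_len(max_order)))
}
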