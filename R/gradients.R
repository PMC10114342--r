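#' Connectivity fingerprints of ROI voxels against a target mask
#'
#' The fingerprint of an ROI voxel is the vector of Pearson correlations
#' between its time series and the target-mask voxel series. For
#' efficiency the target series are first decomposed by SVD and each ROI
#' voxel is correlated with the retained temporal components, scaled by
#' their singular values. Because the full correlation fingerprint is an
#' orthogonal rotation of this compressed form (times a constant), the
#' eta-squared similarity of the full fingerprints can be recovered
#' exactly from the compressed matrix together with the component
#' loading sums, which [similarity_matrix()] does.
#'
#' @param roi,target [bold_data()] with identical numbers of timepoints.
#' @param variance_kept fraction of target variance (cumulative squared
#'   singular values) retained; `1` keeps every component up to the
#'   numerical rank, which makes the compression lossless.
#' @return An object of class `fingerprints`: list with `matrix`
#'   (`V_roi x C`, singular-value scaled component correlations),
#'   `singular_values`, `loading_sums` (column sums of the retained
#'   right singular vectors), and `n_target`.
#' @export
compute_fingerprints <- function(roi, target, variance_kept = 1) {
  stopifnot(is_bold_data(roi), is_bold_data(target))
  if (nrow(roi$series) != nrow(target$series)) {
    stop("roi and target must have the same number of timepoints")
  }
  if (variance_kept <= 0 || variance_kept > 1) {
    stop("`variance_kept` must be in (0, 1]")
  }
  tt <- nrow(target$series)
  X <- target$series
  sdx <- apply(X, 2, stats::sd)
  if (all(sdx <= 0)) stop("target has no variance")
  if (any(sdx <= 0)) {
    warning(sum(sdx <= 0), " constant target voxel(s) dropped from the SVD",
            call. = FALSE)
    X <- X[, sdx > 0, drop = FALSE]
  }
  Xs <- scale(X)
  sv <- svd(Xs)
  rank <- sum(sv$d > sv$d[1] * max(dim(Xs)) * .Machine$double.eps)
  frac <- cumsum(sv$d[seq_len(rank)]^2) / sum(sv$d[seq_len(rank)]^2)
  C <- which(frac >= variance_kept - 1e-12)[1]
  if (is.na(C)) C <- rank

  R <- roi$series
  sdr <- apply(R, 2, stats::sd)
  Rs <- scale(R)
  if (any(sdr <= 0)) {
    warning(sum(sdr <= 0), " constant ROI voxel(s) given all-zero fingerprints",
            call. = FALSE)
    Rs[, sdr <= 0] <- 0
  }
  # cor(roi_v, u_j) = Rs' u_j / sqrt(T - 1) since u_j is mean-zero, unit-norm
  corr <- crossprod(Rs, sv$u[, seq_len(C), drop = FALSE]) / sqrt(tt - 1)
  fp <- corr %*% diag(sv$d[seq_len(C)], nrow = C)
  structure(list(
    matrix = fp,
    singular_values = sv$d[seq_len(C)],
    loading_sums = colSums(sv$v[, seq_len(C), drop = FALSE]),
    n_target = ncol(Xs),
    variance_kept = frac[C]
  ), class = "fingerprints")
}

#' @export
print.fingerprints <- function(x, ...) {
  cat("<fingerprints> ", nrow(x$matrix), " ROI voxels x ", ncol(x$matrix),
      " components (", round(100 * x$variance_kept, 2),
      "% target variance)\n", sep = "")
  invisible(x)
}

#' Eta-squared similarity of two connectivity profiles
#'
#' \deqn{\eta^2 = 1 - \frac{\sum_i (a_i - m_i)^2 + (b_i - m_i)^2}
#'                         {\sum_i (a_i - M)^2 + (b_i - M)^2}}
#' with \eqn{m_i = (a_i + b_i)/2} and \eqn{M} the mean over all elements
#' of both profiles. Equal profiles give 1; the value lies in `[0, 1]`
#' and is symmetric in its arguments.
#'
#' @param a,b numeric vectors of equal length (at least 2).
#' @return A scalar in `[0, 1]`.
#' @export
eta_squared <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  if (length(a) < 2L) stop("profiles must have length >= 2")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite profile values")
  m <- (a + b) / 2
  M <- mean(c(a, b))
  num <- sum((a - m)^2 + (b - m)^2)
  den <- sum((a - M)^2 + (b - M)^2)
  if (den <= 0) {
    if (num <= 0) return(1)
    stop("degenerate profiles: zero total deviation but unequal")
  }
  min(max(1 - num / den, 0), 1)
}

# eta-squared matrix from row profiles F (optionally living in a rotated
# basis: `loading_sums` maps rows back to element sums in the original
# space of `n` elements). Identity used: with m_i = (a+b)/2,
#   numerator = ||a - b||^2 / 2,
#   denominator = ||a||^2 + ||b||^2 - (sum(a) + sum(b))^2 / (2 n).
eta_squared_rows <- function(F, loading_sums = NULL, n = ncol(F)) {
  G <- tcrossprod(F)
  r <- diag(G)
  t_ <- if (is.null(loading_sums)) rowSums(F) else drop(F %*% loading_sums)
  rr <- outer(r, r, "+")
  num <- (rr - 2 * G) / 2
  den <- rr - outer(t_, t_, "+")^2 / (2 * n)
  E <- 1 - num / pmax(den, .Machine$double.xmin)
  E[den <= 0 & num <= 1e-12 * pmax(rr, 1)] <- 1
  E <- (E + t(E)) / 2
  E[E < 0] <- 0
  E[E > 1] <- 1
  diag(E) <- 1
  E
}

#' Eta-squared similarity matrix between all ROI voxel fingerprints
#'
#' For a `fingerprints` object the similarity is that of the full
#' (voxel-space) correlation fingerprints, evaluated exactly in the SVD
#' basis; for a plain matrix each row is treated as a raw profile.
#' The result is validated to be symmetric with unit diagonal and
#' entries in `[0, 1]`.
#'
#' @param x a `fingerprints` object from [compute_fingerprints()], or a
#'   numeric matrix of row profiles.
#' @return A symmetric `V x V` similarity matrix.
#' @export
similarity_matrix <- function(x) {
  if (inherits(x, "fingerprints")) {
    E <- eta_squared_rows(x$matrix, loading_sums = x$loading_sums,
                          n = x$n_target)
  } else {
    x <- as.matrix(x)
    if (nrow(x) < 2L) stop("need at least 2 profiles")
    E <- eta_squared_rows(x)
  }
  stopifnot(isSymmetric(E), all(abs(diag(E) - 1) < 1e-12),
            all(E >= 0 & E <= 1))
  E
}

#' Sparsified connected graph from a similarity matrix
#'
#' Keeps, for each voxel, its `k_neighbors` most similar neighbours
#' (symmetric union), weighted by the contrast-sharpened similarity
#' `eta2^sharpen`. If the resulting graph is disconnected, `k` is
#' doubled until it is connected; the value used is recorded in
#' `attr(, "k_used")` and reported via `message()`.
#'
#' Sharpening is a strictly monotone transform, so it changes neither
#' which neighbours are selected nor the graph's edge set; it widens the
#' weight contrast between strong and weak edges. Eta-squared saturates
#' from below at about 0.5 for unrelated profiles, so without sharpening
#' a clique of genuinely aberrant voxels stays so strongly tied to the
#' rest of the graph that it can never dominate the embedding the way
#' artifactual voxels do in real data; with sharpening the smooth
#' gradient structure of normal data is unaffected while aberrant
#' cliques decouple.
#'
#' @param S eta-squared similarity matrix (symmetric, unit diagonal,
#'   values in `[0,1]`).
#' @param k_neighbors number of nearest neighbours to keep (>= 1).
#' @param sharpen exponent applied to the similarity to form edge
#'   weights; `1` keeps raw eta-squared weights.
#' @param dense if `TRUE`, skip sparsification and return the sharpened
#'   similarity with a zeroed diagonal.
#' @return Weighted adjacency matrix (zero diagonal, symmetric).
#' @export
build_graph <- function(S, k_neighbors = 8, sharpen = 20, dense = FALSE) {
  S <- as.matrix(S)
  v <- nrow(S)
  if (v < 2L || ncol(S) != v) stop("similarity matrix must be at least 2x2 and square")
  if (sharpen <= 0) stop("`sharpen` must be > 0")
  if (dense) {
    W <- S^sharpen
    diag(W) <- 0
    attr(W, "k_used") <- v - 1L
    return(W)
  }
  k <- as.integer(k_neighbors)
  if (k < 1L) stop("`k_neighbors` must be >= 1")
  repeat {
    W <- matrix(0, v, v)
    for (i in seq_len(v)) {
      ord <- order(S[i, -i], decreasing = TRUE)
      nb <- seq_len(v)[-i][ord[seq_len(min(k, v - 1L))]]
      W[i, nb] <- S[i, nb]
    }
    W <- pmax(W, t(W))  # union of directed kNN edges
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    if (igraph::is_connected(g) || k >= v - 1L) break
    k <- min(2L * k, v - 1L)
    message("graph disconnected; k_neighbors escalated to ", k)
  }
  W <- W^sharpen
  diag(W) <- 0
  attr(W, "k_used") <- k
  W
}

#' Construct a gradient map
#'
#' One scalar per ROI voxel, min-max normalised to `[0, 1]`, with the
#' associated Laplacian eigenvalue and gradient index (1 = dominant).
#'
#' @param values numeric vector of per-voxel gradient values.
#' @param eigenvalue generalized Laplacian eigenvalue.
#' @param index gradient rank (1 = smallest non-zero eigenvalue).
#' @param grid,mask optional spatial context for writing volumes.
#' @param coords optional `V x 3` world coordinates of the voxels.
#' @param flipped whether the sign convention has been flipped.
#' @param normalize min-max normalise `values` to `[0, 1]`.
#' @return An object of class `gradient_map`.
#' @export
gradient_map <- function(values, eigenvalue = NA_real_, index = NA_integer_,
                         grid = NULL, mask = NULL, coords = NULL,
                         flipped = FALSE, normalize = TRUE) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("gradient values must be finite")
  if (normalize) {
    rng <- range(values)
    if (diff(rng) <= 0) stop("constant gradient cannot be normalised")
    values <- (values - rng[1]) / diff(rng)
  }
  structure(list(values = values, eigenvalue = eigenvalue,
                 index = as.integer(index), grid = grid, mask = mask,
                 coords = coords, flipped = flipped),
            class = "gradient_map")
}

#' @export
print.gradient_map <- function(x, ...) {
  cat("<gradient_map> ", length(x$values), " voxels, index ", x$index,
      ", eigenvalue ", format(x$eigenvalue, digits = 4),
      if (x$flipped) ", sign-flipped" else "", "\n", sep = "")
  invisible(x)
}

#' Laplacian eigenmaps of a connectivity graph
#'
#' Solves the generalized eigenproblem `L v = lambda D v` with
#' `L = D - W` the graph Laplacian and `D` the degree diagonal (via the
#' symmetric normalized Laplacian), discards the trivial constant
#' eigenvector at `lambda = 0`, and returns the eigenvectors of the
#' `n_gradients` smallest non-zero eigenvalues, each min-max normalised.
#' The dominant gradient is the one with the smallest non-zero
#' eigenvalue. Near-degenerate eigenvalue ties are reported via
#' `message()`.
#'
#' @param W symmetric non-negative adjacency matrix of a connected graph.
#' @param n_gradients number of gradients to return.
#' @return A list of [gradient_map()] objects, dominant first.
#' @export
laplacian_eigenmaps <- function(W, n_gradients = 1) {
  W <- as.matrix(W)
  v <- nrow(W)
  if (v < 3L) stop("graph too small")
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-10)) || any(W < 0)) {
    stop("adjacency must be symmetric and non-negative")
  }
  if (n_gradients < 1 || n_gradients > v - 2L) {
    stop("`n_gradients` out of range")
  }
  d <- rowSums(W)
  if (any(d <= 0)) stop("graph has isolated vertices; not connected")
  gcheck <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  if (!igraph::is_connected(gcheck)) {
    stop("graph is disconnected; eigenmaps are only defined on a connected graph")
  }
  ds <- 1 / sqrt(d)
  Lsym <- diag(v) - (ds * W) %*% diag(ds)  # rows scaled then columns
  Lsym <- (Lsym + t(Lsym)) / 2
  e <- eigen(Lsym, symmetric = TRUE)
  vals <- rev(e$values)               # ascending
  vecs <- e$vectors[, rev(seq_len(v)), drop = FALSE]
  scale_ <- max(abs(vals))
  # The trivial generalized eigenvector is known exactly: u0 = D^{1/2} 1.
  # Identify it by overlap rather than by eigenvalue rank, and project it
  # out of the retained eigenvectors, so that graphs whose smallest
  # non-trivial eigenvalue is numerically at the zero floor (e.g. an
  # artifact clique hanging on to the rest by vanishing weights) still
  # yield a well-defined dominant gradient.
  u0 <- sqrt(d) / sqrt(sum(d))
  trivial <- which.max(abs(crossprod(vecs, u0)))
  keep <- setdiff(seq_len(v), trivial)[seq_len(n_gradients)]
  gaps <- diff(vals[setdiff(seq_len(v), trivial)][seq_len(min(n_gradients + 1L, v - 2L))])
  if (any(gaps < 1e-10 * max(scale_, 1))) {
    message("near-degenerate Laplacian eigenvalues; gradient order not unique")
  }
  lapply(seq_along(keep), function(j) {
    u <- vecs[, keep[j]]
    u <- u - sum(u * u0) * u0
    gradient_map(u * ds,              # back-transform: v = D^{-1/2} u
                 eigenvalue = vals[keep[j]], index = j)
  })
}

#' Align the sign of a gradient to a reference
#'
#' Eigenvector signs are arbitrary; a gradient is flipped
#' (`value -> 1 - value`) when its Pearson correlation with the
#' reference is negative, so that "direction" comparisons are
#' meaningful.
#'
#' @param g a [gradient_map()].
#' @param reference a [gradient_map()] or numeric vector on the same
#'   voxel set.
#' @return `g`, possibly flipped.
#' @export
align_sign <- function(g, reference) {
  ref <- if (inherits(reference, "gradient_map")) reference$values else as.numeric(reference)
  if (length(ref) != length(g$values)) stop("voxel sets differ")
  if (stats::sd(g$values) == 0 || stats::sd(ref) == 0) {
    stop("zero-variance gradient")
  }
  if (stats::cor(g$values, ref) < 0) {
    g$values <- 1 - g$values
    g$flipped <- !isTRUE(g$flipped)
  }
  g
}

#' Group-average gradient
#'
#' Voxelwise mean of sign-aligned gradients: each gradient is aligned to
#' the first, averaged, then each is re-aligned to the running mean and
#' averaged again; the result is renormalised to `[0, 1]`.
#'
#' @param gradients list of [gradient_map()] on identical voxel sets.
#' @return A [gradient_map()].
#' @export
group_gradient <- function(gradients) {
  if (length(gradients) < 1L) stop("need at least one gradient")
  nv <- length(gradients[[1]]$values)
  if (!all(vapply(gradients, function(g) length(g$values), 0L) == nv)) {
    stop("mismatched voxel sets")
  }
  aligned <- lapply(gradients, align_sign, reference = gradients[[1]])
  avg <- rowMeans(vapply(aligned, function(g) g$values, numeric(nv)))
  aligned <- lapply(gradients, align_sign, reference = avg)
  avg <- rowMeans(vapply(aligned, function(g) g$values, numeric(nv)))
  g1 <- gradients[[1]]
  gradient_map(avg, eigenvalue = NA_real_, index = 1L, grid = g1$grid,
               mask = g1$mask, coords = g1$coords)
}

#' Full connectopic-mapping pipeline for one subject
#'
#' Fingerprints -> eta-squared similarity -> kNN graph -> Laplacian
#' eigenmaps, with world coordinates attached and the sign convention
#' applied: gradients are aligned to `reference` when given, otherwise
#' oriented so that values increase with the world z-coordinate
#' (inferior to superior).
#'
#' @param roi,target [bold_data()] with matching timepoints.
#' @inheritParams compute_fingerprints
#' @inheritParams build_graph
#' @param n_gradients number of gradients to return.
#' @param dense use the dense (unsparsified) similarity graph.
#' @param reference optional reference gradient for sign alignment.
#' @return List of [gradient_map()]; `attr(, "k_used")` records the
#'   neighbourhood size actually used.
#' @export
connectopic_gradients <- function(roi, target, n_gradients = 1,
                                  k_neighbors = 8, variance_kept = 1,
                                  reference = NULL, sharpen = 20,
                                  dense = FALSE) {
  fp <- compute_fingerprints(roi, target, variance_kept = variance_kept)
  S <- similarity_matrix(fp)
  W <- build_graph(S, k_neighbors = k_neighbors, sharpen = sharpen,
                   dense = dense)
  maps <- laplacian_eigenmaps(W, n_gradients = n_gradients)
  coords <- world_coords(roi$grid, roi$mask)
  maps <- lapply(maps, function(g) {
    g$grid <- roi$grid
    g$mask <- roi$mask
    g$coords <- coords
    if (!is.null(reference)) {
      align_sign(g, reference)
    } else if (stats::sd(coords[, "z"]) > 0 &&
               stats::cor(g$values, coords[, "z"]) < 0) {
      g$values <- 1 - g$values
      g$flipped <- TRUE
      g
    } else {
      g
    }
  })
  attr(maps, "k_used") <- attr(W, "k_used")
  maps
}
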