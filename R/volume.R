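#' Voxel grid with a world-coordinate affine
#'
#' A `volume_grid` ties a 3D voxel lattice to world (MNI-like, mm)
#' coordinates through a 4x4 voxel-to-world affine. All spatial
#' modelling downstream (trend surfaces in particular) works in world
#' coordinates derived from this affine, never in raw voxel indices.
#'
#' @param shape integer vector of length 3, voxel counts per axis (all >= 1).
#' @param affine 4x4 voxel-to-world matrix (must be invertible). Voxel
#'   index `(i, j, k)` (1-based, R convention) maps to world coordinates
#'   as `affine %*% c(i - 1, j - 1, k - 1, 1)`. Defaults to an
#'   axis-aligned grid with isotropic `voxel_size` mm voxels.
#' @param voxel_size voxel edge length in mm used for the default affine.
#' @return An object of class `volume_grid` with elements `shape` and
#'   `affine`.
#' @export
volume_grid <- function(shape, affine = NULL, voxel_size = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    stop("`shape` must be 3 positive integers")
  }
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size, 3), 1))
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine))) {
    stop("`affine` must be a finite 4x4 matrix")
  }
  if (abs(det(affine)) < .Machine$double.eps * 64) {
    stop("`affine` must be invertible")
  }
  structure(list(shape = shape, affine = affine), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels, det(affine) = ", format(det(x$affine)), "\n", sep = "")
  invisible(x)
}

#' Voxel indices of a mask, in canonical order
#'
#' The voxel ordering used throughout the package (fingerprints,
#' similarity matrices, gradients, trend-surface rows) is the order in
#' which `which()` traverses an R array: the first index varies fastest
#' (column-major). It is deterministic for a given mask and is the only
#' ordering any function in this package produces or consumes.
#'
#' @param mask 3D logical (or 0/1 numeric) array.
#' @return Integer matrix with one row per `TRUE` voxel and columns
#'   `i`, `j`, `k` (1-based indices).
#' @export
mask_indices <- function(mask) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  idx <- which(mask != 0 & !is.na(mask), arr.ind = TRUE)
  colnames(idx) <- c("i", "j", "k")
  idx
}

#' World (mm) coordinates of mask voxels
#'
#' @param grid a [volume_grid()].
#' @param mask 3D logical array matching `grid$shape`.
#' @return Numeric matrix, one row per mask voxel (canonical order, see
#'   [mask_indices()]) with columns `x`, `y`, `z` in mm.
#' @export
world_coords <- function(grid, mask) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!identical(dim(mask), as.integer(grid$shape))) {
    stop("mask dimensions do not match grid shape")
  }
  idx <- mask_indices(mask)
  xyz <- cbind(idx - 1L, 1)  # affine acts on 0-based indices
  out <- xyz %*% t(grid$affine)
  out <- out[, 1:3, drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Masked 4D BOLD time series
#'
#' Stores the time series of the voxels inside a mask as a dense
#' `T x V` matrix (V = number of mask voxels, canonical voxel order).
#'
#' @param grid a [volume_grid()].
#' @param mask 3D logical array matching the grid.
#' @param series numeric `T x V` matrix, `T >= 2`, all values finite.
#' @return An object of class `bold_data`.
#' @export
bold_data <- function(grid, mask, series) {
  stopifnot(inherits(grid, "volume_grid"))
  mask <- array(mask != 0, dim = dim(mask))
  if (!identical(dim(mask), as.integer(grid$shape))) {
    stop("mask dimensions do not match grid shape")
  }
  series <- as.matrix(series)
  v <- sum(mask)
  if (v < 2L) stop("mask must contain at least 2 voxels")
  if (nrow(series) < 2L) stop("need at least 2 timepoints")
  if (ncol(series) != v) {
    stop("series has ", ncol(series), " columns but mask has ", v, " voxels")
  }
  if (!all(is.finite(series))) stop("series contains non-finite values")
  structure(list(grid = grid, mask = mask, series = series),
            class = "bold_data")
}

#' @export
print.bold_data <- function(x, ...) {
  cat("<bold_data> T = ", nrow(x$series), " timepoints, V = ",
      ncol(x$series), " voxels\n", sep = "")
  invisible(x)
}

#' @rdname bold_data
#' @param x object to test.
#' @export
is_bold_data <- function(x) inherits(x, "bold_data")

n_timepoints <- function(x) nrow(x$series)
n_voxels <- function(x) ncol(x$series)
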