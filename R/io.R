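#' Read a NIfTI volume as a mask or BOLD data
#'
#' 3D files are interpreted as masks (non-zero voxels are `TRUE`); 4D
#' files yield [bold_data()] over the non-zero voxels (or an explicit
#' mask). The affine stored in the file header defines the
#' [volume_grid()].
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param mask optional 3D logical array selecting the voxels to keep
#'   from a 4D file; by default every voxel whose series is not
#'   identically zero is kept.
#' @return For 3D input, a list with elements `grid` and `mask`; for 4D
#'   input, a [bold_data()].
#' @export
read_volume <- function(path, mask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  nd <- length(dim(arr))
  if (nd == 3L) {
    grid <- volume_grid(dim(arr), affine = aff)
    m <- array(arr != 0 & !is.na(arr), dim = dim(arr))
    if (!any(m)) stop("empty mask: ", path)
    return(list(grid = grid, mask = m))
  }
  if (nd != 4L) stop("expected a 3D or 4D NIfTI file, got ", nd, "D")
  if (dim(arr)[4] < 2L) stop("4D file with fewer than 2 timepoints")
  grid <- volume_grid(dim(arr)[1:3], affine = aff)
  if (is.null(mask)) {
    mask <- apply(arr != 0, c(1, 2, 3), any)
  }
  flat <- matrix(arr, prod(dim(arr)[1:3]), dim(arr)[4])
  series <- t(flat[which(mask), , drop = FALSE])
  bold_data(grid, mask, series)
}

#' Write a mask, 3D volume, or BOLD data as NIfTI
#'
#' @param x a [bold_data()], a 3D array, or a `gradient_map` with grid
#'   and mask attached (written as a 3D float volume with `NaN` outside
#'   the ROI).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param grid a [volume_grid()]; required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "bold_data")) {
    dims <- c(x$grid$shape, nrow(x$series))
    arr <- array(0, dim = dims)
    flat <- matrix(arr, prod(dims[1:3]), dims[4])
    flat[which(x$mask), ] <- t(x$series)
    arr <- array(flat, dim = dims)
    img <- RNifti::asNifti(arr)
    RNifti::sform(img) <- structure(x$grid$affine, code = 2L)
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (inherits(x, "gradient_map")) {
    if (is.null(x$grid) || is.null(x$mask)) {
      stop("gradient_map lacks grid/mask; cannot write a volume")
    }
    arr <- array(NaN, dim = x$grid$shape)
    arr[which(x$mask)] <- x$values
    img <- RNifti::asNifti(arr)
    RNifti::sform(img) <- structure(x$grid$affine, code = 2L)
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  arr <- as.array(x)
  if (length(dim(arr)) != 3L) stop("expected bold_data, gradient_map, or 3D array")
  if (is.null(grid)) stop("`grid` is required when writing a bare array")
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Concatenate runs after per-run voxelwise standardisation
#'
#' Each voxel's series in each run is mean-centred and scaled to unit
#' standard deviation before runs are stacked along time, so that no
#' single run dominates the concatenated series. Voxels with zero
#' variance in a run (e.g. masked air) have that run's block set to all
#' zeros, with a warning.
#'
#' @param runs a list of [bold_data()] sharing an identical grid and mask.
#' @return A [bold_data()] with `T = sum(T_runs)`.
#' @export
concat_runs <- function(runs) {
  if (inherits(runs, "bold_data")) runs <- list(runs)
  if (length(runs) < 1L) stop("need at least one run")
  stopifnot(all(vapply(runs, is_bold_data, logical(1))))
  ref <- runs[[1]]
  for (r in runs[-1]) {
    if (!isTRUE(all.equal(ref$grid$affine, r$grid$affine)) ||
        !identical(ref$grid$shape, r$grid$shape) ||
        !identical(which(ref$mask), which(r$mask))) {
      stop("all runs must share the same grid and mask")
    }
  }
  blocks <- lapply(seq_along(runs), function(ri) {
    s <- runs[[ri]]$series
    mu <- colMeans(s)
    sdv <- apply(s, 2, stats::sd)
    dead <- sdv <= 0
    if (any(dead)) {
      warning(sum(dead), " zero-variance voxel(s) in run ", ri,
              " set to zeros", call. = FALSE)
      sdv[dead] <- 1
    }
    out <- sweep(sweep(s, 2, mu, "-"), 2, sdv, "/")
    out[, dead] <- 0
    out
  })
  bold_data(ref$grid, ref$mask, do.call(rbind, blocks))
}

#' Read / write cohort tables
#'
#' Cohort tables are TSV files with a header row; missing values are
#' encoded as empty fields and handled listwise by each analysis.
#'
#' @param path file path.
#' @return [read_cohort()] returns a tibble.
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, na = c("", "NA"), show_col_types = FALSE,
                  progress = FALSE)
}

#' @rdname read_cohort
#' @param x a data frame of per-subject rows.
#' @export
write_cohort <- function(x, path) {
  readr::write_tsv(x, path, na = "")
  invisible(path)
}
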