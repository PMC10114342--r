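#' Gradient-direction quality check
#'
#' A subject's dominant gradient is kept only if it preserves the main
#' direction of the reference (group-average) gradient, operationalised
#' as `|Pearson r| >= r_min`; the absolute value makes the check
#' insensitive to the arbitrary eigenvector sign, which [align_sign()]
#' handles separately.
#'
#' @param g a [gradient_map()] or numeric vector.
#' @param reference reference gradient on the same voxel set.
#' @param r_min correlation threshold in `(0, 1)`.
#' @return Logical flag.
#' @export
check_direction <- function(g, reference, r_min = 0.5) {
  gv <- if (inherits(g, "gradient_map")) g$values else as.numeric(g)
  rv <- if (inherits(reference, "gradient_map")) reference$values else as.numeric(reference)
  if (length(gv) != length(rv)) stop("voxel sets differ")
  if (r_min <= 0 || r_min >= 1) stop("`r_min` must be in (0, 1)")
  if (stats::sd(gv) == 0 || stats::sd(rv) == 0) stop("zero-variance gradient")
  abs(stats::cor(gv, rv)) >= r_min
}

#' Explained-variance quality check
#'
#' A subject is kept only when the trend-surface model describes at
#' least `threshold` of the total variance in the spatial layout of
#' the dominant gradient (inclusive bound: exactly `threshold` passes).
#' Gradients failing this are typically artifactual — driven by a few
#' outlier voxels rather than a smooth spatial pattern.
#'
#' @param model a [fit_tsm()] model (or a number, taken as
#'   `var_explained` directly).
#' @param threshold minimum explained-variance fraction.
#' @return Logical flag.
#' @export
check_variance <- function(model, threshold = 0.70) {
  ve <- if (inherits(model, "tsm_model")) model$var_explained else as.numeric(model)
  if (is.na(ve)) stop("model has no explained variance")
  ve >= threshold
}

#' Per-subject QC flags
#'
#' @param direction_ok,variance_ok logical vectors from
#'   [check_direction()] / [check_variance()].
#' @return Tibble with `direction_ok`, `variance_ok` and
#'   `included = direction_ok & variance_ok`.
#' @export
qc_flags <- function(direction_ok, variance_ok) {
  stopifnot(length(direction_ok) == length(variance_ok))
  tibble::tibble(direction_ok = as.logical(direction_ok),
                 variance_ok = as.logical(variance_ok),
                 included = as.logical(direction_ok) & as.logical(variance_ok))
}

#' Compare excluded and included subjects
#'
#' Descriptive comparability check of the QC-excluded subjects against
#' the analysed sample: continuous variables by two-sample Student's
#' t-test (equal variances; Welch by flag), binary variables by
#' Fisher's exact test. P-values are reported uncorrected.
#'
#' @param cohort data frame of per-subject rows.
#' @param included logical vector, `TRUE` for analysed subjects.
#' @param continuous,binary character vectors of column names.
#' @param welch use Welch's t-test instead of Student's.
#' @return Tibble with `variable`, `test`, `statistic`, `p`,
#'   `n_included`, `n_excluded`. Variables whose groups are too small
#'   are skipped with a warning.
#' @export
compare_excluded <- function(cohort, included,
                             continuous = character(), binary = character(),
                             welch = FALSE) {
  stopifnot(nrow(cohort) == length(included))
  included <- as.logical(included)
  rows <- list()
  for (v in continuous) {
    x <- cohort[[v]][included]
    y <- cohort[[v]][!included]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L) {
      warning("skipping '", v, "': fewer than 2 subjects in a group",
              call. = FALSE)
      next
    }
    tt <- stats::t.test(x, y, var.equal = !welch)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, test = if (welch) "welch_t" else "student_t",
      statistic = unname(tt$statistic), p = tt$p.value,
      n_included = length(x), n_excluded = length(y))
  }
  for (v in binary) {
    f <- factor(cohort[[v]])
    ok <- !is.na(f)
    if (sum(included & ok) < 2L || sum(!included & ok) < 2L ||
        nlevels(droplevels(f[ok])) < 2L) {
      warning("skipping '", v, "': group too small or constant",
              call. = FALSE)
      next
    }
    tab <- table(included[ok], f[ok])
    ft <- stats::fisher.test(tab)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, test = "fisher", statistic = NA_real_, p = ft$p.value,
      n_included = sum(included & ok), n_excluded = sum(!included & ok))
  }
  if (!length(rows)) {
    return(tibble::tibble(variable = character(), test = character(),
                          statistic = numeric(), p = numeric(),
                          n_included = integer(), n_excluded = integer()))
  }
  do.call(rbind, rows)
}
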