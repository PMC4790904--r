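#' Canonical double-gamma hemodynamic response function
#'
#' The standard difference-of-gammas shape (response peaking near 6 s, an
#' undershoot near 16 s with 1/6 amplitude), sampled at `t` seconds.
#'
#' @param t numeric vector of times in seconds.
#' @return HRF values, scaled to unit peak.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

#' General design matrix for per-voxel regression
#'
#' @param X a T x k numeric matrix of regressors (full column rank).
#' @param contrast a length-k contrast vector (not all zero).
#' @return An object of class `design_matrix`.
#' @export
design_matrix <- function(X, contrast) {
  X <- as.matrix(X)
  contrast <- as.numeric(contrast)
  if (length(contrast) != ncol(X)) stop("contrast length must equal ncol(X)")
  if (all(contrast == 0)) stop("contrast must not be all zero")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  structure(list(X = X, contrast = contrast), class = "design_matrix")
}

#' Blocked-design task regressor and design matrix
#'
#' Builds the two-column design (task boxcar + intercept) for an alternating
#' blocked paradigm that starts with a control block, e.g. four 30-s control
#' blocks alternating with four task blocks at TR = 2 s gives
#' `n_timepoints = 120`, `block_length = 15`.
#'
#' @param n_timepoints number of volumes; must be divisible by
#'   `2 * block_length`.
#' @param block_length volumes per block.
#' @param tr repetition time in seconds (only used when `hrf = TRUE`).
#' @param hrf convolve the boxcar with [canonical_hrf()]. Off by default:
#'   with 30-s blocks the convolved regressor is nearly the boxcar.
#' @return A `design_matrix` whose contrast picks out the task regressor.
#' @export
block_design <- function(n_timepoints, block_length, tr = 2, hrf = FALSE) {
  n_timepoints <- as.integer(n_timepoints)
  block_length <- as.integer(block_length)
  if (block_length < 1L) stop("'block_length' must be >= 1")
  if (n_timepoints %% (2L * block_length) != 0L)
    stop("'n_timepoints' must be divisible by 2 * block_length")
  boxcar <- rep(rep(c(0, 1), each = block_length),
                times = n_timepoints %/% (2L * block_length))
  reg <- boxcar
  if (hrf) {
    h <- canonical_hrf(seq(0, 32, by = tr))
    reg <- stats::convolve(boxcar, rev(h), type = "open")[seq_len(n_timepoints)]
    reg <- reg / max(reg)
  }
  d <- design_matrix(cbind(task = reg, intercept = 1), contrast = c(1, 0))
  d$boxcar <- boxcar
  d
}

#' Construct a first-level result directly from maps
#'
#' Mostly used to wrap externally computed (or hand-built) beta and t maps;
#' [fit_glm()] is the usual producer.
#'
#' @param grid a [volume_grid()].
#' @param beta,tmap per-voxel contrast coefficient and t statistic (vector or
#'   array, one value per voxel).
#' @param df residual degrees of freedom (> 0).
#' @param series optional T x V matrix of per-voxel timecourses (V in linear
#'   voxel order), needed by the eigenimage-weighted and peak-correlation
#'   measures.
#' @return An object of class `first_level`.
#' @export
first_level <- function(grid, beta, tmap, df, series = NULL) {
  if (length(beta) != n_voxels(grid) || length(tmap) != n_voxels(grid))
    stop("beta and tmap must have one value per voxel")
  df <- as.integer(df)
  if (df <= 0L) stop("df must be positive")
  if (!is.null(series)) {
    series <- as.matrix(series)
    if (ncol(series) != n_voxels(grid))
      stop("series must have one column per voxel")
  }
  structure(list(grid = grid,
                 beta = array(as.numeric(beta), dim = grid$shape),
                 tmap = array(as.numeric(tmap), dim = grid$shape),
                 df = df, series = series),
            class = "first_level")
}

#' @export
print.first_level <- function(x, ...) {
  cat(sprintf("first_level on %d x %d x %d grid, df = %d, series %s\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3], x$df,
              if (is.null(x$series)) "absent" else
                sprintf("%d timepoints", nrow(x$series))))
  invisible(x)
}

#' Per-voxel ordinary least squares fit of a task contrast
#'
#' Fits `y = X b + e` independently at every voxel and forms the contrast
#' coefficient `beta = c' (X'X)^-1 X' y` with its t statistic
#' `t = beta / sqrt(sigma2 * c' (X'X)^-1 c)` on `T - k` degrees of freedom.
#' Voxels with (numerically) zero residual variance get `t = +Inf`, a
#' sentinel that survives any p threshold; it only arises on noise-free
#' synthetic data.
#'
#' @param series T x V numeric matrix of timecourses, one column per voxel in
#'   linear voxel order.
#' @param design a [design_matrix()] or [block_design()].
#' @param grid the [volume_grid()] the voxels live on.
#' @param keep_series retain the series in the result (needed by measures
#'   that use timecourses).
#' @return A [first_level()] object.
#' @export
fit_glm <- function(series, design, grid, keep_series = TRUE) {
  series <- as.matrix(series)
  X <- design$X
  cvec <- design$contrast
  k <- ncol(X)
  T <- nrow(X)
  if (nrow(series) != T) stop("series and design disagree on T")
  if (ncol(series) != n_voxels(grid)) stop("series must have one column per voxel")
  if (T < k + 2L) stop("need at least k + 2 timepoints")
  if (qr(X)$rank < k) stop("design matrix is rank deficient")
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, series)          # k x V
  cb <- drop(crossprod(cvec, B))
  rss <- colSums((series - X %*% B)^2)
  df <- T - k
  cvc <- drop(crossprod(cvec, XtXinv %*% cvec))
  sigma2 <- rss / df
  tstat <- cb / sqrt(sigma2 * cvc)
  zero <- rss <= T * .Machine$double.eps^1.5 * pmax(colSums(series^2), 1)
  tstat[zero] <- Inf
  first_level(grid, cb, tstat, df, series = if (keep_series) series else NULL)
}

#' Threshold a t map at a per-voxel p value within an ROI
#'
#' Keeps the ROI voxels whose t statistic exceeds the one-sided upper-tail
#' Student-t critical value at the fit's degrees of freedom. Activation is
#' taken as positive contrast, so the threshold is one-sided; `p = 1` keeps
#' the whole ROI. The result may be empty, which downstream measures treat
#' as a missing value.
#'
#' @param flm a [first_level()] object.
#' @param roi an [roi_mask()] on the same grid.
#' @param p per-voxel uncorrected p threshold in (0, 1]; default 0.05.
#' @return An [roi_mask()] (possibly empty).
#' @export
activation_mask <- function(flm, roi, p = 0.05) {
  if (!same_grid(flm$grid, roi$grid)) stop("grid mismatch between map and ROI")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("'p' must be a single value in (0, 1]")
  crit <- stats::qt(1 - p, df = flm$df)
  roi_mask(flm$grid, roi$mask & (flm$tmap > crit), allow_empty = TRUE)
}
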