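#' Spherical ROI around a point
#'
#' Selects the voxels whose centers lie within `radius_mm` (Euclidean, mm) of
#' `center_mm`. Membership is by voxel-center distance, without
#' partial-volume weighting.
#'
#' @param grid a [volume_grid()].
#' @param center_mm sphere center, mm; must lie inside the grid.
#' @param radius_mm sphere radius, mm (>= 0). Radius 0 selects exactly the
#'   voxel containing the center.
#' @return An [roi_mask()].
#' @export
sphere_roi <- function(grid, center_mm, radius_mm) {
  if (radius_mm < 0) stop("'radius_mm' must be >= 0")
  if (!mm_in_bounds(grid, center_mm)) stop("sphere center lies outside the grid")
  ax <- lapply(1:3, function(a)
    (grid$origin_mm[a] + (seq_len(grid$shape[a]) - 1) * grid$voxel_size[a] -
       center_mm[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  mask <- d2 <= radius_mm^2
  if (!any(mask)) {
    ctr <- mm_to_voxel(grid, center_mm, clip = TRUE)
    mask[ijk_to_index(grid, ctr)] <- TRUE
  }
  roi_mask(grid, mask)
}

#' Task-activated ROI from group activation maps
#'
#' For each group, a one-sample t test across the subjects' beta maps is run
#' at every voxel of the anatomical mask; voxels surviving a familywise-error
#' threshold (Bonferroni over the anatomical voxel count, one-sided positive)
#' are that group's task-activated voxels. The joint map combines the
#' per-group suprathreshold masks.
#'
#' @param group_flms list of groups, each a list of [first_level()] objects
#'   (>= 3 subjects per group).
#' @param anatomical an [roi_mask()] defining the search region.
#' @param alpha familywise error level; `alpha = 1` keeps the whole
#'   anatomical mask.
#' @param combine `"union"` (default) keeps voxels activated in any group;
#'   `"intersection"` keeps voxels activated in all groups.
#' @return An [roi_mask()]; an empty joint map is an error, since every
#'   summary measure needs at least one voxel.
#' @export
task_activated_roi <- function(group_flms, anatomical, alpha = 0.05,
                               combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  if (!length(group_flms)) stop("need at least one group")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  idx <- roi_indices(anatomical)
  m <- length(idx)
  joint <- NULL
  for (flms in group_flms) {
    n <- length(flms)
    if (n < 3L) stop("each group needs at least 3 subjects")
    for (f in flms)
      if (!same_grid(f$grid, anatomical$grid))
        stop("grid mismatch between maps and anatomical mask")
    betas <- vapply(flms, function(f) f$beta[idx], numeric(m))  # m x n
    if (m == 1L) betas <- matrix(betas, nrow = 1L)
    mu <- rowMeans(betas)
    sd <- sqrt(rowSums((betas - mu)^2) / (n - 1))
    t <- mu / (sd / sqrt(n))
    crit <- stats::qt(1 - alpha / m, df = n - 1)
    supra <- !is.na(t) & t > crit
    joint <- if (is.null(joint)) supra
    else if (combine == "union") joint | supra
    else joint & supra
  }
  mask <- array(FALSE, anatomical$grid$shape)
  mask[idx[joint]] <- TRUE
  if (!any(mask))
    stop(errorCondition("task-activated joint map is empty",
                        class = c("roisum_empty_roi", "error", "condition")))
  roi_mask(anatomical$grid, mask)
}

#' Read and write ROI masks as NIfTI
#'
#' Masks are stored as 0/1 volumes with the grid affine in the header;
#' `read_mask()` reconstructs the [volume_grid()] from the header. A save /
#' load round trip preserves the grid and the voxel set. An all-zero file
#' loads as an empty mask (with the empty flag set).
#'
#' @param mask an [roi_mask()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param grid optional [volume_grid()] to check the file against; a
#'   mismatch is an error.
#' @return `read_mask()` returns an [roi_mask()]; `write_mask()` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  write_nifti_array(array(as.integer(mask$mask), mask$grid$shape),
                    mask$grid, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, grid = NULL) {
  x <- read_nifti_array(path)
  if (!is.null(grid) && !same_grid(x$grid, grid))
    stop("mask grid does not match the expected grid")
  roi_mask(x$grid, x$values != 0, allow_empty = TRUE)
}
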