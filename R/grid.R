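#' Define a common voxel grid
#'
#' Every map and mask in roisum lives on a `volume_grid`: a rectangular voxel
#' lattice with a voxel size (mm per axis) and the mm coordinates of the
#' center of voxel (1,1,1). The mapping between 1-based voxel indices and mm
#' coordinates is affine and invertible.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size mm per axis; a scalar is recycled. Default 3 mm
#'   isotropic, the common-space resolution typical of group fMRI studies.
#' @param origin_mm mm coordinates of the center of voxel (1,1,1).
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(c(10, 10, 10))
#' voxel_to_mm(g, c(1, 1, 1))
#' @export
volume_grid <- function(shape, voxel_size = c(3, 3, 3), origin_mm = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive numbers (mm)")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("'origin_mm' must be 3 finite numbers (mm)")
  structure(list(shape = shape, voxel_size = voxel_size, origin_mm = origin_mm),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid a [volume_grid()].
#' @return Integer voxel count.
#' @export
n_voxels <- function(grid) prod(grid$shape)

#' Test two grids for equality
#' @param a,b [volume_grid()] objects (or objects carrying a `$grid`).
#' @param tol numeric tolerance on voxel size and origin.
#' @return Logical.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  if (!inherits(a, "volume_grid")) a <- a$grid
  if (!inherits(b, "volume_grid")) b <- b$grid
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

## linear index (1-based, column-major) <-> (i, j, k) triplets
index_to_ijk <- function(grid, idx) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% nx
  j <- (idx0 %/% nx) %% ny
  k <- idx0 %/% (nx * ny)
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

ijk_to_index <- function(grid, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  nx <- grid$shape[1]; ny <- grid$shape[2]
  ijk[, 1] + (ijk[, 2] - 1L) * nx + (ijk[, 3] - 1L) * nx * ny
}

## lexicographic (i, then j, then k) rank of voxels, used for tie-breaking
lex_rank <- function(grid, idx) {
  ijk <- index_to_ijk(grid, idx)
  ny <- grid$shape[2]; nz <- grid$shape[3]
  ((ijk[, 1] - 1) * ny + (ijk[, 2] - 1)) * nz + ijk[, 3]
}

#' Convert voxel indices to mm coordinates
#'
#' @param grid a [volume_grid()].
#' @param ijk a length-3 vector or an n x 3 matrix of 1-based voxel indices.
#' @return An n x 3 matrix of mm coordinates of the voxel centers.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(sweep(ijk - 1, 2, grid$voxel_size, `*`), 2, grid$origin_mm, `+`)
}

#' Convert mm coordinates to the nearest voxel index
#'
#' @param grid a [volume_grid()].
#' @param mm a length-3 vector or an n x 3 matrix of mm coordinates.
#' @param clip clamp out-of-grid coordinates to the nearest edge voxel
#'   (default) rather than returning an out-of-range index.
#' @return An n x 3 integer matrix of voxel indices.
#' @export
mm_to_voxel <- function(grid, mm, clip = TRUE) {
  mm <- matrix(as.numeric(mm), ncol = 3L)
  ijk <- round(sweep(sweep(mm, 2, grid$origin_mm, `-`), 2, grid$voxel_size, `/`)) + 1
  if (clip)
    ijk <- pmin(pmax(ijk, 1), matrix(grid$shape, nrow(ijk), 3L, byrow = TRUE))
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  colnames(ijk) <- c("i", "j", "k")
  ijk
}

## is an mm coordinate inside the grid's bounding box (voxel edges included)?
mm_in_bounds <- function(grid, mm) {
  mm <- as.numeric(mm)
  lo <- grid$origin_mm - grid$voxel_size / 2
  hi <- grid$origin_mm + (grid$shape - 1) * grid$voxel_size + grid$voxel_size / 2
  all(mm >= lo & mm <= hi)
}

#' A per-voxel scalar map on a grid
#'
#' @param grid a [volume_grid()].
#' @param values numeric vector or array with one value per voxel; `NA`
#'   encodes missing voxels.
#' @return An object of class `scalar_map` with fields `grid` and `values`
#'   (a 3-D array).
#' @export
scalar_map <- function(grid, values) {
  if (length(values) != n_voxels(grid))
    stop("'values' must have one entry per voxel")
  values <- array(as.numeric(values), dim = grid$shape)
  structure(list(grid = grid, values = values), class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("scalar_map on %d x %d x %d grid: range [%.4g, %.4g], %d missing\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

#' A binary region-of-interest mask on a grid
#'
#' @param grid a [volume_grid()].
#' @param mask logical vector or array with one entry per voxel.
#' @param allow_empty permit a mask with no `TRUE` voxel; such masks carry
#'   `empty = TRUE` and are only valid where a downstream rule maps them to a
#'   missing value.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(grid, mask, allow_empty = FALSE) {
  if (length(mask) != n_voxels(grid))
    stop("'mask' must have one entry per voxel")
  mask <- array(as.logical(mask), dim = grid$shape)
  if (any(is.na(mask))) stop("'mask' must not contain NA")
  empty <- !any(mask)
  if (empty && !allow_empty)
    stop("ROI mask has no voxels; pass allow_empty = TRUE if intentional")
  structure(list(grid = grid, mask = mask, empty = empty), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask on %d x %d x %d grid: %d voxels%s\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              sum(x$mask), if (x$empty) " (empty)" else ""))
  invisible(x)
}

#' Linear indices of the voxels in an ROI
#' @param roi an [roi_mask()].
#' @return Integer vector of 1-based linear voxel indices.
#' @export
roi_indices <- function(roi) which(roi$mask)
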