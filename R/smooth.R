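## Separable 3-D Gaussian smoothing on a voxel array. Kernels are truncated
## at 3 sigma and renormalized at the edges so a constant image stays
## constant.

gaussian_kernel_1d <- function(fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  n <- nrow(m)
  r <- (length(kernel) - 1L) / 2L
  acc <- matrix(0, nrow(m), ncol(m))
  wt <- numeric(n)
  for (s in seq_along(kernel)) {
    off <- s - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    acc[ok, ] <- acc[ok, ] + kernel[s] * m[src[ok], , drop = FALSE]
    wt[ok] <- wt[ok] + kernel[s]
  }
  acc <- acc / wt
  aperm(array(acc, d[perm]), order(perm))
}

#' Gaussian-smooth a 3-D volume
#'
#' Separable Gaussian filter with edge renormalization, applied along each
#' axis in turn.
#'
#' @param arr a 3-D numeric array.
#' @param fwhm_mm full width at half maximum of the kernel, mm. 0 returns the
#'   input unchanged.
#' @param voxel_size_mm voxel size per axis, mm.
#' @return The smoothed array.
#' @export
gaussian_smooth <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(arr)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  for (axis in 1:3)
    arr <- smooth_axis(arr, gaussian_kernel_1d(fwhm_mm, voxel_size_mm[axis]), axis)
  arr
}
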