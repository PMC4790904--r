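# Fixture builders used across test files. All data are generated in code.

# random subject maps with a correlated timecourse structure so the
# peak-correlation measure has something to find
rand_flm <- function(grid, T = 30, df = 50, series = TRUE) {
  V <- prod(grid$shape)
  flm_series <- NULL
  if (series) {
    s1 <- rnorm(T)
    s2 <- rnorm(T)
    in1 <- runif(V) < 0.4
    in2 <- runif(V) < 0.4
    flm_series <- outer(s1, ifelse(in1, runif(V, 0.5, 1.5), 0)) +
      outer(s2, ifelse(in2, runif(V, 0.5, 1.5), 0)) +
      matrix(rnorm(T * V, sd = 0.5), T, V)
  }
  first_level(grid, beta = rnorm(V), tmap = rnorm(V), df = df,
              series = flm_series)
}

# a random ROI of about n_vox voxels (possibly disconnected)
rand_roi <- function(grid, n_vox) {
  V <- prod(grid$shape)
  idx <- sample.int(V, min(n_vox, V))
  m <- logical(V)
  m[idx] <- TRUE
  roi_mask(grid, m)
}

# a filled box ROI (always 26-connected)
box_roi <- function(grid, lo, hi) {
  m <- array(FALSE, grid$shape)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  roi_mask(grid, m)
}

# build a first_level directly from a beta/t specification on a tiny grid
flm_from_maps <- function(grid, beta, tmap, df = 50, series = NULL) {
  first_level(grid, beta, tmap, df, series = series)
}
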