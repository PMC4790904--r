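small_cfg <- function(...) {
  args <- list(
    grid = volume_grid(c(8, 8, 8)),
    groups = data.frame(label = c("a", "b"), n = c(3, 3),
                        amplitude_mean = c(1, 1), amplitude_sd = c(0.3, 0.3),
                        stringsAsFactors = FALSE),
    n_timepoints = 24, block_length = 3, blob_fwhm_mm = 9,
    peak_jitter_sd_mm = 3, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

test_that("simulation is bitwise reproducible under a fixed seed", {
  s1 <- simulate_cohort(small_cfg())
  s2 <- simulate_cohort(small_cfg())
  expect_identical(s1$series, s2$series)
  expect_identical(s1$truth, s2$truth)
})

test_that("without jitter and with tiny noise every subject peaks at the nominal center", {
  # a compact blob (FWHM 6 mm) keeps the center-vs-neighbor t ratio far from
  # the residual-variance fluctuations that order an almost-noise-free t map
  cfg <- small_cfg(peak_jitter_sd_mm = 0, noise_sd = 1e-6, blob_fwhm_mm = 6)
  sim <- simulate_first_levels(cfg)
  center <- drop(mm_to_voxel(cfg$grid, cfg$nominal_center_mm))
  roi <- roi_mask(cfg$grid, array(TRUE, cfg$grid$shape))
  for (f in sim$flms) {
    pk <- attr(find_peak(f, roi), "ijk")
    expect_equal(unname(pk), unname(center))
  }
})

test_that("with no noise or smoothing the beta map equals amplitude * blob", {
  cfg <- small_cfg(peak_jitter_sd_mm = 0, noise_sd = 1e-9)
  sim <- simulate_first_levels(cfg)
  for (i in seq_along(sim$flms)) {
    tr <- sim$truth[i, ]
    blob <- roisum:::gaussian_blob(
      cfg$grid, drop(voxel_to_mm(cfg$grid, c(tr$peak_i, tr$peak_j, tr$peak_k))),
      cfg$blob_fwhm_mm)
    expect_equal(as.vector(sim$flms[[i]]$beta), tr$amplitude * blob,
                 tolerance = 1e-6)
  }
})

test_that("empirical TSNR at blob-free voxels approaches baseline / noise_sd", {
  cfg <- small_cfg(peak_jitter_sd_mm = 0, noise_sd = 2, baseline = 100,
                   n_timepoints = 120, block_length = 15)
  sim <- simulate_cohort(cfg)
  tsnr <- compute_tsnr(sim$series[[1]], cfg$grid)
  blob <- roisum:::gaussian_blob(cfg$grid, cfg$nominal_center_mm, cfg$blob_fwhm_mm)
  far <- blob < 1e-4
  expect_equal(mean(tsnr$values[far]), 100 / 2, tolerance = 0.08)
})

test_that("TSNR follows the mean-over-sample-SD definition", {
  x <- c(90, 100, 110)          # mean 100, sample SD 10
  expect_equal(compute_tsnr(x), 10)
  expect_true(is.na(compute_tsnr(rep(5, 10))))   # constant -> missing
  expect_error(compute_tsnr(3), "2 timepoints")
  set.seed(1)
  y <- rnorm(200, mean = 50, sd = 5)
  expect_equal(compute_tsnr(y), mean(y) / sd(y))
  expect_equal(compute_tsnr(y), 10, tolerance = 0.15)
})

test_that("jitter beyond the grid is clipped, never fatal", {
  cfg <- small_cfg(peak_jitter_sd_mm = 200)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$peak_i >= 1 & sim$truth$peak_i <= 8))
  expect_true(all(sim$truth$peak_k >= 1 & sim$truth$peak_k <= 8))
})

test_that("invalid configurations are rejected", {
  expect_error(small_cfg(noise_sd = 0), "noise_sd")
  expect_error(small_cfg(n_timepoints = 25), "divisible")
  expect_error(simulation_config(groups = data.frame(
    label = "a", n = 1, amplitude_mean = 1, amplitude_sd = 1)), "n >= 2")
})

test_that("null amplitude difference gives near-zero mean Cohen's d of measures", {
  # null by construction: identical amplitude distributions
  set.seed(99)
  ds <- replicate(60, {
    seed <- sample.int(1e6, 1)
    cfg <- small_cfg(seed = seed)
    sim <- simulate_first_levels(cfg)
    roi <- sphere_roi(cfg$grid, drop(voxel_to_mm(cfg$grid, c(4, 4, 4))), 7)
    tab <- extract_all(sim$flms, roi, list(measure_spec(1)), meta = sim$truth)
    g <- split(tab$m01A, tab$group)
    cohens_d(g[[1]], g[[2]])
  })
  expect_lt(abs(mean(ds)), 0.25)   # MC error at n=3/group, 60 reps
})
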