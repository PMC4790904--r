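## Synthetic blocked-design BOLD cohorts with known ground truth: a focal
## Gaussian activation blob whose per-subject peak jitters around a nominal
## center, a between-group difference in activation amplitude, and white
## temporal noise calibrated through baseline / noise_sd (the temporal SNR
## of blob-free voxels).

## evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Per-group covariate model for simulated cohorts
#'
#' Covariates are drawn i.i.d. per group: Gaussian age (years), WRAT score
#' and task accuracy (% correct, capped at 100), Bernoulli sex (coded 0/1).
#' Group differences in covariates are introduced by giving per-group vectors
#' for the means; the defaults describe matched groups.
#'
#' @param labels group labels (one row per group is produced).
#' @param age_mean,age_sd,wrat_mean,wrat_sd,accuracy_mean,accuracy_sd,sex_prop
#'   scalars or one value per group.
#' @return A data frame with one row per group.
#' @export
covariate_model <- function(labels, age_mean = 33, age_sd = 10,
                            wrat_mean = 105, wrat_sd = 10,
                            accuracy_mean = 85, accuracy_sd = 8,
                            sex_prop = 0.5) {
  data.frame(label = labels,
             age_mean = rep_len(age_mean, length(labels)),
             age_sd = rep_len(age_sd, length(labels)),
             wrat_mean = rep_len(wrat_mean, length(labels)),
             wrat_sd = rep_len(wrat_sd, length(labels)),
             accuracy_mean = rep_len(accuracy_mean, length(labels)),
             accuracy_sd = rep_len(accuracy_sd, length(labels)),
             sex_prop = rep_len(sex_prop, length(labels)),
             stringsAsFactors = FALSE)
}

#' Configuration of a synthetic fMRI cohort
#'
#' The defaults emulate a blocked working-memory paradigm on a 3-mm common
#' grid: 120 volumes of four 30-s control blocks alternating with four 30-s
#' task blocks at TR = 2 s, a 12-mm FWHM activation blob whose per-subject
#' peak jitters around the nominal center with 6-mm SD, two groups of 50
#' subjects whose activation amplitudes differ by half a pooled SD, and
#' white noise giving a baseline temporal SNR of 100.
#'
#' @param grid a [volume_grid()].
#' @param groups data frame with columns `label`, `n` (>= 2),
#'   `amplitude_mean`, `amplitude_sd` (arbitrary units).
#' @param nominal_center_mm nominal activation center (mm); default the grid
#'   center voxel.
#' @param peak_jitter_sd_mm per-axis SD of the Gaussian peak-location jitter,
#'   mm (>= 0). Jittered centers are rounded to the nearest voxel and clipped
#'   inside the grid.
#' @param blob_fwhm_mm FWHM of the Gaussian activation profile, mm (> 0).
#' @param n_timepoints,block_length,tr blocked design parameters, see
#'   [block_design()].
#' @param noise_sd SD of the white temporal noise (a.u., > 0).
#' @param baseline baseline signal level (a.u.); baseline / noise_sd is the
#'   temporal SNR at blob-free voxels.
#' @param smoothing_fwhm_mm optional spatial Gaussian smoothing applied to
#'   every simulated volume; 0 (default) disables it.
#' @param hrf convolve the task regressor with the canonical HRF when
#'   generating signal (and in the returned design).
#' @param covariates a [covariate_model()] data frame, one row per group.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(grid = volume_grid(c(20, 20, 20)),
                              groups = data.frame(
                                label = c("control", "patient"),
                                n = c(50, 50),
                                amplitude_mean = c(1, 1.25),
                                amplitude_sd = c(0.5, 0.5),
                                stringsAsFactors = FALSE),
                              nominal_center_mm = NULL,
                              peak_jitter_sd_mm = 6,
                              blob_fwhm_mm = 12,
                              n_timepoints = 120, block_length = 15, tr = 2,
                              noise_sd = 1, baseline = 100,
                              smoothing_fwhm_mm = 0,
                              hrf = FALSE,
                              covariates = covariate_model(groups$label),
                              seed = 1L) {
  stopifnot(inherits(grid, "volume_grid"))
  req <- c("label", "n", "amplitude_mean", "amplitude_sd")
  if (!all(req %in% names(groups))) stop("'groups' needs columns ", paste(req, collapse = ", "))
  if (any(groups$n < 2)) stop("every group needs n >= 2")
  if (anyDuplicated(groups$label)) stop("group labels must be unique")
  if (is.null(nominal_center_mm))
    nominal_center_mm <- drop(voxel_to_mm(grid, ceiling(grid$shape / 2)))
  if (!mm_in_bounds(grid, nominal_center_mm))
    stop("'nominal_center_mm' lies outside the grid")
  if (peak_jitter_sd_mm < 0) stop("'peak_jitter_sd_mm' must be >= 0")
  if (blob_fwhm_mm <= 0) stop("'blob_fwhm_mm' must be > 0")
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  if (smoothing_fwhm_mm < 0) stop("'smoothing_fwhm_mm' must be >= 0")
  if (n_timepoints %% (2L * block_length) != 0L)
    stop("'n_timepoints' must be divisible by 2 * block_length")
  if (!all(groups$label %in% covariates$label))
    stop("'covariates' must have a row for every group")
  structure(list(grid = grid, groups = groups,
                 nominal_center_mm = as.numeric(nominal_center_mm),
                 peak_jitter_sd_mm = peak_jitter_sd_mm,
                 blob_fwhm_mm = blob_fwhm_mm,
                 n_timepoints = as.integer(n_timepoints),
                 block_length = as.integer(block_length), tr = tr,
                 noise_sd = noise_sd, baseline = baseline,
                 smoothing_fwhm_mm = smoothing_fwhm_mm, hrf = hrf,
                 covariates = covariates, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config:\n")
  cat(sprintf("  grid %d x %d x %d @ %g mm; T = %d (block %d, TR %g s)\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$voxel_size[1], x$n_timepoints, x$block_length, x$tr))
  cat(sprintf("  blob FWHM %g mm, jitter SD %g mm, noise SD %g, baseline %g, seed %d\n",
              x$blob_fwhm_mm, x$peak_jitter_sd_mm, x$noise_sd, x$baseline, x$seed))
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  group %-10s n = %3d, amplitude %g +/- %g\n",
                x$groups$label[i], x$groups$n[i],
                x$groups$amplitude_mean[i], x$groups$amplitude_sd[i]))
  invisible(x)
}

## Gaussian spatial profile (unit peak) centered at center_mm, as a V-vector
gaussian_blob <- function(grid, center_mm, fwhm_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  ax <- lapply(1:3, function(a)
    (grid$origin_mm[a] + (seq_len(grid$shape[a]) - 1) * grid$voxel_size[a] -
       center_mm[a])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  as.vector(exp(-d2 / (2 * sigma^2)))
}

#' Simulate a cohort of blocked-design BOLD time series
#'
#' For each subject: the activation center is drawn as the nominal center
#' plus per-axis Gaussian jitter, rounded to the nearest voxel and clipped
#' inside the grid; the activation amplitude is drawn from the subject's
#' group distribution; the time series is
#' `baseline + amplitude * blob * task_regressor + noise`, optionally
#' spatially smoothed. Covariates are drawn from the per-group covariate
#' model and each subject's realized median temporal SNR is recorded.
#'
#' @param config a [simulation_config()].
#' @return An object of class `sim_cohort` with elements `series` (list of
#'   T x V matrices), `truth` (data frame: subject_id, group, true peak voxel
#'   and amplitude, covariates), `design` (a [block_design()]), `grid`, and
#'   `config`. Deterministic given `config$seed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- config$grid
  design <- block_design(config$n_timepoints, config$block_length,
                         tr = config$tr, hrf = config$hrf)
  reg <- design$X[, 1]
  with_seed(config$seed, {
    n_total <- sum(config$groups$n)
    V <- n_voxels(grid)
    T <- config$n_timepoints
    series <- vector("list", n_total)
    group <- character(n_total)
    peak <- matrix(NA_integer_, n_total, 3)
    amp <- age <- wrat <- acc <- tsnr <- numeric(n_total)
    sex <- integer(n_total)
    sid <- 0L
    for (gi in seq_len(nrow(config$groups))) {
      g <- config$groups[gi, ]
      cv <- config$covariates[config$covariates$label == g$label, ]
      for (s in seq_len(g$n)) {
        sid <- sid + 1L
        center <- config$nominal_center_mm +
          stats::rnorm(3, 0, config$peak_jitter_sd_mm)
        pk <- drop(mm_to_voxel(grid, center, clip = TRUE))
        a <- stats::rnorm(1, g$amplitude_mean, g$amplitude_sd)
        blob <- gaussian_blob(grid, drop(voxel_to_mm(grid, pk)),
                              config$blob_fwhm_mm)
        y <- config$baseline + outer(reg, a * blob) +
          matrix(stats::rnorm(T * V, 0, config$noise_sd), T, V)
        if (config$smoothing_fwhm_mm > 0)
          for (t in seq_len(T))
            y[t, ] <- as.vector(gaussian_smooth(array(y[t, ], grid$shape),
                                                config$smoothing_fwhm_mm,
                                                grid$voxel_size))
        ## median per-voxel TSNR: mean over sample SD (n - 1)
        m <- colMeans(y)
        sdv <- sqrt(pmax(colSums(y * y) - T * m * m, 0) / (T - 1))
        series[[sid]] <- y
        group[sid] <- g$label
        peak[sid, ] <- pk
        amp[sid] <- a
        age[sid] <- stats::rnorm(1, cv$age_mean, cv$age_sd)
        sex[sid] <- stats::rbinom(1, 1, cv$sex_prop)
        wrat[sid] <- stats::rnorm(1, cv$wrat_mean, cv$wrat_sd)
        acc[sid] <- min(100, stats::rnorm(1, cv$accuracy_mean, cv$accuracy_sd))
        tsnr[sid] <- stats::median(ifelse(sdv == 0, NA_real_, m / sdv),
                                   na.rm = TRUE)
      }
    }
    truth <- data.frame(subject_id = sprintf("S%03d", seq_len(n_total)),
                        group = group, peak_i = peak[, 1], peak_j = peak[, 2],
                        peak_k = peak[, 3], amplitude = amp, age = age,
                        sex = sex, wrat = wrat, accuracy = acc, tsnr = tsnr,
                        stringsAsFactors = FALSE)
    structure(list(series = series, truth = truth,
                   design = design, grid = grid, config = config),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d subjects (%s), T = %d, grid %d x %d x %d\n",
              length(x$series),
              paste(sprintf("%s: %d", x$config$groups$label, x$config$groups$n),
                    collapse = ", "),
              x$config$n_timepoints,
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}

#' Simulate a cohort and fit the first-level GLM for every subject
#'
#' Convenience wrapper: [simulate_cohort()] followed by [fit_glm()] per
#' subject.
#'
#' @param config a [simulation_config()].
#' @param keep_series retain each subject's time series in the fitted object
#'   (needed by the eigenimage and peak-correlation measures).
#' @return A list with `flms` (list of [first_level()] objects), `truth`,
#'   `design`, `grid`, `config`.
#' @export
simulate_first_levels <- function(config, keep_series = TRUE) {
  sim <- simulate_cohort(config)
  flms <- lapply(sim$series, fit_glm, design = sim$design, grid = sim$grid,
                 keep_series = keep_series)
  list(flms = flms, truth = sim$truth, design = sim$design, grid = sim$grid,
       config = sim$config)
}

#' Temporal signal-to-noise ratio
#'
#' Per-voxel TSNR: the mean of the timecourse divided by its standard
#' deviation (sample SD, n - 1 denominator). Voxels with zero SD get `NA`.
#'
#' @param series a T x V matrix of timecourses (T >= 2), or a single
#'   timecourse as a numeric vector.
#' @param grid the [volume_grid()] of the voxels; omit for a single
#'   timecourse.
#' @return A [scalar_map()] of TSNR values, or a single number when `series`
#'   is a vector.
#' @export
compute_tsnr <- function(series, grid = NULL) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1L)
  T <- nrow(series)
  if (T < 2L) stop("TSNR needs at least 2 timepoints")
  m <- colMeans(series)
  s <- sqrt(colSums((series - rep(m, each = T))^2) / (T - 1))
  tsnr <- ifelse(s == 0, NA_real_, m / s)
  if (is.null(grid)) {
    if (length(tsnr) == 1L) return(unname(tsnr))
    stop("'grid' is required for multi-voxel input")
  }
  scalar_map(grid, tsnr)
}
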