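## File formats: NIfTI-1 volumes (single file, grid affine in the header),
## CSV tables with a header row and empty cells for missing values, YAML
## simulation configs.

grid_affine <- function(grid) {
  aff <- diag(c(grid$voxel_size, 1))
  aff[1:3, 4] <- grid$origin_mm
  aff
}

grid_from_nifti <- function(img) {
  aff <- RNifti::xform(img)
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  volume_grid(dim(img)[1:3], vox, aff[1:3, 4])
}

write_nifti_array <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(grid$voxel_size, rep(1, max(0L, nd - 3L)))
  RNifti::qform(img) <- structure(grid_affine(grid), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  list(grid = grid_from_nifti(img), values = as.array(img))
}

#' Read and write scalar maps as NIfTI
#'
#' @param map a [scalar_map()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_map()` returns a [scalar_map()]; `write_map()` returns
#'   `path` invisibly.
#' @export
write_map <- function(map, path) {
  write_nifti_array(map$values, map$grid, path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  x <- read_nifti_array(path)
  scalar_map(x$grid, x$values)
}

#' Read and write a subject's 4-D time series as NIfTI
#'
#' The T x V series matrix maps to a 4-D volume (V in linear voxel order).
#'
#' @param series a T x V matrix.
#' @param grid the [volume_grid()].
#' @param path file path.
#' @return `read_series()` returns a list with `series` (T x V matrix) and
#'   `grid`.
#' @export
write_series <- function(series, grid, path) {
  arr <- array(t(series), dim = c(grid$shape, nrow(series)))
  write_nifti_array(arr, grid, path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  x <- read_nifti_array(path)
  d <- dim(x$values)
  if (length(d) != 4L) stop("expected a 4-D NIfTI file")
  grid <- volume_grid(d[1:3], x$grid$voxel_size, x$grid$origin_mm)
  series <- t(matrix(x$values, prod(d[1:3]), d[4]))
  list(series = series, grid = grid)
}

#' Read and write cohort tables as CSV
#'
#' Header row included; missing values are empty cells.
#'
#' @param table a data frame.
#' @param path file path.
#' @return `read_table_csv()` returns a data frame; `write_table_csv()`
#'   returns `path` invisibly.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Save and load a simulation config as YAML
#'
#' All simulation parameters, including the seed, round-trip through a
#' structured text file.
#'
#' @param config a [simulation_config()].
#' @param path file path.
#' @return `read_simulation_config()` returns a [simulation_config()].
#' @export
write_simulation_config <- function(config, path) {
  x <- list(
    grid = list(shape = config$grid$shape,
                voxel_size = config$grid$voxel_size,
                origin_mm = config$grid$origin_mm),
    groups = lapply(seq_len(nrow(config$groups)), function(i)
      as.list(config$groups[i, ])),
    covariates = lapply(seq_len(nrow(config$covariates)), function(i)
      as.list(config$covariates[i, ])),
    nominal_center_mm = config$nominal_center_mm,
    peak_jitter_sd_mm = config$peak_jitter_sd_mm,
    blob_fwhm_mm = config$blob_fwhm_mm,
    n_timepoints = config$n_timepoints,
    block_length = config$block_length,
    tr = config$tr,
    noise_sd = config$noise_sd,
    baseline = config$baseline,
    smoothing_fwhm_mm = config$smoothing_fwhm_mm,
    hrf = config$hrf,
    seed = config$seed)
  writeLines(yaml::as.yaml(x), path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  simulation_config(
    grid = volume_grid(unlist(x$grid$shape), unlist(x$grid$voxel_size),
                       unlist(x$grid$origin_mm)),
    groups = do.call(rbind, lapply(x$groups, as.data.frame)),
    nominal_center_mm = unlist(x$nominal_center_mm),
    peak_jitter_sd_mm = x$peak_jitter_sd_mm,
    blob_fwhm_mm = x$blob_fwhm_mm,
    n_timepoints = x$n_timepoints,
    block_length = x$block_length,
    tr = x$tr,
    noise_sd = x$noise_sd,
    baseline = x$baseline,
    smoothing_fwhm_mm = x$smoothing_fwhm_mm,
    hrf = x$hrf,
    covariates = do.call(rbind, lapply(x$covariates, as.data.frame)),
    seed = x$seed)
}

#' Write a simulated cohort to a directory
#'
#' Writes per-subject 4-D series (`<subject_id>_series.nii.gz`), beta and t
#' maps if first levels are supplied, the truth/covariate table
#' (`truth.csv`), the design matrix (`design.csv`) and the config
#' (`config.yaml`).
#'
#' @param sim a `sim_cohort` from [simulate_cohort()] or the list returned
#'   by [simulate_first_levels()].
#' @param dir output directory (created if needed).
#' @param series write the 4-D series files (they dominate disk use).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, series = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sim$truth$subject_id
  if (series && !is.null(sim$series))
    for (i in seq_along(sim$series))
      write_series(sim$series[[i]], sim$grid,
                   file.path(dir, paste0(ids[i], "_series.nii.gz")))
  if (!is.null(sim$flms))
    for (i in seq_along(sim$flms)) {
      write_map(scalar_map(sim$grid, sim$flms[[i]]$beta),
                file.path(dir, paste0(ids[i], "_beta.nii.gz")))
      write_map(scalar_map(sim$grid, sim$flms[[i]]$tmap),
                file.path(dir, paste0(ids[i], "_tmap.nii.gz")))
      if (series && !is.null(sim$flms[[i]]$series))
        write_series(sim$flms[[i]]$series, sim$grid,
                     file.path(dir, paste0(ids[i], "_series.nii.gz")))
    }
  write_table_csv(sim$truth, file.path(dir, "truth.csv"))
  des <- as.data.frame(sim$design$X)
  write_table_csv(des, file.path(dir, "design.csv"))
  write_simulation_config(sim$config, file.path(dir, "config.yaml"))
  df <- data.frame(df = if (!is.null(sim$flms)) sim$flms[[1]]$df else NA)
  write_table_csv(df, file.path(dir, "df.csv"))
  invisible(dir)
}

#' Load the first-level maps of a cohort directory
#'
#' Reads the beta/t maps (and series when present) written by
#' [write_cohort()] back into [first_level()] objects.
#'
#' @param dir cohort directory.
#' @return A list with `flms`, `truth`, `grid`.
#' @export
read_cohort <- function(dir) {
  truth <- read_table_csv(file.path(dir, "truth.csv"))
  df <- read_table_csv(file.path(dir, "df.csv"))$df[1]
  if (is.na(df)) stop("no first-level maps in this cohort directory")
  flms <- lapply(truth$subject_id, function(id) {
    beta <- read_map(file.path(dir, paste0(id, "_beta.nii.gz")))
    tmap <- read_map(file.path(dir, paste0(id, "_tmap.nii.gz")))
    sf <- file.path(dir, paste0(id, "_series.nii.gz"))
    ser <- if (file.exists(sf)) read_series(sf)$series else NULL
    first_level(beta$grid, beta$values, tmap$values, df, series = ser)
  })
  list(flms = flms, truth = truth, grid = flms[[1]]$grid)
}
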