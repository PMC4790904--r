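#' Specify one ROI summary measure
#'
#' Identifies one of the ten measures, its variant (A: no voxel threshold;
#' B: voxels above the per-voxel p threshold only) and the parameter the
#' measure uses. Variant availability follows the measure definitions:
#' measures 1-4, 7 and 8 exist in both variants; the peak (5) and top-N (6)
#' measures are unthresholded; the peak-cluster measures (9, 10) are
#' intrinsically thresholded.
#'
#' @param measure integer 1..10:
#'   1 mean, 2 median, 3 eigenimage-weighted mean, 4 top-percentile mean,
#'   5 peak beta, 6 top-N contiguous voxels, 7 peak sphere, 8 peak-correlated
#'   voxels, 9 peak-cluster mean, 10 peak-cluster extent.
#' @param variant `"A"` or `"B"`; defaults to the only admissible variant
#'   for measures 5, 6 (A) and 9, 10 (B), otherwise A.
#' @param p_thresh per-voxel p threshold for B variants and measures 9, 10.
#' @param q top percentile for measure 4 (study values 25, 10, 5).
#' @param n_top N for measure 6 (study values 10, 20, 50).
#' @param radius_mm sphere radius for measure 7 (study values 6, 7.5, 10).
#' @param corr_r correlation threshold for measure 8 (study values 0.7, 0.8,
#'   0.9).
#' @return An object of class `measure_spec`.
#' @export
measure_spec <- function(measure, variant = NULL, p_thresh = 0.05,
                         q = 25, n_top = 10, radius_mm = 6, corr_r = 0.7) {
  measure <- as.integer(measure)
  if (is.na(measure) || measure < 1L || measure > 10L)
    stop("'measure' must be an integer in 1..10")
  allowed <- switch(measure,
                    c("A", "B"), c("A", "B"), c("A", "B"), c("A", "B"),
                    "A", "A", c("A", "B"), c("A", "B"), "B", "B")
  if (is.null(variant)) variant <- allowed[1L]
  if (!variant %in% allowed)
    stop(sprintf("variant %s is not defined for measure %d", variant, measure))
  structure(list(measure = measure, variant = variant, p_thresh = p_thresh,
                 q = q, n_top = n_top, radius_mm = radius_mm, corr_r = corr_r),
            class = "measure_spec")
}

#' Column label of a measure spec
#' @param spec a [measure_spec()].
#' @return A short string such as `"m04A_q25"` or `"m05"`, used as the column
#'   name in extracted cohort tables.
#' @export
measure_label <- function(spec) {
  base <- sprintf("m%02d", spec$measure)
  v <- if (spec$measure %in% c(5L, 6L, 9L, 10L)) "" else spec$variant
  param <- switch(spec$measure,
                  "", "", "", sprintf("_q%g", spec$q), "",
                  sprintf("_N%d", spec$n_top), sprintf("_r%g", spec$radius_mm),
                  sprintf("_c%g", spec$corr_r), "", "")
  paste0(base, v, param)
}

#' @export
print.measure_spec <- function(x, ...) {
  cat(sprintf("measure_spec %s (measure %d, variant %s)\n",
              measure_label(x), x$measure, x$variant))
  invisible(x)
}

#' The default battery of measure specs
#'
#' All sixteen measure/variant combinations of the measure table, at one
#' parameter setting each.
#'
#' @inheritParams measure_spec
#' @return A named list of [measure_spec()] objects.
#' @export
default_measure_specs <- function(p_thresh = 0.05, q = 25, n_top = 10,
                                  radius_mm = 6, corr_r = 0.7) {
  combos <- list(c(1, "A"), c(1, "B"), c(2, "A"), c(2, "B"), c(3, "A"),
                 c(3, "B"), c(4, "A"), c(4, "B"), c(5, "A"), c(6, "A"),
                 c(7, "A"), c(7, "B"), c(8, "A"), c(8, "B"), c(9, "B"),
                 c(10, "B"))
  specs <- lapply(combos, function(co)
    measure_spec(as.integer(co[1]), co[2], p_thresh = p_thresh, q = q,
                 n_top = n_top, radius_mm = radius_mm, corr_r = corr_r))
  names(specs) <- vapply(specs, measure_label, character(1))
  specs
}

#' Evaluate one measure spec on one subject
#'
#' Dispatches to the individual measure functions.
#'
#' @param flm a [first_level()] object.
#' @param roi a nonempty [roi_mask()].
#' @param spec a [measure_spec()].
#' @return A `summary_value`.
#' @export
roi_summary <- function(flm, roi, spec) {
  stopifnot(inherits(spec, "measure_spec"))
  check_measure_input(flm, roi)
  rctx <- roi_ctx(flm$grid, roi)
  m_dispatch(flm, rctx, subj_ctx(flm, rctx), spec)
}

m_dispatch <- function(flm, rctx, sctx, spec) {
  v <- spec$variant
  p <- spec$p_thresh
  switch(spec$measure,
         m_central(flm, rctx, sctx, "mean", v, p),
         m_central(flm, rctx, sctx, "median", v, p),
         m_eigen(flm, rctx, sctx, v, p),
         m_percentile(flm, rctx, sctx, spec$q, v, p),
         summary_value(sctx$b[sctx$peak], 1L),
         m_topn(flm, rctx, sctx, spec$n_top),
         m_sphere(flm, rctx, sctx, spec$radius_mm, v, p),
         m_corr(flm, rctx, sctx, spec$corr_r, v, p),
         m_cluster(flm, rctx, sctx, p, extent = FALSE),
         m_cluster(flm, rctx, sctx, p, extent = TRUE))
}

#' Extract all measures for a cohort
#'
#' Applies a list of measure specs to every subject and assembles the cohort
#' table: one row per subject, identifier and covariate columns from `meta`,
#' one column per spec; missing summary values become `NA`.
#'
#' @param flms list of [first_level()] objects, all on the ROI's grid.
#' @param roi a nonempty [roi_mask()].
#' @param specs a list of [measure_spec()] objects (default: the full
#'   default battery).
#' @param meta optional data frame with one row per subject (e.g. the
#'   `truth` table of [simulate_cohort()]); carried through unchanged.
#' @return A data frame.
#' @export
extract_all <- function(flms, roi, specs = default_measure_specs(),
                        meta = NULL) {
  if (inherits(specs, "measure_spec")) specs <- list(specs)
  for (f in flms)
    if (!same_grid(f$grid, roi$grid))
      stop("grid mismatch between subject maps and ROI")
  if (!is.null(meta) && nrow(meta) != length(flms))
    stop("'meta' must have one row per subject")
  labels <- vapply(specs, measure_label, character(1))
  vals <- matrix(NA_real_, nrow = length(flms), ncol = length(specs),
                 dimnames = list(NULL, labels))
  if (length(specs)) {
    if (roi$empty) stop("ROI is empty")
    rctx <- roi_ctx(roi$grid, roi)
    for (i in seq_along(flms)) {
      sctx <- subj_ctx(flms[[i]], rctx)
      for (j in seq_along(specs)) {
        sv <- m_dispatch(flms[[i]], rctx, sctx, specs[[j]])
        if (!sv$missing) vals[i, j] <- sv$value
      }
    }
  }
  if (is.null(meta))
    meta <- data.frame(subject_id = sprintf("S%03d", seq_along(flms)),
                       stringsAsFactors = FALSE)
  out <- cbind(meta, as.data.frame(vals), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
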