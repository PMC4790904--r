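## The ten ROI single-value summary measures. Each takes one subject's
## first-level result and an ROI and returns a `summary_value`. "A" variants
## use every ROI voxel; "B" variants first keep the voxels above a per-voxel
## p threshold (one-sided, uncorrected) and yield a missing value when no
## voxel survives — the same convention the peak-cluster measures use.
##
## Tie-breaking is deterministic throughout: voxels are ranked by t statistic
## and ties broken by the smallest lexicographic (i, j, k) index.
##
## Internally the measures work on a precomputed ROI context (voxel indices,
## lexicographic ranks, mm coordinates, 26-adjacency) and a per-subject
## context (t/beta vectors, the t-ordering, threshold masks), so that
## extract_all() can reuse them across specs and subjects.

summary_value <- function(value, n_voxels_used, missing = FALSE) {
  structure(list(value = if (missing) NA_real_ else value,
                 missing = missing,
                 n_voxels_used = as.integer(n_voxels_used)),
            class = "summary_value")
}

missing_value <- function() summary_value(NA_real_, 0L, missing = TRUE)

#' @export
print.summary_value <- function(x, ...) {
  if (x$missing) cat("summary_value: missing\n")
  else cat(sprintf("summary_value: %.6g (from %d voxels)\n",
                   x$value, x$n_voxels_used))
  invisible(x)
}

check_measure_input <- function(flm, roi) {
  if (!inherits(flm, "first_level")) stop("'flm' must be a first_level object")
  if (!inherits(roi, "roi_mask")) stop("'roi' must be an roi_mask")
  if (!same_grid(flm$grid, roi$grid)) stop("grid mismatch between map and ROI")
  if (roi$empty) stop("ROI is empty")
}

## ROI-level context, shared by all subjects on the same ROI
roi_ctx <- function(grid, roi) {
  idx <- which(roi$mask)
  list(idx = idx,
       m = length(idx),
       lexr = lex_rank(grid, idx),
       mm = voxel_to_mm(grid, index_to_ijk(grid, idx)),
       nbmat = roi_adjacency(grid, idx))
}

## subject-level context: maps restricted to the ROI, the global t-ordering
## (decreasing t, ties by lexicographic index) and a cache of threshold masks
subj_ctx <- function(flm, rctx) {
  t <- flm$tmap[rctx$idx]
  ord <- order(-t, rctx$lexr, na.last = TRUE)
  if (all(is.na(t))) stop("all t values in the ROI are NA")
  list(t = t, b = flm$beta[rctx$idx], ord = ord, peak = ord[1L],
       df = flm$df, acts = new.env(parent = emptyenv()))
}

## logical vector over ROI positions: voxels above the one-sided p threshold
act_pos <- function(sctx, p) {
  key <- format(p, digits = 17)
  if (!is.null(sctx$acts[[key]])) return(sctx$acts[[key]])
  a <- !is.na(sctx$t) & sctx$t > stats::qt(1 - p, df = sctx$df)
  sctx$acts[[key]] <- a
  a
}

## candidate positions for a variant, in t-order
cand_pos <- function(sctx, variant, p) {
  if (variant == "A") sctx$ord
  else {
    a <- act_pos(sctx, p)
    sctx$ord[a[sctx$ord]]
  }
}

#' Peak voxel of an ROI
#'
#' The voxel with the maximum t statistic inside the ROI; ties are broken by
#' the smallest lexicographic (i, j, k) index. `NA` t values are never
#' selected.
#'
#' @param flm a [first_level()] object.
#' @param roi a nonempty [roi_mask()] on the same grid.
#' @return The linear voxel index of the peak, with the (i, j, k) triplet as
#'   attribute `"ijk"`.
#' @export
find_peak <- function(flm, roi) {
  check_measure_input(flm, roi)
  rctx <- roi_ctx(flm$grid, roi)
  sctx <- subj_ctx(flm, rctx)
  peak <- rctx$idx[sctx$peak]
  structure(peak, ijk = drop(index_to_ijk(flm$grid, peak)))
}

#' ROI mean or median (measures 1 and 2)
#'
#' Mean or median of the contrast (beta) coefficients over the ROI (variant
#' A) or over its suprathreshold voxels (variant B). Variant B with no
#' suprathreshold voxel is missing.
#'
#' @param flm a [first_level()] object.
#' @param roi a nonempty [roi_mask()].
#' @param stat `"mean"` or `"median"`.
#' @param variant `"A"` (no threshold) or `"B"` (voxel p threshold first).
#' @param p_thresh per-voxel p threshold used by variant B.
#' @return A `summary_value`.
#' @export
central_summary <- function(flm, roi, stat = c("mean", "median"),
                            variant = c("A", "B"), p_thresh = 0.05) {
  stat <- match.arg(stat)
  variant <- match.arg(variant)
  check_measure_input(flm, roi)
  rctx <- roi_ctx(flm$grid, roi)
  m_central(flm, rctx, subj_ctx(flm, rctx), stat, variant, p_thresh)
}

m_central <- function(flm, rctx, sctx, stat, variant, p_thresh) {
  sel <- cand_pos(sctx, variant, p_thresh)
  if (!length(sel)) return(missing_value())
  b <- sctx$b[sel]
  summary_value(if (stat == "mean") mean(b) else stats::median(b), length(sel))
}

#' Eigenimage-weighted ROI mean (measure 3)
#'
#' The selected voxels' timecourses (mean-centered in time) are decomposed by
#' SVD; the first spatial singular vector — the first eigenimage, the spatial
#' pattern carrying the most timecourse variance — is used as voxel weights,
#' sign-fixed so the weights sum positive, and the summary is the weighted
#' mean of the beta coefficients, `sum(w * beta) / sum(w)`.
#'
#' If the centered timecourses are all zero (no temporal variance) the
#' weights degenerate and equal weights are used.
#'
#' @inheritParams central_summary
#' @return A `summary_value`.
#' @export
eigen_weighted_mean <- function(flm, roi, variant = c("A", "B"),
                                p_thresh = 0.05) {
  variant <- match.arg(variant)
  check_measure_input(flm, roi)
  rctx <- roi_ctx(flm$grid, roi)
  m_eigen(flm, rctx, subj_ctx(flm, rctx), variant, p_thresh)
}

m_eigen <- function(flm, rctx, sctx, variant, p_thresh) {
  if (is.null(flm$series)) stop("this measure needs the subject's time series")
  if (nrow(flm$series) < 2L) stop("need at least 2 timepoints")
  sel <- cand_pos(sctx, variant, p_thresh)
  if (!length(sel)) return(missing_value())
  b <- sctx$b[sel]
  M <- flm$series[, rctx$idx[sel], drop = FALSE]
  M <- M - rep(colMeans(M), each = nrow(M))
  sv <- svd(M, nu = 0, nv = 1)
  w <- sv$v[, 1]
  if (sv$d[1] <= .Machine$double.eps * max(dim(M)) || sum(w) == 0)
    w <- rep(1, length(sel))
  if (sum(w) < 0) w <- -w
  summary_value(sum(w * b) / sum(w), length(sel))
}

#' Mean of the top-percentile voxels (measure 4)
#'
#' Keeps the `ceiling(q/100 * m)` highest-t voxels of the candidate set of
#' size m (so at least one voxel is always kept) and averages their betas.
#'
#' @inheritParams central_summary
#' @param q top percentile to keep, in (0, 100]; 25 keeps the top quarter.
#' @return A `summary_value`.
#' @export
top_percentile_mean <- function(flm, roi, q = 25, variant = c("A", "B"),
                                p_thresh = 0.05) {
  variant <- match.arg(variant)
  if (q <= 0 || q > 100) stop("'q' must be in (0, 100]")
  check_measure_input(flm, roi)
  rctx <- roi_ctx(flm$grid, roi)
  m_percentile(flm, rctx, subj_ctx(flm, rctx), q, variant, p_thresh)
}

m_percentile <- function(flm, rctx, sctx, q, variant, p_thresh) {
  sel <- cand_pos(sctx, variant, p_thresh)
  if (!length(sel)) return(missing_value())
  keep <- ceiling(q / 100 * length(sel))
  summary_value(mean(sctx$b[sel[seq_len(keep)]]), keep)
}

#' Mean of the top-N contiguous voxels around the peak (measure 6)
#'
#' Greedy best-first region growing: starting from the ROI peak, repeatedly
#' add the highest-t voxel (ties by lexicographic index) among the
#' 26-connected neighbors of the current set that lie inside the ROI, until
#' the set holds `min(N, |ROI|)` voxels or the peak's connected component is
#' exhausted. The set always contains the peak and is always 26-connected.
#'
#' @inheritParams central_summary
#' @param n_top target number of voxels N.
#' @return A `summary_value`: the mean beta over the grown set.
#' @export
top_n_contiguous_mean <- function(flm, roi, n_top = 10) {
  if (n_top < 1) stop("'n_top' must be >= 1")
  check_measure_input(flm, roi)
  rctx <- roi_ctx(flm$grid, roi)
  m_topn(flm, rctx, subj_ctx(flm, rctx), n_top)
}

m_topn <- function(flm, rctx, sctx, n_top) {
  target <- min(n_top, rctx$m)
  inset <- logical(rctx$m)
  infront <- logical(rctx$m)
  set <- integer(target)
  set[1L] <- sctx$peak
  inset[sctx$peak] <- TRUE
  fr <- nbmat_row(rctx$nbmat, sctx$peak)
  infront[fr] <- TRUE
  size <- 1L
  while (size < target && length(fr)) {
    best <- fr[order(-sctx$t[fr], rctx$lexr[fr], na.last = TRUE)][1L]
    size <- size + 1L
    set[size] <- best
    inset[best] <- TRUE
    infront[best] <- FALSE
    nb <- nbmat_row(rctx$nbmat, best)
    nb <- nb[!inset[nb] & !infront[nb]]
    infront[nb] <- TRUE
    fr <- c(fr[fr != best], nb)
  }
  set <- set[seq_len(size)]
  summary_value(mean(sctx$b[set]), size)
}

nbmat_row <- function(nbmat, p) {
  nb <- nbmat[p, ]
  nb[!is.na(nb)]
}

#' Mean over a sphere around the peak (measure 7)
#'
#' Voxels within `radius_mm` of the ROI peak voxel's center, restricted to
#' the ROI (variant A) and additionally to the suprathreshold voxels
#' (variant B). Variant B with nothing suprathreshold is missing.
#'
#' @inheritParams central_summary
#' @param radius_mm sphere radius in mm; 0 keeps only the peak voxel.
#' @return A `summary_value`.
#' @export
peak_sphere_mean <- function(flm, roi, radius_mm = 6, variant = c("A", "B"),
                             p_thresh = 0.05) {
  variant <- match.arg(variant)
  if (radius_mm < 0) stop("'radius_mm' must be >= 0")
  check_measure_input(flm, roi)
  rctx <- roi_ctx(flm$grid, roi)
  m_sphere(flm, rctx, subj_ctx(flm, rctx), radius_mm, variant, p_thresh)
}

m_sphere <- function(flm, rctx, sctx, radius_mm, variant, p_thresh) {
  sel <- cand_pos(sctx, variant, p_thresh)
  if (!length(sel)) return(missing_value())
  ctr <- rctx$mm[sctx$peak, ]
  d2 <- (rctx$mm[sel, 1] - ctr[1])^2 + (rctx$mm[sel, 2] - ctr[2])^2 +
    (rctx$mm[sel, 3] - ctr[3])^2
  keep <- sel[d2 <= radius_mm^2]
  if (!length(keep)) return(missing_value())
  summary_value(mean(sctx$b[keep]), length(keep))
}

#' Mean over voxels correlated with the peak timecourse (measure 8)
#'
#' Pearson-correlates every candidate voxel's timecourse with the ROI peak
#' voxel's timecourse, keeps those with `r >= corr_r`, and then keeps only
#' the 26-connected component containing the peak ("highly correlated and
#' clustered together with the peak"). Zero-variance timecourses correlate 0
#' and are excluded; the peak itself always correlates 1.
#'
#' @inheritParams central_summary
#' @param corr_r correlation threshold in (0, 1].
#' @return A `summary_value`.
#' @export
peak_correlated_mean <- function(flm, roi, corr_r = 0.7, variant = c("A", "B"),
                                 p_thresh = 0.05) {
  variant <- match.arg(variant)
  if (corr_r <= 0 || corr_r > 1) stop("'corr_r' must be in (0, 1]")
  check_measure_input(flm, roi)
  rctx <- roi_ctx(flm$grid, roi)
  m_corr(flm, rctx, subj_ctx(flm, rctx), corr_r, variant, p_thresh)
}

m_corr <- function(flm, rctx, sctx, corr_r, variant, p_thresh) {
  if (is.null(flm$series)) stop("this measure needs the subject's time series")
  sel <- cand_pos(sctx, variant, p_thresh)
  if (!length(sel)) return(missing_value())
  p <- flm$series[, rctx$idx[sctx$peak]]
  p <- p - mean(p)
  M <- flm$series[, rctx$idx[sel], drop = FALSE]
  M <- M - rep(colMeans(M), each = nrow(M))
  den <- sqrt(colSums(M^2) * sum(p^2))
  r <- ifelse(den == 0, 0, colSums(M * p) / den)
  r[sel == sctx$peak] <- 1
  kept <- logical(rctx$m)
  kept[sel[r >= corr_r]] <- TRUE
  comp <- reach_component(rctx$nbmat, kept, sctx$peak)
  summary_value(mean(sctx$b[comp]), length(comp))
}

#' Mean of the suprathreshold cluster containing the peak (measure 9)
#'
#' The suprathreshold voxels of the ROI are split into 26-connected
#' clusters; the summary is the mean beta over the cluster containing the
#' ROI peak, with no maximum cluster size. With no suprathreshold voxel the
#' subject's value is missing.
#'
#' @inheritParams central_summary
#' @return A `summary_value`.
#' @export
peak_cluster_mean <- function(flm, roi, p_thresh = 0.05) {
  check_measure_input(flm, roi)
  rctx <- roi_ctx(flm$grid, roi)
  m_cluster(flm, rctx, subj_ctx(flm, rctx), p_thresh, extent = FALSE)
}

#' Extent of the suprathreshold cluster containing the peak (measure 10)
#'
#' As [peak_cluster_mean()] but the summary is the cluster's voxel count.
#'
#' @inheritParams central_summary
#' @return A `summary_value` whose value is a non-negative integer count.
#' @export
peak_cluster_extent <- function(flm, roi, p_thresh = 0.05) {
  check_measure_input(flm, roi)
  rctx <- roi_ctx(flm$grid, roi)
  m_cluster(flm, rctx, subj_ctx(flm, rctx), p_thresh, extent = TRUE)
}

m_cluster <- function(flm, rctx, sctx, p_thresh, extent) {
  act <- act_pos(sctx, p_thresh)
  if (!any(act)) return(missing_value())
  ## the ROI peak has the maximum t, so it is suprathreshold whenever
  ## anything is
  comp <- reach_component(rctx$nbmat, act, sctx$peak)
  summary_value(if (extent) length(comp) else mean(sctx$b[comp]), length(comp))
}
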