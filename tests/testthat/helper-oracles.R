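# Independent brute-force oracles for the summary measures. These
# deliberately use different code paths from the package: data-frame sorts
# with explicit (i, j, k) columns, pairwise Chebyshev-distance adjacency,
# igraph connected components, and eigen() instead of svd().

o_coords <- function(grid, idx) {
  ijk <- arrayInd(idx, grid$shape)
  colnames(ijk) <- c("i", "j", "k")
  ijk
}

# voxels of idx sorted by decreasing t, ties by (i, j, k) ascending
o_sorted <- function(flm, idx) {
  ijk <- o_coords(flm$grid, idx)
  idx[order(-flm$tmap[idx], ijk[, 1], ijk[, 2], ijk[, 3])]
}

o_act_idx <- function(flm, roi, p) {
  idx <- which(roi$mask)
  idx[flm$tmap[idx] > stats::qt(1 - p, flm$df)]
}

o_candidates <- function(flm, roi, variant, p) {
  if (variant == "A") which(roi$mask) else o_act_idx(flm, roi, p)
}

o_peak <- function(flm, roi) o_sorted(flm, which(roi$mask))[1]

# adjacency by pairwise Chebyshev distance, components via igraph
o_components <- function(grid, idx) {
  n <- length(idx)
  if (n == 0) return(integer(0))
  ijk <- o_coords(grid, idx)
  edges <- c()
  if (n > 1)
    for (a in 1:(n - 1))
      for (b in (a + 1):n)
        if (max(abs(ijk[a, ] - ijk[b, ])) <= 1) edges <- c(edges, a, b)
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::components(g)$membership
}

o_measure <- function(flm, roi, spec) {
  v <- spec$variant
  p <- spec$p_thresh
  sel <- o_candidates(flm, roi, v, p)
  if (spec$measure %in% c(1, 2, 3, 4, 7, 8) && length(sel) == 0)
    return(NA_real_)
  switch(spec$measure,
         mean(flm$beta[sel]),
         stats::median(flm$beta[sel]),
         o_eigen(flm, sel),
         {
           keep <- o_sorted(flm, sel)[seq_len(ceiling(spec$q / 100 * length(sel)))]
           mean(flm$beta[keep])
         },
         flm$beta[o_peak(flm, roi)],
         o_top_n(flm, roi, spec$n_top),
         {
           ctr <- voxel_to_mm(flm$grid, o_coords(flm$grid, o_peak(flm, roi)))
           mm <- voxel_to_mm(flm$grid, o_coords(flm$grid, sel))
           keep <- sel[sqrt(rowSums(sweep(mm, 2, drop(ctr))^2)) <= spec$radius_mm]
           if (!length(keep)) NA_real_ else mean(flm$beta[keep])
         },
         o_peak_corr(flm, roi, sel, spec$corr_r),
         o_peak_cluster(flm, roi, p, extent = FALSE),
         o_peak_cluster(flm, roi, p, extent = TRUE))
}

o_eigen <- function(flm, sel) {
  M <- flm$series[, sel, drop = FALSE]
  M <- scale(M, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(M), symmetric = TRUE)
  w <- ev$vectors[, 1]
  if (sum(w) < 0) w <- -w
  sum(w * flm$beta[sel]) / sum(w)
}

# region growth re-implemented with pairwise Chebyshev adjacency
o_top_n <- function(flm, roi, n_top) {
  idx <- which(roi$mask)
  target <- min(n_top, length(idx))
  set <- o_peak(flm, roi)
  while (length(set) < target) {
    ijk_set <- o_coords(flm$grid, set)
    rest <- setdiff(idx, set)
    adj <- vapply(rest, function(vv) {
      d <- abs(sweep(ijk_set, 2, as.numeric(o_coords(flm$grid, vv))))
      any(apply(d, 1, max) <= 1)
    }, logical(1))
    frontier <- rest[adj]
    if (!length(frontier)) break
    set <- c(set, o_sorted(flm, frontier)[1])
  }
  mean(flm$beta[set])
}

o_peak_corr <- function(flm, roi, sel, r_thresh) {
  if (!length(sel)) return(NA_real_)
  peak <- o_peak(flm, roi)
  r <- vapply(sel, function(vv) {
    if (stats::sd(flm$series[, vv]) == 0) return(0)
    stats::cor(flm$series[, peak], flm$series[, vv])
  }, numeric(1))
  r[sel == peak] <- 1
  kept <- sel[r >= r_thresh]
  memb <- o_components(flm$grid, kept)
  comp <- kept[memb == memb[kept == peak]]
  mean(flm$beta[comp])
}

o_peak_cluster <- function(flm, roi, p, extent) {
  act <- o_act_idx(flm, roi, p)
  if (!length(act)) return(NA_real_)
  peak <- o_peak(flm, roi)
  memb <- o_components(flm$grid, act)
  comp <- act[memb == memb[act == peak]]
  if (extent) length(comp) else mean(flm$beta[comp])
}
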