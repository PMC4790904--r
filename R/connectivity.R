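## 26-connectivity helpers. All cluster-based measures use the full 3-D
## neighborhood (faces, edges and corners of each voxel).

.offsets26 <- local({
  o <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
})

## valid 26-neighbors (linear indices) of one voxel
voxel_neighbors <- function(grid, idx) {
  ijk <- index_to_ijk(grid, idx)
  nb <- sweep(.offsets26, 2, as.integer(ijk), `+`)
  ok <- nb[, 1] >= 1L & nb[, 1] <= grid$shape[1] &
    nb[, 2] >= 1L & nb[, 2] <= grid$shape[2] &
    nb[, 3] >= 1L & nb[, 3] <= grid$shape[3]
  ijk_to_index(grid, nb[ok, , drop = FALSE])
}

## adjacency of a voxel set, vectorized over the 26 offsets: an m x 26
## integer matrix of positions into idx (NA where no in-set neighbor)
roi_adjacency <- function(grid, idx) {
  m <- length(idx)
  if (!m) return(matrix(NA_integer_, 0, 26))
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  ijk <- index_to_ijk(grid, idx)
  pos_of <- integer(n_voxels(grid))
  pos_of[idx] <- seq_len(m)
  nbmat <- matrix(NA_integer_, m, 26L)
  for (s in seq_len(26L)) {
    ni <- ijk[, 1] + .offsets26[s, 1]
    nj <- ijk[, 2] + .offsets26[s, 2]
    nk <- ijk[, 3] + .offsets26[s, 3]
    ok <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny & nk >= 1L & nk <= nz
    p <- pos_of[ni[ok] + (nj[ok] - 1L) * nx + (nk[ok] - 1L) * nx * ny]
    p[p == 0L] <- NA_integer_
    nbmat[ok, s] <- p
  }
  nbmat
}

## BFS over adjacency positions: all positions reachable from `start` while
## staying inside the logical set `inside` (length m)
reach_component <- function(nbmat, inside, start) {
  m <- length(inside)
  visited <- logical(m)
  visited[start] <- TRUE
  queue <- start
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]
    head <- head + 1L
    nb <- nbmat[v, ]
    nb <- nb[!is.na(nb)]
    nb <- nb[inside[nb] & !visited[nb]]
    if (length(nb)) {
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  which(visited)
}

#' Label 26-connected components of a voxel set
#'
#' @param grid a [volume_grid()].
#' @param idx integer vector of linear voxel indices (a voxel set).
#' @return Integer vector of component labels (1, 2, ...) aligned with `idx`;
#'   labels are assigned in order of first appearance in `idx`.
#' @export
connected_components <- function(grid, idx) {
  idx <- as.integer(idx)
  m <- length(idx)
  if (!m) return(integer(0))
  nbmat <- roi_adjacency(grid, idx)
  inside <- rep(TRUE, m)
  label <- integer(m)
  cur <- 0L
  for (p in seq_len(m)) {
    if (label[p] > 0L) next
    cur <- cur + 1L
    label[reach_component(nbmat, inside, p)] <- cur
  }
  label
}
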