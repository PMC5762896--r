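# Vectorized voxel-neighborhood machinery shared by the texture matrices and
# by connected-component cleanup of synthetic masks.

# The 13 unique 3D displacement directions (one per +/- pair): every nonzero
# offset in {-1,0,1}^3 whose first nonzero component is positive.
glcm_offsets_3d <- function(distance = 1L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- apply(g, 1, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[1]] > 0
  })
  g[keep, , drop = FALSE] * as.integer(distance)
}

# Neighbor pairs among a voxel subset of a 3D grid.
#
# idx: linear indices of the subset (e.g. in-mask voxels); dims: grid shape;
# offsets: k x 3 integer displacement matrix (one direction per +/- pair).
# Returns a 2-column matrix of positions *within idx* (i, j), each unordered
# pair listed once.
voxel_neighbor_pairs <- function(idx, dims, offsets = glcm_offsets_3d(1L)) {
  if (length(idx) == 0L) return(matrix(integer(0), ncol = 2))
  lut <- integer(prod(dims))
  lut[idx] <- seq_along(idx)
  co <- arrayInd(idx, dims)
  out <- vector("list", nrow(offsets))
  for (r in seq_len(nrow(offsets))) {
    nb <- co + rep(offsets[r, ], each = nrow(co))
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * dims[1] +
      (nb[ok, 3] - 1L) * dims[1] * dims[2]
    j <- lut[lin]
    hit <- j > 0L
    if (!any(hit)) next
    out[[r]] <- cbind(which(ok)[hit], j[hit])
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs)) matrix(integer(0), ncol = 2) else pairs
}

# 26- or 6-connectivity direction set (13 or 3 unique directions).
connectivity_offsets <- function(connectivity = 26) {
  o <- glcm_offsets_3d(1L)
  if (connectivity == 26) return(o)
  if (connectivity == 6) return(o[rowSums(abs(o)) == 1L, , drop = FALSE])
  stop("connectivity must be 6 or 26")
}

# Label connected components of a voxel subset; returns integer labels
# (1..n_components) parallel to idx. Components are maximal under the given
# connectivity.
label_components <- function(idx, dims, connectivity = 26) {
  if (length(idx) == 0L) return(integer(0))
  pairs <- voxel_neighbor_pairs(idx, dims, connectivity_offsets(connectivity))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(pairs) > 0L) g <- igraph::add_edges(g, t(pairs))
  igraph::components(g)$membership
}
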