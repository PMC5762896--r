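# 3D convex hull as a half-space intersection, used by roi_solidity().
#
# The hull is built by randomized incremental insertion on deterministically
# jittered copies of the input points; facet offsets are then re-tightened
# against the *unjittered* points so the returned half-spaces always contain
# the original point set. For voxel-center geometry (integer coordinates in a
# grid of a few hundred voxels per axis) the smallest nonzero point-to-facet
# distance is >> 1e-4, so a membership tolerance of 1e-6 (relative) cannot
# misclassify a point that is genuinely outside, while points exactly on a
# hull facet are always counted as inside.

# Deterministic quasi-random jitter in [-1, 1), no RNG state touched.
.hull_jitter <- function(n) {
  i <- seq_len(n)
  ((i * 2654435761) %% 4099) / 2049.5 - 1
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Outward-oriented plane through three points; returns c(normal, offset) with
# unit normal such that normal . interior < offset, or NULL if degenerate.
.facet_plane <- function(v1, v2, v3, interior, eps) {
  n <- .cross3(v2 - v1, v3 - v1)
  nn <- sqrt(sum(n^2))
  if (nn < eps) return(NULL)
  n <- n / nn
  b <- sum(n * v1)
  if (sum(n * interior) > b) {
    n <- -n
    b <- -b
  }
  c(n, b)
}

#' Convex hull of 3D points as half-space inequalities
#'
#' Computes the convex hull of a set of 3D points and returns it in
#' half-space form: a matrix of unit outward normals `normals` and offsets
#' `offsets` such that a point `x` lies inside or on the hull iff
#' `normals %*% x <= offsets + tol` for every row.
#'
#' @param points numeric matrix with 3 columns (one point per row).
#' @return list with elements `normals` (f x 3), `offsets` (length f) and
#'   `scale` (the coordinate magnitude used to set tolerances).
#' @keywords internal
convex_hull_halfspaces <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  P0 <- unique(points)
  m <- nrow(P0)
  scl <- max(1, max(abs(P0)))
  eps <- 1e-12 * scl
  if (m < 4) {
    stop("degenerate geometry: need at least 4 distinct non-coplanar points")
  }

  jit <- matrix(.hull_jitter(3L * m), ncol = 3) * 1e-7 * scl
  P <- P0 + jit

  # Initial simplex: four affinely independent points.
  i1 <- which.min(P[, 1])
  d2 <- rowSums((P - rep(P[i1, ], each = m))^2)
  i2 <- which.max(d2)
  e12 <- P[i2, ] - P[i1, ]
  rel <- P - rep(P[i1, ], each = m)
  cr <- cbind(rel[, 2] * e12[3] - rel[, 3] * e12[2],
              rel[, 3] * e12[1] - rel[, 1] * e12[3],
              rel[, 1] * e12[2] - rel[, 2] * e12[1])
  i3 <- which.max(rowSums(cr^2))
  nrm <- .cross3(e12, P[i3, ] - P[i1, ])
  nn <- sqrt(sum(nrm^2))
  if (nn < eps) stop("degenerate geometry: points are collinear")
  hdist <- abs(rel %*% (nrm / nn))
  i4 <- which.max(hdist)
  # Jitter makes exact coplanarity measure-zero, but the unjittered input can
  # still be a plane: detect via the unjittered points.
  rel0 <- P0 - rep(P0[i1, ], each = m)
  n0 <- .cross3(P0[i2, ] - P0[i1, ], P0[i3, ] - P0[i1, ])
  if (sqrt(sum(n0^2)) > eps) {
    if (max(abs(rel0 %*% (n0 / sqrt(sum(n0^2))))) < 1e-9 * scl) {
      stop("degenerate geometry: points are coplanar")
    }
  }
  simplex <- c(i1, i2, i3, i4)
  interior <- colMeans(P[simplex, , drop = FALSE])

  tri <- rbind(simplex[c(1, 2, 3)], simplex[c(1, 2, 4)],
               simplex[c(1, 3, 4)], simplex[c(2, 3, 4)])
  planes <- t(apply(tri, 1, function(ix) {
    .facet_plane(P[ix[1], ], P[ix[2], ], P[ix[3], ], interior, eps)
  }))

  eps_vis <- 1e-9 * scl
  rest <- setdiff(seq_len(m), simplex)
  # Far points first: keeps the partial hull growing outward quickly.
  rest <- rest[order(-rowSums((P[rest, , drop = FALSE] -
                                 rep(interior, each = length(rest)))^2))]

  for (ip in rest) {
    p <- P[ip, ]
    vis <- which(planes[, 1:3, drop = FALSE] %*% p - planes[, 4] > eps_vis)
    if (length(vis) == 0L) next
    vt <- tri[vis, , drop = FALSE]
    ed <- rbind(vt[, c(1, 2), drop = FALSE],
                vt[, c(2, 3), drop = FALSE],
                vt[, c(3, 1), drop = FALSE])
    key <- pmin(ed[, 1], ed[, 2]) * (m + 1) + pmax(ed[, 1], ed[, 2])
    # Horizon = undirected edges appearing in exactly one visible facet.
    horizon <- ed[!(key %in% key[duplicated(key)]), , drop = FALSE]
    new_tri <- NULL
    new_pl <- NULL
    ok <- TRUE
    for (r in seq_len(nrow(horizon))) {
      a <- horizon[r, 1]; b <- horizon[r, 2]
      pl <- .facet_plane(P[a, ], P[b, ], p, interior, eps)
      if (is.null(pl)) { ok <- FALSE; break }
      new_tri <- rbind(new_tri, c(a, b, ip))
      new_pl <- rbind(new_pl, pl)
    }
    if (!ok) next  # numerically degenerate insertion; point is (near-)boundary
    tri <- rbind(tri[-vis, , drop = FALSE], new_tri)
    planes <- rbind(planes[-vis, , drop = FALSE], new_pl)
  }

  normals <- planes[, 1:3, drop = FALSE]
  # Re-tighten offsets against the unjittered points so every original point
  # satisfies all inequalities exactly (up to fp rounding).
  offsets <- apply(normals %*% t(P0), 1, max)
  list(normals = normals, offsets = offsets, scale = scl)
}

#' Count grid points inside a convex hull
#'
#' Tests candidate points against the half-space form returned by
#' [convex_hull_halfspaces()], in chunks to bound memory.
#'
#' @param hs half-space list from [convex_hull_halfspaces()].
#' @param pts numeric matrix (n x 3) of points to classify.
#' @return logical vector: inside or on the hull.
#' @keywords internal
points_in_hull <- function(hs, pts) {
  tol <- 1e-6 * hs$scale
  n <- nrow(pts)
  inside <- logical(n)
  chunk <- max(1L, floor(4e6 / max(1L, nrow(hs$normals))))
  start <- 1L
  while (start <= n) {
    end <- min(n, start + chunk - 1L)
    v <- hs$normals %*% t(pts[start:end, , drop = FALSE]) - hs$offsets
    inside[start:end] <- colSums(v > tol) == 0L
    start <- end + 1L
  }
  inside
}

# Count integer grid points (voxel centers) inside or on the hull, exploiting
# convexity: within each (y, z) column the in-hull x coordinates form one
# contiguous interval whose bounds follow from the facet inequalities
# a1 x <= b + tol - a2 y - a3 z.
count_hull_grid_points <- function(hs, xrange, yrange, zrange) {
  tol <- 1e-6 * hs$scale
  A <- hs$normals
  b <- hs$offsets + tol
  eps <- 1e-9
  yz <- as.matrix(expand.grid(y = seq.int(yrange[1], yrange[2]),
                              z = seq.int(zrange[1], zrange[2])))
  S <- b - A[, 2:3, drop = FALSE] %*% t(yz)  # f x m
  a1 <- A[, 1]
  pos <- a1 > eps
  neg <- a1 < -eps
  ver <- !pos & !neg
  m <- nrow(yz)
  xu <- rep(Inf, m)
  xl <- rep(-Inf, m)
  if (any(pos))
    xu <- pmin(xu, apply(S[pos, , drop = FALSE] / a1[pos], 2, min))
  if (any(neg))
    xl <- pmax(xl, apply(S[neg, , drop = FALSE] / a1[neg], 2, max))
  feas <- if (any(ver)) colSums(S[ver, , drop = FALSE] < 0) == 0L else
    rep(TRUE, m)
  xu <- pmin(xu, xrange[2])
  xl <- pmax(xl, xrange[1])
  cnt <- floor(xu + 1e-9) - ceiling(xl - 1e-9) + 1
  sum(pmax(0, cnt[feas & cnt > 0]))
}
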