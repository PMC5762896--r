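#' 3D shape features of a segmented lesion
#'
#' Shape descriptors of a binary tumor mask: solidity (convexity), extent
#' (bounding-box fill) and eccentricity (ellipsoid-fit elongation). Following
#' the convention that the contour drawn on the first post-contrast series is
#' mapped to all timepoints, shape is a property of the single mask and is
#' computed once per lesion.
#'
#' @param mask logical (or 0/1) 3D array; `TRUE` marks tumor voxels.
#' @param spacing numeric length-3 voxel spacing in mm (used by
#'   [roi_eccentricity()] only; solidity and extent are voxel-count ratios).
#' @return scalar feature value.
#' @name shape_features
NULL

.check_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  m <- mask != 0
  if (!any(m)) stop("empty mask")
  m
}

#' @describeIn shape_features Fraction of convex-hull grid voxels occupied by
#'   the lesion: (foreground voxel count) / (number of grid voxel centers
#'   inside or on the convex hull of the foreground voxel centers). 1 for a
#'   convex lesion; lower for lesions with concave, irregular margins.
#'   Requires at least 4 non-coplanar foreground voxels.
#' @export
roi_solidity <- function(mask) {
  m <- .check_mask(mask)
  dims <- dim(m)
  fg <- which(m)
  co <- arrayInd(fg, dims)
  cand <- .hull_candidates(co)
  hs <- convex_hull_halfspaces(cand)
  # Hull of voxel centers lies inside the foreground bounding box.
  rng <- apply(co, 2, range)
  n_hull <- count_hull_grid_points(hs, rng[, 1], rng[, 2], rng[, 3])
  min(1, length(fg) / n_hull)
}

# Candidate hull vertices: union over z-slices of 2D convex-hull vertices.
# Any extreme point of the 3D cloud is extreme within its own slice.
.hull_candidates <- function(co) {
  keep <- unlist(lapply(split(seq_len(nrow(co)), co[, 3]), function(ix) {
    if (length(ix) <= 4L) return(ix)
    xy <- co[ix, 1:2, drop = FALSE]
    ix[unique(grDevices::chull(xy[, 1], xy[, 2]))]
  }), use.names = FALSE)
  co[keep, , drop = FALSE]
}

#' @describeIn shape_features Foreground voxel count divided by the volume (in
#'   voxels) of the tight axis-aligned bounding box.
#' @export
roi_extent <- function(mask) {
  m <- .check_mask(mask)
  co <- arrayInd(which(m), dim(m))
  box <- prod(apply(co, 2, function(v) diff(range(v)) + 1L))
  sum(m) / box
}

#' @describeIn shape_features Meridional eccentricity `sqrt(1 - l_min/l_max)`
#'   of the best-fit ellipsoid, where `l_min <= l_max` are the smallest and
#'   largest eigenvalues of the covariance of foreground voxel center
#'   coordinates scaled by `spacing` (physical, mm-space elongation). 0 for a
#'   ball, approaching 1 for a needle. A single-voxel mask returns 0.
#' @export
roi_eccentricity <- function(mask, spacing = c(1, 1, 1)) {
  m <- .check_mask(mask)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  co <- arrayInd(which(m), dim(m))
  if (nrow(co) < 2L) return(0)
  xyz <- sweep(co, 2, spacing, `*`)
  ev <- eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  sqrt(max(0, 1 - min(ev) / max(ev)))
}
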