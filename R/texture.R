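# Texture features: 16-level quantization, gray-level co-occurrence matrix
# (GLCM) and gray-level size zone matrix (GLSZM).

#' Quantize in-mask intensities to discrete gray levels
#'
#' Equal-width binning of the in-mask intensity range into `levels` gray
#' levels: `level = min(L, floor((v - min) / (max - min) * L) + 1)`. The
#' minimum in-mask intensity maps to level 1 and the maximum to level `L`.
#' Binning is per scan within the ROI, which makes the downstream texture
#' features invariant to global intensity scaling of a sequence. A constant
#' region is legal and maps every voxel to level 1.
#'
#' @param values numeric 3D array of intensities.
#' @param mask logical 3D array, same shape.
#' @param levels number of gray levels (default 16).
#' @return object of class `quantized_roi`: list with `levels` (3D integer
#'   array, 0 outside the mask, 1..L inside), `n_levels`, and `bin_edges`
#'   (length L + 1).
#' @export
quantize_roi <- function(values, mask, levels = 16L) {
  m <- .check_mask(mask)
  if (!identical(dim(values), dim(m))) stop("values/mask shape mismatch")
  L <- as.integer(levels)
  stopifnot(L >= 1L)
  x <- values[m]
  lo <- min(x)
  hi <- max(x)
  q <- array(0L, dim(values))
  if (hi > lo) {
    lv <- pmin(L, floor((x - lo) / (hi - lo) * L) + 1L)
  } else {
    lv <- rep(1L, length(x))
  }
  q[m] <- as.integer(lv)
  structure(list(levels = q, n_levels = L,
                 bin_edges = seq(lo, hi, length.out = L + 1)),
            class = "quantized_roi")
}

#' Gray-level co-occurrence matrix of a quantized ROI
#'
#' Accumulates co-occurring level pairs over the 13 unique 3D directions at a
#' fixed voxel `distance`, with both voxels inside the mask. Pairs are counted
#' symmetrically (each contributes to `(i, j)` and `(j, i)`) and all
#' directions are pooled into one matrix, which is then normalized to pair
#' probabilities. Pooling across directions (rather than averaging per
#' direction features) is the package convention; see `aggregate`.
#'
#' @param q a [quantize_roi()] result.
#' @param distance voxel offset length along each direction (default 1).
#' @param aggregate `"sum"` (default) pools counts over directions before
#'   normalizing. (Kept as an explicit argument so a per-direction variant can
#'   be added without changing the call sites.)
#' @return object of class `glcm`: list with `p` (L x L probability matrix)
#'   and `offsets_used`.
#' @export
glcm_matrix <- function(q, distance = 1L, aggregate = c("sum")) {
  stopifnot(inherits(q, "quantized_roi"))
  aggregate <- match.arg(aggregate)
  L <- q$n_levels
  dims <- dim(q$levels)
  idx <- which(q$levels > 0L)
  offs <- glcm_offsets_3d(distance)
  pairs <- voxel_neighbor_pairs(idx, dims, offs)
  if (nrow(pairs) == 0L) stop("no in-mask voxel pairs at this distance")
  lv <- q$levels[idx]
  i <- lv[pairs[, 1]]
  j <- lv[pairs[, 2]]
  counts <- matrix(tabulate(c((i - 1L) * L + j, (j - 1L) * L + i),
                            nbins = L * L),
                   nrow = L, byrow = TRUE)
  structure(list(p = counts / sum(counts), offsets_used = offs),
            class = "glcm")
}

#' GLCM scalar features
#'
#' The four co-occurrence features: energy `sum(p^2)`, entropy
#' `-sum(p log2 p)` (with `0 log 0 = 0`), homogeneity (inverse difference)
#' `sum(p / (1 + |i - j|))` and contrast `sum(p (i - j)^2)`.
#'
#' @param g a [glcm_matrix()] result.
#' @param homogeneity `"inverse_difference"` (default) or
#'   `"inverse_difference_moment"` (`1 + (i - j)^2` denominator).
#' @return named numeric vector: `energy`, `entropy`, `homogeneity`,
#'   `contrast`.
#' @export
glcm_features <- function(g, homogeneity = c("inverse_difference",
                                             "inverse_difference_moment")) {
  stopifnot(inherits(g, "glcm"))
  homogeneity <- match.arg(homogeneity)
  p <- g$p
  L <- nrow(p)
  i <- row(p)
  j <- col(p)
  nz <- p > 0
  dd <- if (homogeneity == "inverse_difference") 1 + abs(i - j) else
    1 + (i - j)^2
  c(energy = sum(p^2),
    entropy = -sum(p[nz] * log2(p[nz])),
    homogeneity = sum(p / dd),
    contrast = sum(p * (i - j)^2))
}

#' Gray-level size zone matrix of a quantized ROI
#'
#' A zone is a maximal connected set of in-mask voxels sharing one gray
#' level; `counts[i, j]` is the number of zones of level `i` and size `j`
#' voxels. Connectivity is 26 (face, edge and corner neighbors) by default,
#' the 3D analog of the original 8-connected 2D definition; 6-connectivity is
#' available.
#'
#' @param q a [quantize_roi()] result.
#' @param connectivity 26 (default) or 6.
#' @return object of class `glszm`: list with `counts` (L x S_max matrix),
#'   `n_zones` and `n_voxels`.
#' @export
glszm_matrix <- function(q, connectivity = 26) {
  stopifnot(inherits(q, "quantized_roi"))
  L <- q$n_levels
  dims <- dim(q$levels)
  idx <- which(q$levels > 0L)
  lv <- q$levels[idx]
  pairs <- voxel_neighbor_pairs(idx, dims, connectivity_offsets(connectivity))
  same <- pairs[lv[pairs[, 1]] == lv[pairs[, 2]], , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(same) > 0L) g <- igraph::add_edges(g, t(same))
  memb <- igraph::components(g)$membership
  zone_size <- tabulate(memb)
  zone_level <- lv[match(seq_along(zone_size), memb)]
  smax <- max(zone_size)
  counts <- matrix(0, nrow = L, ncol = smax)
  for (z in seq_along(zone_size)) {
    counts[zone_level[z], zone_size[z]] <- counts[zone_level[z], zone_size[z]] + 1
  }
  structure(list(counts = counts, n_zones = length(zone_size),
                 n_voxels = length(idx)),
            class = "glszm")
}

#' The 11 GLSZM scalar features
#'
#' With `P = counts`, `N_z` the zone count and `N_p` the in-mask voxel count,
#' gray level `i` and zone size `j`:
#' \describe{
#'   \item{SZE / LZE}{small-/large-zone emphasis, `(1/N_z) sum P / j^2` and
#'     `(1/N_z) sum P j^2`}
#'   \item{LIZE / HIZE}{low-/high-intensity zone emphasis, `1/i^2` and `i^2`
#'     weights}
#'   \item{LISZE, HISZE, LILZE, HILZE}{the four intensity x size crossed
#'     emphases}
#'   \item{GLN, ZSN}{gray-level and zone-size non-uniformity}
#'   \item{ZP}{zone percentage `N_z / N_p`}
#' }
#'
#' @param z a [glszm_matrix()] result.
#' @return named numeric vector of the 11 features.
#' @export
glszm_features <- function(z) {
  stopifnot(inherits(z, "glszm"))
  P <- z$counts
  nz <- z$n_zones
  if (nz < 1) stop("no zones")
  i <- row(P)
  j <- col(P)
  c(SZE = sum(P / j^2) / nz,
    LZE = sum(P * j^2) / nz,
    LIZE = sum(P / i^2) / nz,
    HIZE = sum(P * i^2) / nz,
    LISZE = sum(P / (i^2 * j^2)) / nz,
    HISZE = sum(P * i^2 / j^2) / nz,
    LILZE = sum(P * j^2 / i^2) / nz,
    HILZE = sum(P * i^2 * j^2) / nz,
    GLN = sum(rowSums(P)^2) / nz,
    ZSN = sum(colSums(P)^2) / nz,
    ZP = nz / z$n_voxels)
}

#' Feature dictionary
#'
#' Names and defining formulas of every feature the extractor emits, for the
#' run report.
#'
#' @return data frame with columns `feature`, `family`, `formula`.
#' @export
feature_dictionary <- function() {
  rbind(
    data.frame(feature = c("solidity", "extent", "eccentricity"),
               family = "shape",
               formula = c(
                 "n_foreground / n_voxel_centers_in_convex_hull",
                 "n_foreground / n_bounding_box_voxels",
                 "sqrt(1 - lambda_min/lambda_max) of spacing-scaled covariance")),
    data.frame(feature = c("minimum", "median", "mean", "variance",
                           "skewness", "kurtosis"),
               family = "histogram",
               formula = c("min(x)", "median(x)", "mean(x)",
                           "m2 (population)", "m3/m2^1.5",
                           "m4/m2^2 (Pearson, normal = 3)")),
    data.frame(feature = c("energy", "entropy", "homogeneity", "contrast"),
               family = "glcm",
               formula = c("sum p^2", "-sum p log2 p",
                           "sum p/(1+|i-j|)", "sum p (i-j)^2")),
    data.frame(feature = c("SZE", "LZE", "LIZE", "HIZE", "LISZE", "HISZE",
                           "LILZE", "HILZE", "GLN", "ZSN", "ZP"),
               family = "glszm",
               formula = c("sum P/j^2 / Nz", "sum P j^2 / Nz",
                           "sum P/i^2 / Nz", "sum P i^2 / Nz",
                           "sum P/(i^2 j^2) / Nz", "sum P i^2/j^2 / Nz",
                           "sum P j^2/i^2 / Nz", "sum P i^2 j^2 / Nz",
                           "sum_i (sum_j P)^2 / Nz", "sum_j (sum_i P)^2 / Nz",
                           "Nz / Np")))
}
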