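# Independent brute-force oracles and small fixtures shared by the tests.
# These deliberately use naive enumeration, never the package's own
# vectorized code paths.

# Voxelized ball centered on a half-integer grid point (so the bounding box
# is 2r voxels wide and the sphere-in-cube ratio pi/6 applies).
ball_mask <- function(radius, n = 2 * (radius + 1)) {
  ctr <- (n + 1) / 2  # half-integer for even n
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  array(sqrt(rowSums(sweep(co, 2, ctr)^2)) <= radius, c(n, n, n))
}

# Voxelized ellipsoid with given semi-axes (integer-centered odd grid).
ellipsoid_mask <- function(radii, margin = 2) {
  n <- 2 * ceiling(radii) + 1 + 2 * margin
  ctr <- (n + 1) / 2
  co <- as.matrix(expand.grid(1:n[1], 1:n[2], 1:n[3]))
  u <- sweep(sweep(co, 2, ctr), 2, radii, `/`)
  array(rowSums(u^2) <= 1, n)
}

# Is point p inside the convex hull of rows of S? Brute force via
# Caratheodory: p is in the hull iff it lies in some tetrahedron of 4 points
# of S (barycentric coordinates all >= 0). O(n^4) - tiny inputs only.
point_in_hull_bruteforce <- function(p, S) {
  n <- nrow(S)
  combs <- utils::combn(n, 4)
  for (c_i in seq_len(ncol(combs))) {
    V <- S[combs[, c_i], , drop = FALSE]
    A <- rbind(t(V), rep(1, 4))
    b <- c(p, 1)
    lam <- tryCatch(solve(A, b), error = function(e) NULL)
    if (!is.null(lam) && all(lam >= -1e-9)) return(TRUE)
  }
  FALSE
}

# GLCM by explicit enumeration: for every voxel and every one of the 13
# direction offsets (times distance), count the symmetric level pair if both
# ends are in the mask.
glcm_bruteforce <- function(lev, L, distance = 1) {
  dims <- dim(lev)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[apply(offs, 1, function(o) {
    nz <- which(o != 0); length(nz) > 0 && o[nz[1]] > 0
  }), , drop = FALSE] * distance
  cnt <- matrix(0, L, L)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    i <- lev[x, y, z]
    if (i == 0) next
    for (r in seq_len(nrow(offs))) {
      xx <- x + offs[r, 1]; yy <- y + offs[r, 2]; zz <- z + offs[r, 3]
      if (xx < 1 || xx > dims[1] || yy < 1 || yy > dims[2] ||
          zz < 1 || zz > dims[3]) next
      j <- lev[xx, yy, zz]
      if (j == 0) next
      cnt[i, j] <- cnt[i, j] + 1
      cnt[j, i] <- cnt[j, i] + 1
    }
  }
  cnt
}

# GLSZM by breadth-first flood fill over equal-level neighbors.
glszm_bruteforce <- function(lev, L, connectivity = 26) {
  dims <- dim(lev)
  seen <- array(FALSE, dims)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, , drop = FALSE]
  if (connectivity == 6) nb <- nb[rowSums(abs(nb)) == 1, , drop = FALSE]
  zones <- list()
  for (start in which(lev > 0)) {
    if (seen[start]) next
    lv <- lev[start]
    queue <- start
    seen[start] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      size <- size + 1
      cc <- arrayInd(cur, dims)
      for (r in seq_len(nrow(nb))) {
        q <- cc + nb[r, ]
        if (any(q < 1) || any(q > dims)) next
        ql <- q[1] + (q[2] - 1) * dims[1] + (q[3] - 1) * dims[1] * dims[2]
        if (!seen[ql] && lev[ql] == lv) {
          seen[ql] <- TRUE
          queue <- c(queue, ql)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = lv, size = size)
  }
  m <- do.call(rbind, zones)
  counts <- matrix(0, L, max(m[, "size"]))
  for (r in seq_len(nrow(m)))
    counts[m[r, "level"], m[r, "size"]] <- counts[m[r, "level"], m[r, "size"]] + 1
  counts
}

# BW-ratio by naive double loop over samples and classes.
bw_bruteforce <- function(X, y) {
  vapply(seq_len(ncol(X)), function(j) {
    xb <- mean(X[, j])
    between <- 0; within <- 0
    for (i in seq_len(nrow(X))) {
      for (k in unique(y)) {
        if (y[i] == k) {
          xkb <- mean(X[y == k, j])
          between <- between + (xkb - xb)^2
          within <- within + (X[i, j] - xkb)^2
        }
      }
    }
    between / within
  }, numeric(1))
}

# Random quantized test volume with a random mask.
random_quantized <- function(dims, L, seed, p_mask = 0.8) {
  set.seed(seed)
  lev <- array(sample(0:L, prod(dims), replace = TRUE,
                      prob = c(1 - p_mask, rep(p_mask / L, L))),
               dims)
  lev
}

as_quantized_roi <- function(lev, L) {
  structure(list(levels = lev, n_levels = L, bin_edges = seq(0, 1, length.out = L + 1)),
            class = "quantized_roi")
}
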