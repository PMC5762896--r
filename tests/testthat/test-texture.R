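# Quantization, GLCM and GLSZM.

test_that("quantization maps the ROI range onto 1..L as specified", {
  v <- array(0, c(4, 4, 1)); v[1:16] <- 0:15
  m <- array(TRUE, c(4, 4, 1))
  q <- quantize_roi(v, m, 16)
  expect_identical(sort(unique(q$levels[m])), 1:16)

  # edges at 1.5 for {0,1,2,3} with L = 2
  v2 <- array(c(0, 1, 2, 3), c(1, 1, 4)); m2 <- array(TRUE, c(1, 1, 4))
  q2 <- quantize_roi(v2, m2, 2)
  expect_identical(as.integer(q2$levels[m2]), c(1L, 1L, 2L, 2L))

  # constant ROI -> all level 1
  q3 <- quantize_roi(array(5, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 16)
  expect_true(all(q3$levels == 1L))

  # monotone: v1 <= v2 => level1 <= level2; min -> 1, max -> L
  set.seed(41)
  v4 <- array(rnorm(60), c(5, 4, 3)); m4 <- array(runif(60) < 0.7, c(5, 4, 3))
  m4[1] <- TRUE
  q4 <- quantize_roi(v4, m4, 16)
  ord <- order(v4[m4])
  expect_true(all(diff(q4$levels[m4][ord]) >= 0))
  expect_identical(min(q4$levels[m4]), 1L)
  expect_identical(max(q4$levels[m4]), 16L)
  expect_true(all(q4$levels[!m4] == 0L))
})

test_that("GLCM matches hand-enumerated examples", {
  # constant 2x2x2 ROI: all mass on (1,1)
  q <- quantize_roi(array(3, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 16)
  g <- glcm_matrix(q)
  expect_equal(g$p[1, 1], 1)
  expect_equal(sum(g$p), 1)

  # 1x1x4 strip 1,2,1,2: 3 adjacent discordant pairs, symmetrized
  v <- array(c(1, 2, 1, 2), c(1, 1, 4)); m <- array(TRUE, c(1, 1, 4))
  q2 <- quantize_roi(v, m, 2)
  g2 <- glcm_matrix(q2)
  expect_equal(g2$p, matrix(c(0, 0.5, 0.5, 0), 2), ignore_attr = TRUE)
})

test_that("GLCM equals the pair-enumeration oracle on random arrays", {
  for (rep in 1:40) {
    dims <- c(sample(2:6, 1), sample(2:6, 1), sample(2:5, 1))
    L <- sample(2:6, 1)
    lev <- random_quantized(dims, L, seed = 500 + rep)
    q <- as_quantized_roi(lev, L)
    want <- glcm_bruteforce(lev, L)
    if (sum(want) == 0) {
      expect_error(glcm_matrix(q), "no in-mask")
      next
    }
    got <- glcm_matrix(q)
    expect_equal(got$p, want / sum(want), tolerance = 1e-12)
    # symmetry + normalization invariants
    expect_equal(got$p, t(got$p), tolerance = 1e-12)
    expect_equal(sum(got$p), 1, tolerance = 1e-9)
    # invariance under axis relabeling
    qp <- as_quantized_roi(aperm(lev, c(3, 1, 2)), L)
    expect_equal(glcm_matrix(qp)$p, got$p, tolerance = 1e-12)
  }
})

test_that("GLCM features match closed forms", {
  diag1 <- structure(list(p = diag(c(1, 0)), offsets_used = NULL), class = "glcm")
  f <- glcm_features(diag1)
  expect_equal(unname(f), c(1, 0, 1, 0))

  off <- structure(list(p = matrix(c(0, 0.5, 0.5, 0), 2), offsets_used = NULL),
                   class = "glcm")
  f2 <- glcm_features(off)
  expect_equal(f2[["energy"]], 0.5)
  expect_equal(f2[["entropy"]], 1)
  expect_equal(f2[["homogeneity"]], 0.5)
  expect_equal(f2[["contrast"]], 1)

  unif <- structure(list(p = matrix(1 / 256, 16, 16), offsets_used = NULL),
                    class = "glcm")
  expect_equal(glcm_features(unif)[["entropy"]], 8)
})

test_that("GLSZM matches hand examples and the flood-fill oracle", {
  # constant ROI of 8 voxels: one zone of size 8
  q <- quantize_roi(array(1, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 16)
  z <- glszm_matrix(q)
  expect_equal(z$n_zones, 1)
  expect_equal(z$counts[1, 8], 1)

  # strip 1,1,2,2: two runs of two
  v <- array(c(1, 1, 2, 2), c(1, 1, 4)); m <- array(TRUE, c(1, 1, 4))
  z2 <- glszm_matrix(quantize_roi(v, m, 2))
  expect_equal(z2$counts[1, 2], 1)
  expect_equal(z2$counts[2, 2], 1)
  expect_equal(z2$n_zones, 2)

  for (rep in 1:40) {
    dims <- c(sample(2:6, 1), sample(2:6, 1), sample(2:5, 1))
    L <- sample(2:6, 1)
    lev <- random_quantized(dims, L, seed = 700 + rep)
    if (sum(lev > 0) == 0) next
    q3 <- as_quantized_roi(lev, L)
    for (conn in c(26, 6)) {
      got <- glszm_matrix(q3, connectivity = conn)
      want <- glszm_bruteforce(lev, L, conn)
      expect_equal(got$counts[, seq_len(ncol(want)), drop = FALSE], want,
                   ignore_attr = TRUE)
      # conservation: every voxel in exactly one zone
      expect_equal(sum(got$counts %*% seq_len(ncol(got$counts))),
                   sum(lev > 0))
      expect_equal(sum(got$counts), got$n_zones)
    }
  }
})

test_that("GLSZM features match closed forms", {
  # single zone, level 1, size 8
  z <- structure(list(counts = matrix(c(rep(0, 7), 1), 1, 8), n_zones = 1,
                      n_voxels = 8), class = "glszm")
  f <- glszm_features(z)
  expect_equal(f[["LZE"]], 64)
  expect_equal(f[["SZE"]], 1 / 64)
  expect_equal(f[["ZP"]], 1 / 8)
  expect_equal(f[["HILZE"]], 64)

  # two zones: (level 1, size 2), (level 2, size 2)
  cnt <- matrix(0, 2, 2); cnt[1, 2] <- 1; cnt[2, 2] <- 1
  z2 <- structure(list(counts = cnt, n_zones = 2, n_voxels = 4),
                  class = "glszm")
  f2 <- glszm_features(z2)
  expect_equal(f2[["GLN"]], 1)
  expect_equal(f2[["ZSN"]], 2)
  expect_equal(f2[["LIZE"]], 0.625)

  # all singleton zones
  cnt3 <- matrix(c(3, 2), 2, 1)  # 5 voxels, 5 zones, sizes 1
  z3 <- structure(list(counts = cnt3, n_zones = 5, n_voxels = 5),
                  class = "glszm")
  f3 <- glszm_features(z3)
  expect_equal(f3[["SZE"]], 1)
  expect_equal(f3[["LZE"]], 1)
  expect_equal(f3[["ZP"]], 1)
})

test_that("longer intensity correlation length increases large-zone emphasis", {
  mask <- ball_mask(8)
  lze <- function(sigma, seed) {
    p <- class_params(texture_corr_length = sigma)
    v <- generate_series(mask, p, seed = seed)$post1
    glszm_features(glszm_matrix(quantize_roi(v, mask)))[["LZE"]]
  }
  short <- vapply(1:5, function(s) lze(0.6, s), numeric(1))
  long <- vapply(1:5, function(s) lze(2.2, 100 + s), numeric(1))
  expect_gt(mean(long), mean(short))
})
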