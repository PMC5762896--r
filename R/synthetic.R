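# Synthetic phantom cohort: labeled lesion volumes (one pre-contrast + three
# post-contrast timepoints) whose two classes differ in shape convexity and in
# intensity-histogram skewness, emulating the statistical structure of a
# re-excision vs no-re-excision breast-MRI cohort.

#' Per-class phantom parameters
#'
#' Parameters of one lesion class for the phantom generator.
#'
#' @param solidity_target intended mean solidity of the class (documentation
#'   anchor for the preset calibration; the achieved solidity is driven by
#'   `irregularity`).
#' @param irregularity non-negative amplitude scale of the random radial
#'   surface bumps; 0 gives an exact ellipsoid, larger values give more
#'   concave, less solid lesions.
#' @param skew_shape skew-normal shape parameter of the intensity noise;
#'   positive values give right-skewed in-mask histograms.
#' @param enhancement_curve multiplicative contrast-enhancement factors for
#'   (pre, post1, post2, post3); post1 must enhance over pre.
#' @param texture_corr_length Gaussian smoothing sigma (voxels) of the
#'   intensity noise field; larger values give larger same-level zones.
#' @param base_radii ellipsoid semi-axes in voxels (all >= 2).
#' @return object of class `class_params`.
#' @export
class_params <- function(solidity_target = 0.9,
                         irregularity = 0.1,
                         skew_shape = 0,
                         enhancement_curve = c(1, 2.2, 2.0, 1.8),
                         texture_corr_length = 1.5,
                         base_radii = c(9, 8, 7)) {
  stopifnot(solidity_target > 0, solidity_target <= 1,
            irregularity >= 0,
            length(enhancement_curve) == 4,
            texture_corr_length > 0,
            length(base_radii) == 3, all(base_radii >= 2))
  if (!(enhancement_curve[1] < enhancement_curve[2]))
    stop("post-contrast 1 must enhance over pre-contrast")
  structure(list(solidity_target = solidity_target,
                 irregularity = irregularity,
                 skew_shape = skew_shape,
                 enhancement_curve = enhancement_curve,
                 texture_corr_length = texture_corr_length,
                 base_radii = base_radii),
            class = "class_params")
}

#' Calibrated class presets
#'
#' Default parameter sets for the two outcome classes, calibrated so the
#' achieved shape statistics match the exemplar operating range of resected
#' vs re-excised lesions: the no-re-excision class is a near-convex, compact,
#' left-skewed lesion (mean solidity near 0.94, extent near 0.55); the
#' re-excision class is more irregular, more eccentric and right-skewed with
#' coarser intensity zones (mean solidity near 0.80, extent near 0.41).
#'
#' @param class `"no_reexcision"` (label 0) or `"reexcision"` (label 1).
#' @return a [class_params()] object.
#' @export
preset_class_params <- function(class = c("no_reexcision", "reexcision")) {
  class <- match.arg(class)
  if (class == "no_reexcision") {
    class_params(solidity_target = 0.94,
                 irregularity = 0.20,
                 skew_shape = -4,
                 enhancement_curve = c(1, 2.2, 2.0, 1.8),
                 texture_corr_length = 1.2,
                 base_radii = c(9, 8, 7))
  } else {
    class_params(solidity_target = 0.80,
                 irregularity = 0.52,
                 skew_shape = 4,
                 enhancement_curve = c(1, 2.3, 2.1, 1.9),
                 texture_corr_length = 1.8,
                 base_radii = c(10, 8, 6))
  }
}

#' Cohort specification
#'
#' @param n_per_class lesions per class (>= 2; leave-one-out cross-validation
#'   needs both classes in every training fold).
#' @param class0,class1 [class_params()] for the no-re-excision (label 0) and
#'   re-excision (label 1) classes.
#' @param grid_shape voxel counts per axis.
#' @param spacing voxel spacing in mm per axis.
#' @param seed master seed; per-lesion substreams are derived from it by a
#'   counter scheme (`seed * 1e5 + 2 * lesion_index` for the mask stream and
#'   `+ 1` for the intensity stream), so enlarging a cohort never reshuffles
#'   existing lesions.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 50,
                        class0 = preset_class_params("no_reexcision"),
                        class1 = preset_class_params("reexcision"),
                        grid_shape = c(36, 36, 36),
                        spacing = c(1, 1, 1),
                        seed = 1L) {
  stopifnot(n_per_class >= 2, inherits(class0, "class_params"),
            inherits(class1, "class_params"),
            length(grid_shape) == 3, all(grid_shape >= 8),
            length(spacing) == 3, all(spacing > 0))
  for (p in list(class0, class1)) .check_fits(p, grid_shape)
  structure(list(n_per_class = as.integer(n_per_class),
                 class0 = class0, class1 = class1,
                 grid_shape = as.integer(grid_shape),
                 spacing = spacing, seed = as.integer(seed)),
            class = "cohort_spec")
}

.check_fits <- function(params, grid_shape) {
  center <- (grid_shape + 1) / 2
  if (any(center + params$base_radii + 1 > grid_shape) ||
      any(center - params$base_radii - 1 < 1))
    stop("lesion exceeds grid bounds: base radii do not fit with a 1-voxel margin")
  invisible(TRUE)
}

.lesion_seed <- function(master, lesion_index, stream = 0L) {
  as.integer((as.double(master) * 1e5 + 2 * lesion_index + stream) %%
               .Machine$integer.max)
}

#' Generate a phantom tumor mask
#'
#' Voxelizes a superellipsoid body (p = 3 norm, which fills its bounding box
#' the way compact breast lesions do, extent near 0.72 when unperturbed)
#' whose radius field is carved by `K = 16` random inward surface Gaussian
#' bumps with amplitudes proportional to `irregularity`; larger amplitudes
#' cut deeper concavities, monotonically lowering the expected solidity
#' without inflating the bounding box. If the perturbation fragments the
#' mask, the largest 26-connected component is kept so every volume holds
#' exactly one lesion.
#'
#' @param params a [class_params()] object.
#' @param grid_shape voxel counts per axis.
#' @param seed integer seed; the mask is a pure function of
#'   `(params, grid_shape, seed)`.
#' @return logical 3D array.
#' @export
generate_mask <- function(params, grid_shape = c(36, 36, 36), seed = 1L) {
  stopifnot(inherits(params, "class_params"))
  grid_shape <- as.integer(grid_shape)
  .check_fits(params, grid_shape)
  withr::with_seed(seed, {
    K <- 16L
    dirs <- matrix(stats::rnorm(3L * K), ncol = K)
    dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), `/`)
    widths <- stats::runif(K, 0.15, 0.35)
    amps <- -params$irregularity * stats::runif(K, 0.8, 1.6)

    center <- (grid_shape + 1) / 2
    co <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                                y = seq_len(grid_shape[2]),
                                z = seq_len(grid_shape[3])))
    u <- sweep(sweep(co, 2, center, `-`), 2, params$base_radii, `/`)
    r <- rowSums(abs(u)^3)^(1 / 3)            # p = 3 superellipsoid radius
    re <- sqrt(rowSums(u^2))
    d <- u / pmax(re, 1e-12)
    cosang <- d %*% dirs
    cosang[cosang > 1] <- 1
    cosang[cosang < -1] <- -1
    theta <- acos(cosang)
    bump <- exp(-sweep(theta^2, 2, 2 * widths^2, `/`)) %*% amps
    inside <- r <= pmax(0.2, 1 + bump)
  })
  mask <- array(inside, grid_shape)
  idx <- which(mask)
  lab <- label_components(idx, grid_shape, connectivity = 26)
  keep <- idx[lab == which.max(tabulate(lab))]
  mask[] <- FALSE
  mask[keep] <- TRUE
  co <- arrayInd(which(mask), grid_shape)
  if (any(co == 1L) || any(sweep(co, 2, grid_shape, `==`)))
    stop("lesion exceeds grid bounds: mask touches the grid boundary")
  mask
}

# Skew-normal deviates by the delta construction:
# Z = delta |U0| + sqrt(1 - delta^2) U1, delta = alpha / sqrt(1 + alpha^2).
rskewnorm <- function(n, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  delta * abs(stats::rnorm(n)) + sqrt(1 - delta^2) * stats::rnorm(n)
}

# Separable 3D Gaussian smoothing with edge replication.
gaussian_smooth_3d <- function(x, sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  dims <- dim(x)
  for (axis in 1:3) {
    n <- dims[axis]
    out <- array(0, dims)
    for (t in seq_along(k)) {
      sh <- pmin(n, pmax(1L, seq_len(n) + (t - r - 1L)))
      out <- out + k[t] * switch(axis,
                                 x[sh, , , drop = FALSE],
                                 x[, sh, , drop = FALSE],
                                 x[, , sh, drop = FALSE])
    }
    x <- out
  }
  x
}

#' Generate the four-timepoint intensity series of a lesion
#'
#' Each timepoint gets an independent spatially correlated skew-normal noise
#' field: two i.i.d. standard-normal fields are smoothed with a Gaussian
#' kernel of width `texture_corr_length` (this spatial correlation is what
#' creates non-singleton size zones), standardized, and combined by the
#' skew-normal delta construction
#' `f = delta |g0| + sqrt(1 - delta^2) g1`, `delta = a / sqrt(1 + a^2)` with
#' `a = skew_shape` — so every voxel's marginal is exactly skew-normal with
#' shape `a` (smoothing first, skewing second: smoothing *after* skewing
#' would average the third moment away). The field is standardized and
#' mapped affinely to `enhancement_curve[t] * (100 + 20 * f)` inside the
#' mask; outside, voxels carry low-level non-negative background noise.
#' In-mask sample skewness increases with `skew_shape` and is 0 in
#' expectation at `skew_shape = 0`.
#'
#' @param mask logical 3D array from [generate_mask()] (must be nonempty).
#' @param params a [class_params()] object.
#' @param seed integer seed.
#' @return named list of four 3D arrays: `pre`, `post1`, `post2`, `post3`.
#' @export
generate_series <- function(mask, params, seed = 1L) {
  stopifnot(inherits(params, "class_params"))
  m <- .check_mask(mask)
  dims <- dim(m)
  tags <- c("pre", "post1", "post2", "post3")
  withr::with_seed(seed, {
    vols <- lapply(seq_along(tags), function(t) {
      std <- function(x) (x - mean(x)) / stats::sd(x)
      g0 <- std(gaussian_smooth_3d(array(stats::rnorm(prod(dims)), dims),
                                   params$texture_corr_length))
      g1 <- std(gaussian_smooth_3d(array(stats::rnorm(prod(dims)), dims),
                                   params$texture_corr_length))
      delta <- params$skew_shape / sqrt(1 + params$skew_shape^2)
      f <- std(delta * abs(g0) + sqrt(1 - delta^2) * g1)
      v <- array(pmax(0, stats::rnorm(prod(dims), 5, 2)), dims)
      v[m] <- params$enhancement_curve[t] * (100 + 20 * f[m])
      v
    })
  })
  names(vols) <- tags
  vols
}

#' Generate one lesion in memory
#'
#' Convenience wrapper pairing [generate_mask()] and [generate_series()] with
#' the cohort's per-lesion seed streams.
#'
#' @param params a [class_params()] object.
#' @param grid_shape voxel counts per axis.
#' @param mask_seed,series_seed integer seeds for the two stages.
#' @return list with `mask` (logical array) and `volumes` (list of 4 arrays).
#' @export
simulate_lesion <- function(params, grid_shape = c(36, 36, 36),
                            mask_seed = 1L, series_seed = 2L) {
  mask <- generate_mask(params, grid_shape, mask_seed)
  list(mask = mask, volumes = generate_series(mask, params, series_seed))
}

#' Write a synthetic cohort to disk
#'
#' Generates `2 * n_per_class` labeled lesions (class 0 = no re-excision,
#' class 1 = re-excision), writes each volume and mask as NIfTI (`.nii.gz`,
#' voxel spacing in the header) and returns the manifest, also written as
#' `manifest.csv`. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()] object.
#' @param dir output directory (created if needed).
#' @return data frame manifest with columns `lesion_id`, `pre_path`,
#'   `post1_path`, `post2_path`, `post3_path`, `mask_path`, `label`.
#' @export
generate_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  rows <- vector("list", 2L * spec$n_per_class)
  for (i in seq_len(2L * spec$n_per_class)) {
    label <- if (i <= spec$n_per_class) 0L else 1L
    params <- if (label == 0L) spec$class0 else spec$class1
    id <- sprintf("lesion%03d", i)
    les <- simulate_lesion(params, spec$grid_shape,
                           mask_seed = .lesion_seed(spec$seed, i, 0L),
                           series_seed = .lesion_seed(spec$seed, i, 1L))
    paths <- c(pre_path = file.path(dir, paste0(id, "_pre.nii.gz")),
               post1_path = file.path(dir, paste0(id, "_post1.nii.gz")),
               post2_path = file.path(dir, paste0(id, "_post2.nii.gz")),
               post3_path = file.path(dir, paste0(id, "_post3.nii.gz")),
               mask_path = file.path(dir, paste0(id, "_mask.nii.gz")))
    for (t in 1:4) .write_nifti(les$volumes[[t]], spec$spacing, paths[t])
    .write_nifti(les$mask * 1L, spec$spacing, paths[5])
    rows[[i]] <- data.frame(lesion_id = id, t(paths), label = label,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}

.write_nifti <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop("failed to write NIfTI file: ", path)
  invisible(path)
}
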