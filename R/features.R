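# Lesion-level feature extraction: one row of named features per lesion,
# pooled over the four contrast timepoints.

.scan_tags <- c("pre", "post1", "post2", "post3")

#' Extract all features of one lesion
#'
#' Computes the full feature vector of a lesion from its four timepoint
#' volumes and the shared tumor mask: 3 shape features (mask only, reported
#' under the `pre` tag since one contour is mapped to all sequences),
#' 6 histogram features per scan, 4 GLCM features per scan and 11 GLSZM
#' features per scan — 87 features with default settings. Texture features
#' are computed on intensities quantized to `levels` gray levels within the
#' ROI of each scan.
#'
#' @param volumes named list of four 3D arrays (`pre`, `post1`, `post2`,
#'   `post3`).
#' @param mask logical 3D array, shared across timepoints.
#' @param spacing voxel spacing in mm.
#' @param levels quantization levels (default 16).
#' @param glcm_distance co-occurrence offset length in voxels.
#' @param glszm_connectivity 26 or 6.
#' @param families which feature families to compute; any subset of
#'   `c("shape", "histogram", "glcm", "glszm")`.
#' @return named numeric vector, names like `pre.solidity`, `post2.LZE`.
#' @export
extract_lesion_features <- function(volumes, mask, spacing = c(1, 1, 1),
                                    levels = 16L, glcm_distance = 1L,
                                    glszm_connectivity = 26,
                                    families = c("shape", "histogram",
                                                 "glcm", "glszm")) {
  stopifnot(is.list(volumes), all(.scan_tags %in% names(volumes)))
  families <- match.arg(families, several.ok = TRUE)
  out <- numeric(0)
  if ("shape" %in% families) {
    out <- c(out,
             pre.solidity = roi_solidity(mask),
             pre.extent = roi_extent(mask),
             pre.eccentricity = roi_eccentricity(mask, spacing))
  }
  for (tag in .scan_tags) {
    v <- volumes[[tag]]
    if (!identical(dim(v), dim(mask)))
      stop("volume/mask shape mismatch for scan ", tag)
    if ("histogram" %in% families) {
      h <- roi_histogram(v, mask)
      names(h) <- paste(tag, names(h), sep = ".")
      out <- c(out, h)
    }
    if (any(c("glcm", "glszm") %in% families)) {
      q <- quantize_roi(v, mask, levels)
      if ("glcm" %in% families) {
        g <- glcm_features(glcm_matrix(q, distance = glcm_distance))
        names(g) <- paste(tag, names(g), sep = ".")
        out <- c(out, g)
      }
      if ("glszm" %in% families) {
        z <- glszm_features(glszm_matrix(q, connectivity = glszm_connectivity))
        names(z) <- paste(tag, names(z), sep = ".")
        out <- c(out, z)
      }
    }
  }
  out
}

#' Extract the feature table of a cohort on disk
#'
#' Reads each manifest row's NIfTI volumes and mask and extracts the lesion's
#' feature vector. Lesions whose extraction fails (for example a degenerate
#' mask, or a volume/mask shape mismatch) are skipped with a warning and
#' reported in the `errors` attribute; they are never silently imputed.
#'
#' @param manifest data frame from [generate_cohort()] (or the path of a
#'   `manifest.csv` with the same columns).
#' @inheritParams extract_lesion_features
#' @return data frame: `lesion_id`, `label`, then one column per feature.
#'   Attribute `errors` holds a named character vector of skipped lesions.
#' @export
extract_features <- function(manifest, levels = 16L, glcm_distance = 1L,
                             glszm_connectivity = 26,
                             families = c("shape", "histogram",
                                          "glcm", "glszm")) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("lesion_id", paste0(.scan_tags, "_path"), "mask_path", "label")
  if (!all(need %in% names(manifest)))
    stop("manifest lacks required columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  rows <- list()
  errs <- character(0)
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      mask_img <- RNifti::readNifti(manifest$mask_path[i])
      spacing <- RNifti::pixdim(mask_img)[1:3]
      mask <- array(as.array(mask_img) != 0, dim(mask_img))
      vols <- lapply(.scan_tags, function(tag) {
        a <- RNifti::readNifti(manifest[[paste0(tag, "_path")]][i])
        array(as.numeric(a), dim(a))
      })
      names(vols) <- .scan_tags
      extract_lesion_features(vols, mask, spacing, levels, glcm_distance,
                              glszm_connectivity, families)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[manifest$lesion_id[i]] <- conditionMessage(res)
      warning("skipping lesion ", manifest$lesion_id[i], ": ",
              conditionMessage(res))
    } else {
      rows[[manifest$lesion_id[i]]] <- res
    }
  }
  feat <- do.call(rbind, rows)
  out <- data.frame(lesion_id = names(rows),
                    label = manifest$label[match(names(rows),
                                                 manifest$lesion_id)],
                    feat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "errors") <- errs
  out
}

#' Simulate a cohort and extract its features in memory
#'
#' Equivalent to [generate_cohort()] followed by [extract_features()] but
#' without touching disk; used for simulation studies where only the feature
#' table matters.
#'
#' @param spec a [cohort_spec()] object.
#' @inheritParams extract_lesion_features
#' @return data frame as in [extract_features()].
#' @export
simulate_cohort_features <- function(spec, levels = 16L, glcm_distance = 1L,
                                     glszm_connectivity = 26,
                                     families = c("shape", "histogram",
                                                  "glcm", "glszm")) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- 2L * spec$n_per_class
  rows <- vector("list", n)
  labels <- integer(n)
  for (i in seq_len(n)) {
    label <- if (i <= spec$n_per_class) 0L else 1L
    params <- if (label == 0L) spec$class0 else spec$class1
    les <- simulate_lesion(params, spec$grid_shape,
                           mask_seed = .lesion_seed(spec$seed, i, 0L),
                           series_seed = .lesion_seed(spec$seed, i, 1L))
    rows[[i]] <- extract_lesion_features(les$volumes, les$mask, spec$spacing,
                                         levels, glcm_distance,
                                         glszm_connectivity, families)
    labels[i] <- label
  }
  out <- data.frame(lesion_id = sprintf("lesion%03d", seq_len(n)),
                    label = labels, do.call(rbind, rows),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
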