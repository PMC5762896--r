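# Pipeline orchestration: one validated configuration object drives the
# simulate -> extract -> analyze stages, so every silent convention
# (quantization, connectivity, kurtosis definition, SVM settings) is pinned
# per run and recorded next to the outputs.

.config_keys <- c("output_dir", "manifest", "n_per_class", "grid_shape",
                  "spacing", "levels", "glcm_distance", "glszm_connectivity",
                  "svm_C", "svm_gamma", "max_k", "standardize", "seed",
                  "verbose")

#' Pipeline run configuration
#'
#' Builds, validates and (de)serializes the single configuration object used
#' by [run_simulate()], [run_extract()] and [run_analyze()]. Unknown keys are
#' rejected rather than ignored.
#'
#' @param output_dir directory for all outputs.
#' @param manifest path of the cohort manifest CSV (defaults to
#'   `output_dir/cohort/manifest.csv`, where [run_simulate()] writes it).
#' @param n_per_class lesions per class for simulation.
#' @param grid_shape,spacing phantom grid geometry.
#' @param levels quantization levels.
#' @param glcm_distance co-occurrence offset length.
#' @param glszm_connectivity 26 or 6.
#' @param svm_C,svm_gamma,max_k,standardize classifier settings, see
#'   [svm_config()].
#' @param seed master seed.
#' @param verbose log one line per lesion and stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(output_dir = "bcsradiomics_run",
                       manifest = NULL,
                       n_per_class = 50L,
                       grid_shape = c(36L, 36L, 36L),
                       spacing = c(1, 1, 1),
                       levels = 16L,
                       glcm_distance = 1L,
                       glszm_connectivity = 26L,
                       svm_C = 1000,
                       svm_gamma = 0.005,
                       max_k = 30L,
                       standardize = TRUE,
                       seed = 1L,
                       verbose = TRUE) {
  if (is.null(manifest))
    manifest <- file.path(output_dir, "cohort", "manifest.csv")
  cfg <- list(output_dir = output_dir, manifest = manifest,
              n_per_class = as.integer(n_per_class),
              grid_shape = as.integer(grid_shape), spacing = spacing,
              levels = as.integer(levels),
              glcm_distance = as.integer(glcm_distance),
              glszm_connectivity = as.integer(glszm_connectivity),
              svm_C = svm_C, svm_gamma = svm_gamma,
              max_k = as.integer(max_k), standardize = isTRUE(standardize),
              seed = as.integer(seed), verbose = isTRUE(verbose))
  if (cfg$n_per_class < 2)
    stop("n_per_class must be >= 2 (leave-one-out needs both classes in every fold)")
  stopifnot(cfg$levels >= 2, cfg$glcm_distance >= 1,
            cfg$glszm_connectivity %in% c(6L, 26L),
            cfg$svm_C > 0, cfg$svm_gamma > 0, cfg$max_k >= 1)
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration file
#'
#' YAML round-trip of a [run_config()]. Reading re-validates and rejects
#' unknown keys.
#'
#' @param path YAML file path.
#' @param config a `run_config` (for writing).
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.log <- function(config, ...) {
  if (isTRUE(config$verbose))
    message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  invisible(NULL)
}

#' Run the simulation stage
#'
#' Generates the synthetic cohort under `output_dir/cohort/` (NIfTI volumes,
#' masks, `manifest.csv`) with the calibrated class presets, and records the
#' exact configuration used as `output_dir/run_config.yaml`.
#'
#' @param config a [run_config()].
#' @return the manifest data frame, invisibly.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$output_dir))
    stop("unwritable output directory: ", config$output_dir)
  write_run_config(config, file.path(config$output_dir, "run_config.yaml"))
  spec <- cohort_spec(n_per_class = config$n_per_class,
                      grid_shape = config$grid_shape,
                      spacing = config$spacing, seed = config$seed)
  t0 <- Sys.time()
  manifest <- generate_cohort(spec, file.path(config$output_dir, "cohort"))
  .log(config, "simulate: wrote %d lesions in %.1f s", nrow(manifest),
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(manifest)
}

#' Run the feature-extraction stage
#'
#' Extracts the feature table from the cohort manifest and writes it as
#' `output_dir/features.csv`. Lesions that fail extraction are skipped and
#' logged (`extraction_errors.csv`), never imputed.
#'
#' @param config a [run_config()].
#' @return the feature table, invisibly.
#' @export
run_extract <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  features <- extract_features(config$manifest, levels = config$levels,
                               glcm_distance = config$glcm_distance,
                               glszm_connectivity = config$glszm_connectivity)
  utils::write.csv(features, file.path(config$output_dir, "features.csv"),
                   row.names = FALSE)
  errs <- attr(features, "errors")
  if (length(errs) > 0)
    utils::write.csv(data.frame(lesion_id = names(errs), error = errs),
                     file.path(config$output_dir, "extraction_errors.csv"),
                     row.names = FALSE)
  .log(config, "extract: %d lesions, %d features, %d skipped (%.1f s)",
       nrow(features), ncol(features) - 2L, length(errs),
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(features)
}

#' Run the analysis stage
#'
#' Univariate screen plus the LOOCV top-k SVM sweep on an extracted feature
#' table; writes the report bundle (see [write_report()]) into `output_dir`.
#'
#' @param config a [run_config()].
#' @param features feature table (default: read `output_dir/features.csv`).
#' @return the [loocv_sweep()] result, invisibly.
#' @export
run_analyze <- function(config, features = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(features)) {
    path <- file.path(config$output_dir, "features.csv")
    if (!file.exists(path)) stop("no feature table at ", path)
    features <- utils::read.csv(path, check.names = FALSE,
                                stringsAsFactors = FALSE)
  }
  if (!"label" %in% names(features)) stop("feature table lacks a label column")
  t0 <- Sys.time()
  univ <- univariate_screen(features)
  X <- as.matrix(features[, setdiff(names(features), c("lesion_id", "label"))])
  cv <- loocv_sweep(X, features$label,
                    svm_config(C = config$svm_C, gamma = config$svm_gamma,
                               max_k = config$max_k,
                               standardize = config$standardize))
  write_report(cv, univ, config$output_dir, seed = config$seed)
  .log(config, "analyze: best k = %d (accuracy %.3f) in %.1f s", cv$best_k,
       max(cv$curve$accuracy),
       as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(cv)
}
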