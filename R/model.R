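# Multivariate model: BW-ratio feature ranking recomputed inside each
# leave-one-out fold, RBF-kernel SVM classification, and the top-k sweep.

#' SVM / sweep configuration
#'
#' Hyperparameters of the classifier stage. The defaults are the published
#' operating configuration: soft-margin penalty `C = 1000`, RBF width
#' `gamma = 0.005`, and a sweep over the top `1..30` ranked features.
#' Standardization (z-scoring each feature with training-fold mean and sd) is
#' on by default: the RBF kernel at this gamma is scale-sensitive, so the
#' choice is material and explicit.
#'
#' @param C soft-margin penalty (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param max_k largest number of top-ranked features to use.
#' @param standardize z-score features per training fold.
#' @return object of class `svm_config`.
#' @export
svm_config <- function(C = 1000, gamma = 0.005, max_k = 30L,
                       standardize = TRUE) {
  stopifnot(C > 0, gamma > 0, max_k >= 1)
  structure(list(C = C, gamma = gamma, max_k = as.integer(max_k),
                 standardize = isTRUE(standardize)),
            class = "svm_config")
}

#' BW-ratio feature ranking
#'
#' Ranks features by the ratio of between-group to within-group sums of
#' squares. For feature `j` with class means `xbar_kj` and overall mean
#' `xbar_j`:
#' `BW(j) = sum_i sum_k 1(y_i = k) (xbar_kj - xbar_j)^2 /`
#' `        sum_i sum_k 1(y_i = k) (x_ij - xbar_kj)^2`.
#' A feature with zero within-group scatter but distinct class means
#' separates the classes perfectly; its ratio is `+Inf` and it ranks first
#' (with a message). Ties are broken deterministically by feature name.
#'
#' @param X numeric matrix or data frame, lesions x features.
#' @param y binary labels (0/1), both classes with >= 2 members.
#' @return data frame sorted by rank: `feature`, `bw`, `rank`.
#' @export
bw_ratio <- function(X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (min(table(y)) < 2) stop("each class needs at least 2 samples")
  overall <- colMeans(X)
  between <- 0
  within <- 0
  for (k in unique(y)) {
    Xk <- X[y == k, , drop = FALSE]
    mk <- colMeans(Xk)
    between <- between + nrow(Xk) * (mk - overall)^2
    within <- within + colSums(sweep(Xk, 2, mk)^2)
  }
  bw <- ifelse(within > 0, between / within,
               ifelse(between > 0, Inf, 0))
  if (any(is.infinite(bw)))
    message("feature(s) with zero within-group scatter ranked first: ",
            paste(colnames(X)[is.infinite(bw)], collapse = ", "))
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("f", seq_along(bw))
  ord <- order(-bw, nm)
  data.frame(feature = nm[ord], bw = unname(bw[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

.standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, `/`)
}

#' Leave-one-out cross-validated top-k SVM sweep
#'
#' For each held-out lesion, features are ranked by [bw_ratio()] on the
#' remaining `n - 1` lesions only (the held-out row never influences ranking
#' or standardization), and for every `k` up to `config$max_k` an RBF-kernel
#' SVM is trained on the training fold's top-`k` standardized features and
#' predicts the held-out lesion. Per-`k` accuracy, sensitivity (re-excision
#' lesions correctly classified) and specificity (no-re-excision lesions
#' correctly classified) are aggregated over all folds. The reported
#' `best_k` is the smallest `k` maximizing accuracy.
#'
#' The whole procedure is deterministic given the data and configuration.
#'
#' @param X numeric matrix or data frame, lesions x features (named columns).
#' @param y binary labels (0/1); n >= 4 with >= 2 lesions per class.
#' @param config an [svm_config()].
#' @return object of class `cv_result`: list with `curve` (data frame `k`,
#'   `accuracy`, `sensitivity`, `specificity` and Clopper-Pearson 95% CI
#'   bounds), `predictions` (n x max_k matrix), `fold_rankings` (list of
#'   per-fold [bw_ratio()] tables), `consensus` (features by mean rank across
#'   folds), `best_k`, and `config`.
#' @export
loocv_sweep <- function(X, y, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  stopifnot(n >= 4, length(y) == n)
  if (min(table(y)) < 2)
    stop("each class needs at least 2 members so every training fold keeps both")
  max_k <- min(config$max_k, ncol(X))
  preds <- matrix(NA_integer_, nrow = n, ncol = max_k)
  rankings <- vector("list", n)
  yf <- factor(y, levels = c(0L, 1L))

  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- yf[-i]
    rk <- bw_ratio(Xtr, y[-i])
    rankings[[i]] <- rk
    if (config$standardize) {
      st <- .standardize_fit(Xtr)
      Xtr_s <- .standardize_apply(Xtr, st)
      Xte_s <- .standardize_apply(X[i, , drop = FALSE], st)
    } else {
      Xtr_s <- Xtr
      Xte_s <- X[i, , drop = FALSE]
    }
    for (k in seq_len(max_k)) {
      sel <- rk$feature[seq_len(k)]
      fit <- e1071::svm(x = Xtr_s[, sel, drop = FALSE], y = ytr,
                        type = "C-classification", kernel = "radial",
                        cost = config$C, gamma = config$gamma, scale = FALSE)
      preds[i, k] <- as.integer(as.character(
        stats::predict(fit, Xte_s[, sel, drop = FALSE])))
    }
  }

  curve <- do.call(rbind, lapply(seq_len(max_k), function(k) {
    m <- classification_metrics(preds[, k], y)
    data.frame(k = k, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               sens_ci_lo = m$sensitivity_ci[1], sens_ci_hi = m$sensitivity_ci[2],
               spec_ci_lo = m$specificity_ci[1], spec_ci_hi = m$specificity_ci[2])
  }))
  best_k <- curve$k[which.max(curve$accuracy)]

  mean_rank <- rowsum(unlist(lapply(rankings, `[[`, "rank")),
                      unlist(lapply(rankings, `[[`, "feature"))) / n
  consensus <- data.frame(feature = rownames(mean_rank),
                          mean_rank = as.numeric(mean_rank),
                          stringsAsFactors = FALSE)
  consensus <- consensus[order(consensus$mean_rank, consensus$feature), ]
  consensus$consensus_rank <- seq_len(nrow(consensus))
  rownames(consensus) <- NULL

  structure(list(curve = curve, predictions = preds,
                 fold_rankings = rankings, consensus = consensus,
                 best_k = best_k, config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  b <- x$curve[x$curve$k == x$best_k, ]
  cat(sprintf(paste0("LOOCV top-k sweep over k = 1..%d\n",
                     "best k = %d: accuracy %.3f, sensitivity %.3f, ",
                     "specificity %.3f\n"),
              max(x$curve$k), x$best_k, b$accuracy, b$sensitivity,
              b$specificity))
  invisible(x)
}

#' Classification metrics with exact binomial confidence intervals
#'
#' Accuracy, sensitivity (`TP / (TP + FN)` over label-1 lesions) and
#' specificity (`TN / (TN + FP)` over label-0 lesions), each with an exact
#' Clopper-Pearson 95% confidence interval. If a class is absent from `y`,
#' its rate is `NA` with a warning.
#'
#' @param predictions predicted labels (0/1), one per lesion.
#' @param y true labels (0/1).
#' @param conf_level confidence level (default 0.95).
#' @return list with `accuracy`, `sensitivity`, `specificity` and their
#'   `_ci` bounds.
#' @export
classification_metrics <- function(predictions, y, conf_level = 0.95) {
  stopifnot(length(predictions) == length(y))
  p <- as.integer(predictions)
  y <- as.integer(y)
  rate_ci <- function(x, n) {
    if (n == 0) return(list(rate = NA_real_, ci = c(NA_real_, NA_real_)))
    bt <- stats::binom.test(x, n, conf.level = conf_level)
    list(rate = x / n, ci = as.vector(bt$conf.int))
  }
  if (!any(y == 1L) || !any(y == 0L))
    warning("a class is absent from y; its rate is undefined")
  acc <- rate_ci(sum(p == y), length(y))
  sens <- rate_ci(sum(p == 1L & y == 1L), sum(y == 1L))
  spec <- rate_ci(sum(p == 0L & y == 0L), sum(y == 0L))
  list(accuracy = acc$rate, accuracy_ci = acc$ci,
       sensitivity = sens$rate, sensitivity_ci = sens$ci,
       specificity = spec$rate, specificity_ci = spec$ci)
}

#' Write the analysis report bundle
#'
#' Writes the per-k cross-validation curve (`cv_curve.csv`), the consensus
#' top-feature list at the best k with scan tags and ranks
#' (`selected_features.csv`), the univariate screen (`univariate.csv`), the
#' feature dictionary (`feature_dictionary.json`) and a run manifest
#' (`run_manifest.json`: configuration, seed, package version) into `dir`.
#' Re-running from the same inputs reproduces the bundle byte-identically.
#'
#' @param cv a [loocv_sweep()] result.
#' @param univ a [univariate_screen()] result (optional).
#' @param dir output directory.
#' @param seed the master seed used for the run (recorded, not consumed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(cv, univ = NULL, dir, seed = NA_integer_) {
  stopifnot(inherits(cv, "cv_result"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  paths <- character(0)
  f <- file.path(dir, "cv_curve.csv")
  utils::write.csv(cv$curve, f, row.names = FALSE)
  paths <- c(paths, f)

  sel <- utils::head(cv$consensus, cv$best_k)
  sel$scan <- sub("\\..*$", "", sel$feature)
  f <- file.path(dir, "selected_features.csv")
  utils::write.csv(sel[, c("feature", "scan", "mean_rank", "consensus_rank")],
                   f, row.names = FALSE)
  paths <- c(paths, f)

  if (!is.null(univ)) {
    f <- file.path(dir, "univariate.csv")
    utils::write.csv(univ, f, row.names = FALSE)
    paths <- c(paths, f)
  }

  f <- file.path(dir, "feature_dictionary.json")
  jsonlite::write_json(feature_dictionary(), f, dataframe = "rows",
                       pretty = TRUE)
  paths <- c(paths, f)

  f <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(list(config = unclass(cv$config), seed = seed,
                            best_k = cv$best_k,
                            package_version =
                              as.character(utils::packageVersion("bcsradiomics"))),
                       f, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, f)
  invisible(paths)
}
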