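# BW-ratio ranking, LOOCV sweep, metrics, report bundle.

test_that("BW-ratio matches hand computation and the naive oracle", {
  X <- cbind(f = c(1, 2, 3, 4, 5, 6))
  y <- c(0, 0, 0, 1, 1, 1)
  r <- bw_ratio(X, y)
  # between = 3(2-3.5)^2 + 3(5-3.5)^2 = 13.5; within = 2 + 2 = 4
  expect_equal(r$bw, 13.5 / 4, tolerance = 1e-12)

  set.seed(61)
  for (rep in 1:10) {
    n <- sample(6:20, 1)
    p <- sample(2:8, 1)
    Xr <- matrix(rnorm(n * p), n, p,
                 dimnames = list(NULL, paste0("v", 1:p)))
    yr <- c(0, 0, 1, 1, rbinom(n - 4, 1, 0.5))
    got <- bw_ratio(Xr, yr)
    want <- bw_bruteforce(Xr, yr)
    expect_equal(got$bw[match(paste0("v", 1:p), got$feature)], want,
                 tolerance = 1e-10)
    expect_setequal(got$rank, 1:p)
  }
})

test_that("a perfect separator gets rank 1 via the infinite-ratio convention", {
  y <- c(0, 0, 0, 1, 1, 1)
  X <- cbind(perfect = y, noise = c(0.1, 0.5, 0.3, 0.2, 0.6, 0.4))
  expect_message(r <- bw_ratio(X, y), "zero within-group")
  expect_equal(r$feature[1], "perfect")
  expect_true(is.infinite(r$bw[1]))
})

test_that("a strongly shifted feature outranks pure noise almost always", {
  wins <- 0
  for (s in 1:100) {
    set.seed(600 + s)
    y <- rep(c(0, 1), each = 8)
    X <- cbind(shifted = y * 3 + rnorm(16), noise = rnorm(16))
    wins <- wins + (bw_ratio(X, y)$feature[1] == "shifted")
  }
  expect_gte(wins, 95)
})

test_that("LOOCV separates well-separated classes and is deterministic", {
  set.seed(62)
  n <- 20
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(a = y * 5 + rnorm(n), b = y * 5 + rnorm(n), c = rnorm(n),
             d = rnorm(n))
  cv1 <- loocv_sweep(X, y, svm_config(max_k = 4))
  expect_equal(cv1$curve$sensitivity[2], 1)
  expect_equal(cv1$curve$specificity[2], 1)
  expect_equal(nrow(cv1$curve), 4)
  # determinism: identical predictions on a rerun
  cv2 <- loocv_sweep(X, y, svm_config(max_k = 4))
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$curve, cv2$curve)
  # each lesion predicted exactly once per k
  expect_false(anyNA(cv1$predictions))
  expect_error(loocv_sweep(X[1:3, ], y[1:3]), "n >= 4|class")
})

test_that("fold rankings and standardization never touch the held-out row", {
  set.seed(63)
  n <- 12
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  cv <- loocv_sweep(X, y, svm_config(max_k = 3))
  for (i in c(1, 5, n)) {
    rk <- bw_ratio(X[-i, ], y[-i])
    expect_identical(cv$fold_rankings[[i]]$feature, rk$feature)
    expect_equal(cv$fold_rankings[[i]]$bw, rk$bw, tolerance = 1e-12)
  }
  # poisoning the held-out row must not change that fold's ranking
  Xp <- X; Xp[2, ] <- Xp[2, ] + 100
  cvp <- loocv_sweep(Xp, y, svm_config(max_k = 3))
  expect_identical(cvp$fold_rankings[[2]]$feature, cv$fold_rankings[[2]]$feature)
})

test_that("using all features makes fold-wise selection vacuous", {
  set.seed(64)
  n <- 14
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  cv <- loocv_sweep(X, y, svm_config(max_k = 3))
  # at k = p the same feature set is used regardless of ranking order:
  # train directly with all features and compare predictions
  preds <- vapply(seq_len(n), function(i) {
    st <- bcsradiomics:::.standardize_fit(X[-i, , drop = FALSE])
    fit <- e1071::svm(bcsradiomics:::.standardize_apply(X[-i, ], st),
                      factor(y[-i], levels = c(0, 1)),
                      type = "C-classification", kernel = "radial",
                      cost = 1000, gamma = 0.005, scale = FALSE)
    as.integer(as.character(predict(
      fit, bcsradiomics:::.standardize_apply(X[i, , drop = FALSE], st))))
  }, integer(1))
  expect_identical(unname(cv$predictions[, 3]), preds)
})

test_that("metrics match the defining ratios with Clopper-Pearson intervals", {
  m <- classification_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(1, 1, 1))

  # all predicted 0 on balanced labels
  m2 <- classification_metrics(rep(0, 10), rep(c(0, 1), 5))
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)
  expect_equal(m2$accuracy, 0.5)

  # TP 30, FN 12, TN 49, FP 18
  y <- c(rep(1, 42), rep(0, 67))
  p <- c(rep(1, 30), rep(0, 12), rep(0, 49), rep(1, 18))
  m3 <- classification_metrics(p, y)
  expect_equal(m3$sensitivity, 30 / 42, tolerance = 1e-12)
  expect_equal(m3$specificity, 49 / 67, tolerance = 1e-12)
  # Clopper-Pearson via the beta-quantile closed form
  expect_equal(m3$specificity_ci,
               c(qbeta(0.025, 49, 67 - 49 + 1), qbeta(0.975, 49 + 1, 67 - 49)),
               tolerance = 1e-9)
  expect_warning(classification_metrics(c(0, 0), c(0, 0)), "absent")
})

test_that("the report bundle is complete and byte-stable across reruns", {
  set.seed(65)
  n <- 12
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("pre.a", "pre.b",
                                                          "post1.c", "post2.d")))
  cv <- loocv_sweep(X, y, svm_config(max_k = 4))
  univ <- data.frame(feature = colnames(X), rs = 0, p_spearman = 1,
                     t = 0, p_ttest = 1, p_spearman_bh = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(cv, univ, d1, seed = 65)
  write_report(cv, univ, d2, seed = 65)
  files <- c("cv_curve.csv", "selected_features.csv", "univariate.csv",
             "feature_dictionary.json", "run_manifest.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  curve <- read.csv(file.path(d1, "cv_curve.csv"))
  expect_equal(nrow(curve), 4)
  sel <- read.csv(file.path(d1, "selected_features.csv"))
  expect_true(all(c("feature", "scan", "consensus_rank") %in% names(sel)))
  expect_true(all(sel$scan %in% c("pre", "post1", "post2", "post3")))
})
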