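# Univariate screening and cohort tables.

test_that("Spearman correlation handles ties and sign convention", {
  expect_equal(spearman_vs_endpoint(c(0, 0, 1, 1, 0, 1), c(0, 0, 1, 1, 0, 1),
                                    exact = FALSE)$rs, 1)
  expect_equal(spearman_vs_endpoint(c(1, 1, 0, 0, 1, 0), c(0, 0, 1, 1, 0, 1),
                                    exact = FALSE)$rs, -1)
  # tie-corrected hand computation: y ranks (1.5, 1.5, 3.5, 3.5)
  r <- spearman_vs_endpoint(c(1, 2, 3, 4), c(0, 0, 1, 1), exact = FALSE)
  expect_equal(r$rs, 0.894, tolerance = 1e-3)
  # t approximation agrees with cor.test's asymptotic path
  set.seed(51)
  x <- rnorm(40); y <- rbinom(40, 1, 0.5)
  r2 <- spearman_vs_endpoint(x, y, exact = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(r2$rs, unname(ct$estimate), tolerance = 1e-10)
  expect_error(spearman_vs_endpoint(rep(1, 10), rbinom(10, 1, 0.5)),
               "constant")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(52)
  x <- rexp(30); y <- rbinom(30, 1, 0.5)
  r0 <- spearman_vs_endpoint(x, y, exact = FALSE)$rs
  for (f in list(log, sqrt, function(v) v^3 + 5)) {
    expect_equal(spearman_vs_endpoint(f(x), y, exact = FALSE)$rs, r0,
                 tolerance = 1e-12)
  }
})

test_that("exact permutation p-value is exchangeable-consistent at tiny n", {
  x <- c(1, 2, 3, 4, 5, 6); y <- c(0, 0, 0, 1, 1, 1)
  r <- spearman_vs_endpoint(x, y, exact = TRUE)
  # perfect separation: only the 2 extreme assignments of C(6,3)=20 reach |rs|
  expect_equal(r$p, 2 / 20, tolerance = 1e-12)
  expect_error(spearman_vs_endpoint(rnorm(12), rep(c(0, 1), 6), exact = TRUE),
               "n <= 10")
})

test_that("two-sample t-test matches hand computation", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(r$t), 3.674, tolerance = 1e-3)
  expect_equal(r$p, 0.0213, tolerance = 1e-3)
  expect_equal(r$df, 4)
  # identical groups: t = 0, p = 1
  r2 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)
  # p decreases monotonically as the shift grows
  set.seed(53)
  base <- rnorm(20)
  ps <- vapply(c(0.5, 1, 2, 4), function(d) {
    two_sample_t(base, base + d)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero")
})

test_that("categorical test picks chi-square or Fisher by expected counts", {
  r <- categorical_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$test_name, "chi-square")

  # DCIS counts: expected counts all >= 5, chi-square path, p rounds to 0.01
  dcis <- matrix(c(59, 29, 8, 13), nrow = 2, byrow = TRUE)
  r2 <- categorical_test(dcis)
  expect_equal(r2$test_name, "chi-square")
  expect_equal(r2$p, 0.0143, tolerance = 1e-2)
  expect_equal(round(r2$p, 2), 0.01)

  # tiny counts: Fisher path fires
  r3 <- categorical_test(matrix(c(1, 1, 1, 1), 2))
  expect_equal(r3$test_name, "fisher")

  # transposition invariance
  r4 <- categorical_test(t(dcis))
  expect_equal(r4$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r4$p, r2$p, tolerance = 1e-12)

  expect_error(categorical_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "all-zero")
})

test_that("cohort_summary reports group counts, percentages and tests", {
  set.seed(54)
  df <- data.frame(
    label = rep(c(0, 1), c(30, 20)),
    grade = sample(c("low", "high"), 50, replace = TRUE),
    size = c(rnorm(30, 2.0, 0.8), rnorm(20, 2.6, 1.7)))
  cs <- cohort_summary(df)
  expect_s3_class(cs, "cohort_summary")
  g <- cs$grade
  expect_equal(sum(g$counts[1, ]), 30)
  expect_equal(sum(g$counts[2, ]), 20)
  # percentages sum to 100 within rounding
  expect_lte(abs(sum(g$percent[1, ]) - 100), 1)
  expect_lte(abs(sum(g$percent[2, ]) - 100), 1)
  expect_equal(cs$size$type, "continuous")
  expect_equal(cs$size$summary["mean", "label0"], mean(df$size[df$label == 0]))
  # empty level in one group is reported as zero, not dropped
  df2 <- data.frame(label = c(0, 0, 1, 1),
                    m = c("wire", "seed", "wire", "wire"))
  cs2 <- cohort_summary(df2)
  expect_equal(cs2$m$counts[2, "seed"], 0)
  expect_equal(cs2$m$percent[2, "seed"], 0)
})

test_that("published count tables reproduce the printed cohort rates", {
  r <- reexcision_rates()
  expect_equal(r$n_total, 109)
  expect_equal(r$n_reexcision, 42)
  expect_equal(r$reexcision_rate_pct, 38.5, tolerance = 0.05)
  expect_equal(r$residual_carcinoma_rate_pct, 62, tolerance = 0.5)
  expect_equal(r$mastectomy_first_reexcision_rate_pct, 36, tolerance = 0.5)
  expect_equal(r$multifocal_no_reexcision_pct, 24, tolerance = 0.5)
  expect_equal(r$multifocal_reexcision_pct, 40, tolerance = 0.5)
  expect_equal(r$multifocal_one_reexcision_pct, 55, tolerance = 0.5)
  expect_equal(r$multifocal_two_or_more_pct, 9, tolerance = 0.5)
})

test_that("univariate screen emits one row per feature with a BH column", {
  set.seed(55)
  n <- 40
  df <- data.frame(lesion_id = paste0("l", 1:n),
                   label = rep(c(0, 1), each = n / 2))
  df$good <- df$label * 2 + rnorm(n, sd = 0.5)
  df$noise <- rnorm(n)
  df$constant <- 1
  u <- univariate_screen(df)
  expect_equal(nrow(u), 3)
  expect_true(all(c("rs", "p_spearman", "t", "p_ttest", "p_spearman_bh") %in%
                    names(u)))
  expect_gt(u$rs[u$feature == "good"], 0.5)
  expect_lt(u$p_spearman[u$feature == "good"], 0.001)
  expect_true(is.na(u$rs[u$feature == "constant"]))
  expect_true(all(u$p_spearman_bh >= u$p_spearman - 1e-12, na.rm = TRUE))
})
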