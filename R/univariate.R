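# Univariate screening of image features against the binary re-excision
# endpoint, and cohort description tables.

#' Spearman rank correlation of a feature with the endpoint
#'
#' Rank correlation (average ranks for ties) between a feature vector and the
#' binary endpoint; positive values mean larger feature values in the label-1
#' (re-excision) group. The p-value uses the large-sample t approximation
#' with `n - 2` degrees of freedom; for `n <= 10` an exact permutation
#' p-value (enumerating all label assignments) is available.
#'
#' @param x numeric feature vector.
#' @param y binary labels (0/1), same length, both labels present.
#' @param exact `TRUE` to force the exact permutation p-value (only for
#'   `n <= 10`), `FALSE` for the t approximation; default picks exact for
#'   `n <= 10`.
#' @return list with `rs`, `p`, and `method`.
#' @export
spearman_vs_endpoint <- function(x, y, exact = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both labels must be present")
  if (stats::sd(x) == 0) stop("constant feature: Spearman correlation undefined")
  n <- length(x)
  if (is.null(exact)) exact <- n <= 10
  rs <- stats::cor(rank(x), rank(y))
  if (exact) {
    if (n > 10) stop("exact permutation p-value limited to n <= 10")
    idx1 <- utils::combn(n, sum(y == 1L))
    rx <- rank(x)
    null_rs <- apply(idx1, 2, function(ix) {
      yy <- integer(n)
      yy[ix] <- 1L
      stats::cor(rx, rank(yy))
    })
    p <- mean(abs(null_rs) >= abs(rs) - 1e-12)
    method <- "exact permutation"
  } else {
    tval <- rs * sqrt((n - 2) / max(1e-300, 1 - rs^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t approximation"
  }
  list(rs = rs, p = min(1, p), method = method)
}

#' Two-sample t-test between outcome groups
#'
#' Two-sided two-sample t-test; pooled (Student) variance by default, Welch
#' by flag. Thin wrapper over [stats::t.test()] with the pipeline's
#' conventions pinned.
#'
#' @param x0,x1 numeric vectors for the label-0 and label-1 groups (each with
#'   at least 2 observations).
#' @param var_equal pooled variance if `TRUE` (default).
#' @return list with `t`, `p`, `df`, and `method`.
#' @export
two_sample_t <- function(x0, x1, var_equal = TRUE) {
  stopifnot(length(x0) >= 2, length(x1) >= 2)
  if (stats::var(c(x0 - mean(x0), x1 - mean(x1))) == 0)
    stop("zero within-group variance: t statistic undefined")
  ht <- stats::t.test(x1, x0, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       method = if (var_equal) "pooled" else "welch")
}

#' Categorical association test for a contingency table
#'
#' Pearson chi-square without continuity correction; falls back to Fisher's
#' exact test when any expected cell count is below 5. The statistic is
#' invariant under transposition of the table.
#'
#' @param tab matrix of nonnegative integer counts (2 x k).
#' @return list with `statistic` (NA for the Fisher path), `p`, `test_name`.
#' @export
categorical_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has an all-zero row or column")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ht <- stats::fisher.test(tab)
    list(statistic = NA_real_, p = ht$p.value, test_name = "fisher")
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value,
         test_name = "chi-square")
  }
}

#' Univariate screen of every feature against the endpoint
#'
#' Runs [spearman_vs_endpoint()] and [two_sample_t()] for each feature column
#' and returns one row per feature. No multiple-testing correction is applied
#' to the screening decision (significance is judged at p < 0.05); a
#' Benjamini-Hochberg adjusted column `p_spearman_bh` is emitted alongside as
#' a labeled extension, not used for selection. Constant features are
#' reported with `NA` statistics rather than dropped silently.
#'
#' @param features data frame from [extract_features()] (with `label` and
#'   feature columns).
#' @param var_equal passed to [two_sample_t()].
#' @return data frame: `feature`, `rs`, `p_spearman`, `t`, `p_ttest`,
#'   `p_spearman_bh`.
#' @export
univariate_screen <- function(features, var_equal = TRUE) {
  y <- features$label
  cols <- setdiff(names(features), c("lesion_id", "label"))
  rows <- lapply(cols, function(f) {
    x <- features[[f]]
    sp <- tryCatch(spearman_vs_endpoint(x, y, exact = FALSE),
                   error = function(e) list(rs = NA_real_, p = NA_real_))
    tt <- tryCatch(two_sample_t(x[y == 0], x[y == 1], var_equal),
                   error = function(e) list(t = NA_real_, p = NA_real_))
    data.frame(feature = f, rs = sp$rs, p_spearman = sp$p,
               t = tt$t, p_ttest = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_spearman_bh <- stats::p.adjust(out$p_spearman, method = "BH")
  out
}

#' Cohort description table
#'
#' Per-variable comparison of the two outcome groups: categorical variables
#' as counts with percentages of group size (rounded to the nearest integer)
#' and a [categorical_test()] p-value; continuous variables as mean +/- sd
#' per group with a [two_sample_t()] p-value.
#'
#' @param data data frame of per-patient records including `label_col`.
#' @param label_col name of the binary outcome column.
#' @param vars variables to summarize (default: all except the label).
#' @return list of per-variable summaries, class `cohort_summary`.
#' @export
cohort_summary <- function(data, label_col = "label", vars = NULL) {
  stopifnot(label_col %in% names(data))
  y <- as.integer(data[[label_col]])
  if (is.null(vars)) vars <- setdiff(names(data), c(label_col, "lesion_id"))
  out <- lapply(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      s <- vapply(c(0L, 1L), function(g) {
        c(mean = mean(x[y == g], na.rm = TRUE),
          sd = stats::sd(x[y == g], na.rm = TRUE))
      }, numeric(2))
      colnames(s) <- c("label0", "label1")
      p <- tryCatch(two_sample_t(x[y == 0], x[y == 1])$p,
                    error = function(e) NA_real_)
      list(variable = v, type = "continuous", summary = s,
           test = "t-test", p = p)
    } else if (is.character(x) || is.factor(x) || is.logical(x)) {
      tab <- table(factor(y, levels = c(0L, 1L)), x)
      pct <- round(100 * prop.table(tab, margin = 1))
      pct[is.nan(pct)] <- 0
      ct <- tryCatch(categorical_test(tab), error = function(e)
        list(p = NA_real_, test_name = "none"))
      list(variable = v, type = "categorical", counts = unclass(tab),
           percent = unclass(pct), test = ct$test_name, p = ct$p)
    } else {
      stop("unknown variable type for ", v)
    }
  })
  names(out) <- vars
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  for (v in x) {
    cat(v$variable, " (", v$type, ", ", v$test, " p = ",
        formatC(v$p, digits = 3), ")\n", sep = "")
    if (v$type == "continuous") {
      cat(sprintf("  label0: %.2f +/- %.2f   label1: %.2f +/- %.2f\n",
                  v$summary["mean", 1], v$summary["sd", 1],
                  v$summary["mean", 2], v$summary["sd", 2]))
    } else {
      for (lev in colnames(v$counts)) {
        cat(sprintf("  %s: %d (%d%%) vs %d (%d%%)\n", lev,
                    v$counts[1, lev], v$percent[1, lev],
                    v$counts[2, lev], v$percent[2, lev]))
      }
    }
  }
  invisible(x)
}

#' Re-excision outcome rates from cohort count tables
#'
#' Derived whole-cohort statistics from the re-excision reason table and the
#' per-group multifocality table (the package ships the published HER2+
#' cohort's count tables in `inst/extdata/`, used by default): re-excision
#' rate, residual-carcinoma rate and mastectomy-at-first-re-excision rate
#' among re-excised patients, and multifocal/multicentric rates per group.
#' All rates are percentages.
#'
#' @param reasons data frame with columns `reason`, `n`,
#'   `residual_carcinoma`, `mastectomy_first_reexcision` (one row per reason
#'   for re-excision).
#' @param groups data frame with columns `group`
#'   (`no_reexcision`, `one_reexcision`, `two_or_more_reexcisions`), `n`,
#'   `multifocal` (per number of re-excisions).
#' @param multifocal data frame with columns `group` (`no_reexcision`,
#'   `reexcision`), `n`, `multifocal` (two-group multifocality counts).
#' @return named list of rates (percent).
#' @export
reexcision_rates <- function(reasons = read_extdata("reexcision_reasons.csv"),
                             groups = read_extdata("cohort_groups.csv"),
                             multifocal = read_extdata("multifocal_mri.csv")) {
  n_reexc <- sum(reasons$n)
  reexc_groups <- groups$group != "no_reexcision"
  if (sum(groups$n[reexc_groups]) != n_reexc)
    stop("re-excision counts disagree between the two tables")
  n_total <- sum(groups$n)
  g <- function(df, name) df[df$group == name, , drop = FALSE]
  list(
    n_total = n_total,
    n_reexcision = n_reexc,
    reexcision_rate_pct = 100 * n_reexc / n_total,
    residual_carcinoma_rate_pct = 100 * sum(reasons$residual_carcinoma) / n_reexc,
    mastectomy_first_reexcision_rate_pct =
      100 * sum(reasons$mastectomy_first_reexcision) / n_reexc,
    multifocal_no_reexcision_pct =
      100 * g(multifocal, "no_reexcision")$multifocal /
      g(multifocal, "no_reexcision")$n,
    multifocal_reexcision_pct =
      100 * g(multifocal, "reexcision")$multifocal /
      g(multifocal, "reexcision")$n,
    multifocal_one_reexcision_pct =
      100 * g(groups, "one_reexcision")$multifocal /
      g(groups, "one_reexcision")$n,
    multifocal_two_or_more_pct =
      100 * g(groups, "two_or_more_reexcisions")$multifocal /
      g(groups, "two_or_more_reexcisions")$n)
}

#' Read a packaged data table
#'
#' @param file file name under the package's `extdata/`.
#' @return data frame.
#' @export
read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "bcsradiomics")
  if (path == "") stop("no such packaged data file: ", file)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
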