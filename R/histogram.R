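#' First-order histogram features of in-mask intensities
#'
#' Summarizes the raw (unquantized) intensity distribution inside the tumor
#' contour of one timepoint: minimum, median, mean, variance, skewness and
#' kurtosis. Moments are population moments (divisor `n`); skewness is the
#' third standardized moment `m3 / m2^(3/2)` and kurtosis the Pearson (non
#' excess) fourth standardized moment `m4 / m2^2`, so a normal distribution
#' has skewness 0 and kurtosis 3. The median of an even count is the midpoint
#' of the two central order statistics.
#'
#' For a constant region (zero variance) skewness and kurtosis are undefined
#' and returned as `NA` with a warning rather than silently zero.
#'
#' @param values numeric 3D array of intensities (one timepoint).
#' @param mask logical 3D array of the same shape; `TRUE` marks tumor voxels.
#' @return named numeric vector with elements `minimum`, `median`, `mean`,
#'   `variance`, `skewness`, `kurtosis`.
#' @examples
#' v <- array(rnorm(64), c(4, 4, 4))
#' m <- array(TRUE, c(4, 4, 4))
#' roi_histogram(v, m)
#' @export
roi_histogram <- function(values, mask) {
  m <- .check_mask(mask)
  if (!identical(dim(values), dim(m))) stop("values/mask shape mismatch")
  x <- as.numeric(values[m])
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 <= 0) {
    warning("zero-variance region: skewness and kurtosis undefined")
    sk <- NA_real_
    ku <- NA_real_
  } else {
    sk <- mean((x - mu)^3) / m2^1.5
    ku <- mean((x - mu)^4) / m2^2
  }
  c(minimum = min(x),
    median = stats::median(x),
    mean = mu,
    variance = m2,
    skewness = sk,
    kurtosis = ku)
}
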