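# First-order (intensity histogram) features over the masked pixels.

#' Intensity features of a ROI
#'
#' Nine first-order statistics over the masked pixels only: minimum,
#' maximum, mean, stand_deviation, sum, median, skewness, kurtosis,
#' variance. Variance and standard deviation use the population (n)
#' denominator; skewness and kurtosis are the standardized third and
#' fourth central moments (kurtosis is not excess: a Gaussian gives 3).
#'
#' A zero-variance (or single-pixel) ROI leaves skewness and kurtosis
#' undefined; with `strict = TRUE` (default) this raises a
#' degenerate-ROI error so the pipeline can place the lesion on an
#' explicit exclusion list, with `strict = FALSE` the defined statistics
#' are returned and the undefined ones are omitted.
#'
#' @param scan a [roi_scan()].
#' @param strict raise on undefined moments (default `TRUE`).
#' @return named numeric vector.
#' @export
intensity_features <- function(scan, strict = TRUE) {
  v <- masked_values(scan)
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  out <- c(minimum = min(v), maximum = max(v), mean = m,
           stand_deviation = sqrt(m2), sum = sum(v), median = median(v),
           skewness = NA_real_, kurtosis = NA_real_, variance = m2)
  if (n < 2 || m2 == 0) {
    if (strict)
      rader_abort(paste0("degenerate ROI (zero variance, n=", n,
                         "): skewness/kurtosis undefined"), "degenerate_roi")
    return(out[setdiff(names(out), c("skewness", "kurtosis"))])
  }
  out["skewness"] <- mean((v - m)^3) / m2^1.5
  out["kurtosis"] <- mean((v - m)^4) / m2^2
  out
}
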