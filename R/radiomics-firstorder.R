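#' First-order (histogram) features of a VOI
#'
#' Twelve first-order statistics of the in-mask intensity distribution.
#' Location/spread/shape features (mean, median, minimum, maximum, range,
#' variance, skewness, kurtosis, mean absolute deviation) are computed on the
#' raw intensities with population moments; energy, entropy and uniformity
#' are computed on the normalized gray-level histogram of the quantized VOI
#' (log base 2 for entropy). Conventions for a constant VOI: variance,
#' skewness, kurtosis and entropy are 0; energy and uniformity are 1.
#' Kurtosis is excess (Fisher) kurtosis.
#'
#' @param q A `quantized_voi` from [quantize()].
#' @return Named numeric vector of length 12, in registry order.
#' @export
first_order_features <- function(q) {
  stopifnot(inherits(q, "quantized_voi"))
  x <- q$raw
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)  # population variance
  if (m2 > 0) {
    m3 <- mean((x - mu)^3)
    m4 <- mean((x - mu)^4)
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  p <- tabulate(q$levels[q$mask], nbins = q$G) / n
  pp <- p[p > 0]
  c(mean = mu,
    median = stats::median(x),
    minimum = min(x),
    maximum = max(x),
    range = max(x) - min(x),
    variance = m2,
    skewness = skew,
    kurtosis = kurt,
    energy = sum(p^2),
    entropy = -sum(pp * log2(pp)),
    uniformity = sum(p^2),
    mean_absolute_deviation = mean(abs(x - mu)))
}
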