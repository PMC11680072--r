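#' Time-domain statistical features
#'
#' Mean, sample standard deviation (`N - 1` denominator, or population
#' when `population = TRUE`), root mean square, Fisher-Pearson skewness
#' `g1 = m3 / m2^(3/2)`, and kurtosis. Kurtosis defaults to the excess
#' convention (normal -> 0); `kurtosis = "pearson"` reports `m4 / m2^2`
#' (normal -> 3). Constant input yields skewness and kurtosis 0 with a
#' `degenerate` flag instead of NaN.
#'
#' @param sequence Numeric vector, length >= 2.
#' @param population Use population (`N`) instead of sample (`N - 1`)
#'   denominator for the standard deviation.
#' @param kurtosis `"excess"` (default) or `"pearson"`.
#' @return Named list `mean`, `std`, `rms`, `skewness`, `kurtosis`,
#'   `degenerate`.
#' @export
time_domain_features <- function(sequence, population = FALSE,
                                 kurtosis = c("excess", "pearson")) {
  kurtosis <- match.arg(kurtosis)
  x <- as_samples(sequence)
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  std <- if (population) sqrt(m2) else stats::sd(x)
  rms <- sqrt(mean(x^2))
  if (m2 == 0) {
    return(list(mean = mu, std = 0, rms = rms, skewness = 0, kurtosis = 0,
                degenerate = TRUE))
  }
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- m3 / m2^1.5
  kurt <- m4 / m2^2
  if (kurtosis == "excess") kurt <- kurt - 3
  list(mean = mu, std = std, rms = rms, skewness = skew, kurtosis = kurt,
       degenerate = FALSE)
}

#' Zero-crossing rate
#'
#' Counts sign transitions between consecutive nonzero-signed samples
#' (zero samples bridging opposite signs count as a single crossing) and
#' reports the per-sample rate `count / (N - 1)` together with the
#' per-second rate `rate * fs`.
#'
#' @param sequence Numeric vector, length >= 2.
#' @param fs Sampling rate, Hz, for the per-second rate (default 1).
#' @return Named list `count`, `rate` (crossings/sample),
#'   `rate_per_second`.
#' @examples
#' zcr(c(1, -1, 1, -1))
#' @export
zcr <- function(sequence, fs = 1) {
  x <- as_samples(sequence)
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  count <- count_zero_crossings(x)
  rate <- count / (n - 1L)
  list(count = count, rate = rate, rate_per_second = rate * fs)
}

#' Mean squared and root-mean-squared error between signals
#'
#' @param a,b Equal-length numeric vectors or [ecg_signal()]s.
#' @return Named list `mse`, `rmse`.
#' @export
compare_signals <- function(a, b) {
  av <- as_samples(a)
  bv <- as_samples(b)
  if (length(av) != length(bv)) {
    stop("signals must have equal length", call. = FALSE)
  }
  mse <- mean((av - bv)^2)
  list(mse = mse, rmse = sqrt(mse))
}
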