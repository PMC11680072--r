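#' RR interval series from peak indices
#'
#' @param peaks Strictly increasing R-peak sample indices (1-based).
#' @param fs Sampling rate, Hz.
#' @return A list of class `rr_series` with `intervals` (seconds), `peaks`
#'   and `fs`.
#' @export
rr_intervals <- function(peaks, fs) {
  peaks <- as.integer(peaks)
  if (length(peaks) < 2L) {
    stop("need at least 2 peaks to form RR intervals", call. = FALSE)
  }
  if (is.unsorted(peaks, strictly = TRUE)) {
    stop("peaks must be strictly increasing", call. = FALSE)
  }
  structure(list(intervals = diff(peaks) / fs, peaks = peaks, fs = fs),
            class = "rr_series")
}

#' Inter-beat interval histogram
#'
#' Fixed-width binning of the RR intervals over their observed range.
#'
#' @param rr An `rr_series` from [rr_intervals()].
#' @param bin_width_s Bin width in seconds (default 0.025 s).
#' @return List with `breaks` (bin edges, s) and `counts`.
#' @export
ibi_histogram <- function(rr, bin_width_s = 0.025) {
  stopifnot(inherits(rr, "rr_series"))
  if (bin_width_s <= 0) stop("`bin_width_s` must be > 0", call. = FALSE)
  iv <- rr$intervals
  lo <- floor(min(iv) / bin_width_s) * bin_width_s
  hi <- ceiling(max(iv) / bin_width_s) * bin_width_s
  if (hi <= lo) hi <- lo + bin_width_s
  breaks <- seq(lo, hi, by = bin_width_s)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(iv, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts)
}

#' Heart-rate-variability metrics
#'
#' With `N` intervals `RR_i` and `meanRR` their mean:
#' `sdnn = sqrt(sum((RR_i - meanRR)^2) / (N - 1))` (s),
#' `rmssd = sqrt(sum((RR_{i+1} - RR_i)^2) / (N - 1))` (s),
#' `nn50 = #\{|RR_{i+1} - RR_i| > 0.050 s\}`,
#' `pnn50 = 100 * nn50 / (N - 1)` (%), and `mean_hr = 60 / meanRR` (bpm).
#' The 50 ms threshold is the standard NN50 definition and is strict.
#'
#' @param rr An `rr_series` or a numeric vector of intervals in seconds.
#' @return Named list `sdnn`, `rmssd`, `nn50`, `pnn50`, `mean_hr`.
#' @examples
#' hrv_metrics(c(0.7, 0.9))
#' @export
hrv_metrics <- function(rr) {
  iv <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  n <- length(iv)
  if (n < 2L) stop("need at least 2 RR intervals", call. = FALSE)
  if (any(iv <= 0)) stop("RR intervals must be positive", call. = FALSE)
  mean_rr <- mean(iv)
  sdnn <- sqrt(sum((iv - mean_rr)^2) / (n - 1))
  d <- diff(iv)
  rmssd <- sqrt(sum(d^2) / (n - 1))
  nn50 <- sum(abs(d) > 0.050)
  pnn50 <- 100 * nn50 / (n - 1)
  list(sdnn = sdnn, rmssd = rmssd, nn50 = nn50, pnn50 = pnn50,
       mean_hr = 60 / mean_rr)
}
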