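#' Detect R peaks (Pan-Tompkins style)
#'
#' QRS detection by the classic derivative - square - moving-window
#' integration chain: the signal is band-passed to the QRS energy band
#' (5-15 Hz), differentiated with the centred five-point derivative,
#' squared, and integrated over a 150 ms centred window. Integration-wave
#' peaks are screened with adaptive signal/noise thresholds
#' (`SPKI`/`NPKI`, threshold `NPKI + 0.25 (SPKI - NPKI)`) and a 200 ms
#' refractory period, then each accepted peak is refined to the local
#' maximum of the input signal within +/- 75 ms. All internal filters are
#' centred/zero-phase, so reported indices are not systematically shifted.
#'
#' @param signal A preprocessed [ecg_signal()] or numeric vector.
#' @param fs Sampling rate, Hz (from the signal if omitted).
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (1-based).
#' @export
detect_r_peaks <- function(signal, fs = NULL) {
  fs <- signal_fs(signal, fs)
  x <- as_samples(signal)
  n <- length(x)
  if (n < 2 * fs) stop("signal shorter than 2 s", call. = FALSE)

  # QRS band: 5-15 Hz emphasises the R complex, suppresses P/T and noise.
  taps <- min(201L, 2L * floor(n / 4L) + 1L)
  y <- bandpass_filter(x, bandpass_spec(5, min(15, fs / 2 - 1), taps), fs = fs)

  d <- numeric(n)
  idx <- 3:(n - 2L)
  d[idx] <- (-y[idx - 2L] - 2 * y[idx - 1L] + 2 * y[idx + 1L] + y[idx + 2L]) / 8
  sq <- d^2

  win <- max(3L, round(0.15 * fs))
  if (win %% 2L == 0L) win <- win + 1L
  w <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2L))
  w[is.na(w)] <- 0

  cand <- which(diff(sign(diff(w))) < 0) + 1L
  cand <- cand[w[cand] > 0]
  if (length(cand) == 0L) return(integer(0))

  init_span <- seq_len(min(n, round(2 * fs)))
  spki <- max(w[init_span]) * 0.5
  npki <- mean(w[init_span]) * 0.5
  refractory <- round(0.2 * fs)

  accepted <- integer(0)
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (w[i] > thr) {
      if (length(accepted) > 0L && i - accepted[length(accepted)] < refractory) {
        # within refractory: keep the larger integration peak
        if (w[i] > w[accepted[length(accepted)]]) {
          accepted[length(accepted)] <- i
        }
      } else {
        accepted <- c(accepted, i)
      }
      spki <- 0.125 * w[i] + 0.875 * spki
    } else {
      npki <- 0.125 * w[i] + 0.875 * npki
    }
  }
  if (length(accepted) == 0L) return(integer(0))

  # Refine to the local maximum of the input within +/- 75 ms.
  half <- as.integer(round(0.075 * fs))
  peaks <- vapply(accepted, function(i) {
    lo <- max(1L, as.integer(i) - half)
    hi <- min(n, as.integer(i) + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))

  peaks <- sort(unique(peaks))
  # enforce the refractory period on the refined indices too
  if (length(peaks) > 1L) {
    keep <- rep(TRUE, length(peaks))
    last <- 1L
    for (j in 2:length(peaks)) {
      if (peaks[j] - peaks[last] < refractory) {
        if (x[peaks[j]] > x[peaks[last]]) {
          keep[last] <- FALSE
          last <- j
        } else {
          keep[j] <- FALSE
        }
      } else {
        last <- j
      }
    }
    peaks <- peaks[keep]
  }
  peaks
}
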