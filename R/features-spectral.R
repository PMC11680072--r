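#' Discrete Fourier transform of a sequence
#'
#' Forward transform `X[k] = sum_n x[n] exp(-i 2 pi k n / N)` with no
#' scaling (the inverse carries the `1/N`). Returns a two-sided spectrum
#' on the fft bin grid; use [as_one_sided()] to fold it.
#'
#' @param sequence Numeric vector (length >= 1).
#' @param fs Sampling rate, Hz (default 1, giving normalized frequency).
#' @return A list of class `ecg_spectrum`: `coefficients` (complex),
#'   `frequency` (Hz; negative for the upper half), `N`, `fs`, `side`.
#' @export
dft <- function(sequence, fs = 1) {
  x <- as_samples(sequence)
  if (length(x) < 1L) stop("need at least 1 sample", call. = FALSE)
  n <- length(x)
  k <- 0:(n - 1L)
  freq <- ifelse(k <= n / 2, k, k - n) * fs / n
  structure(list(coefficients = stats::fft(x), frequency = freq,
                 N = n, fs = fs, side = "two-sided"),
            class = "ecg_spectrum")
}

#' Inverse discrete Fourier transform
#'
#' `x[n] = (1/N) sum_k X[k] exp(i 2 pi k n / N)`. For a two-sided spectrum
#' of a real signal the imaginary part of the result is numerically zero
#' and is dropped.
#'
#' @param spectrum An `ecg_spectrum` from [dft()] (two-sided).
#' @return Numeric vector of length `N`.
#' @export
idft <- function(spectrum) {
  stopifnot(inherits(spectrum, "ecg_spectrum"))
  if (spectrum$side != "two-sided") {
    stop("idft needs the full two-sided spectrum", call. = FALSE)
  }
  Re(stats::fft(spectrum$coefficients, inverse = TRUE)) / spectrum$N
}

#' Fold a two-sided spectrum to one side
#'
#' Keeps bins from DC to Nyquist. Coefficients are kept verbatim (no
#' doubling); the spectral features below are scale-free, so the fold only
#' fixes the frequency axis to `[0, fs/2]`.
#'
#' @param spectrum A two-sided `ecg_spectrum`.
#' @return A one-sided `ecg_spectrum`.
#' @export
as_one_sided <- function(spectrum) {
  stopifnot(inherits(spectrum, "ecg_spectrum"))
  if (spectrum$side == "one-sided") return(spectrum)
  nh <- floor(spectrum$N / 2)
  keep <- 1:(nh + 1L)
  structure(list(coefficients = spectrum$coefficients[keep],
                 frequency = (0:nh) * spectrum$fs / spectrum$N,
                 N = spectrum$N, fs = spectrum$fs, side = "one-sided"),
            class = "ecg_spectrum")
}

#' Frequency-domain features of a spectrum
#'
#' With power `P[k] = |X[k]|^2` and `p = P / sum(P)`:
#' dominant frequency = `argmax |X|`; spectral centroid =
#' `sum(f * p)`; spread = `sqrt(sum((f - centroid)^2 * p))`; entropy =
#' `-sum(p log2 p)` (bits); rolloff = smallest `f` whose cumulative power
#' reaches `energy_fraction` of the total (cumulating in frequency-axis
#' order, so on a two-sided spectrum the rolloff can be negative, matching
#' the two-sided convention).
#'
#' @param spectrum An `ecg_spectrum` (one- or two-sided; the features use
#'   the spectrum's own frequency axis).
#' @param energy_fraction Rolloff energy fraction (default 0.85).
#' @return Named list `dominant_frequency`, `spectral_centroid`,
#'   `spectral_spread`, `spectral_entropy`, `spectral_rolloff`.
#' @export
frequency_features <- function(spectrum, energy_fraction = 0.85) {
  stopifnot(inherits(spectrum, "ecg_spectrum"))
  if (energy_fraction <= 0 || energy_fraction > 1) {
    stop("`energy_fraction` must be in (0, 1]", call. = FALSE)
  }
  P <- Mod(spectrum$coefficients)^2
  if (all(P == 0)) stop("all-zero spectrum has no features", call. = FALSE)
  f <- spectrum$frequency
  ord <- order(f)
  f <- f[ord]
  P <- P[ord]
  p <- P / sum(P)
  centroid <- sum(f * p)
  spread <- sqrt(sum((f - centroid)^2 * p))
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  rolloff <- f[which(cumsum(p) >= energy_fraction)[1L]]
  list(dominant_frequency = f[which.max(P)],
       spectral_centroid = centroid,
       spectral_spread = spread,
       spectral_entropy = entropy,
       spectral_rolloff = rolloff)
}

#' Short-time Fourier transform magnitude grid
#'
#' Hann-windowed frames of the input, per-frame DFT magnitudes on the
#' one-sided grid. Frame count is `floor((N - window) / hop) + 1`; frame
#' time stamps are at the window centres.
#'
#' @param sequence Numeric vector.
#' @param window Window length in samples (default `fs`, i.e. 1 s).
#' @param hop Hop in samples (default `window / 2`, 50% overlap).
#' @param fs Sampling rate, Hz.
#' @return A list of class `stft_grid`: `magnitude` (freq x frames
#'   matrix), `frequency` (Hz), `time` (s, frame centres), `window`,
#'   `hop`, `fs`.
#' @export
stft <- function(sequence, window = NULL, hop = NULL, fs = 1) {
  x <- as_samples(sequence)
  if (is.null(window)) window <- max(8L, round(fs))
  window <- as.integer(window)
  if (is.null(hop)) hop <- max(1L, window %/% 2L)
  hop <- as.integer(hop)
  if (hop <= 0L) stop("`hop` must be positive", call. = FALSE)
  n <- length(x)
  if (window > n) stop("`window` exceeds the signal length", call. = FALSE)
  n_frames <- (n - window) %/% hop + 1L
  w <- hann_window(window)
  nh <- floor(window / 2)
  mag <- matrix(0, nh + 1L, n_frames)
  times <- numeric(n_frames)
  for (j in seq_len(n_frames)) {
    start <- (j - 1L) * hop + 1L
    frame <- x[start:(start + window - 1L)] * w
    X <- stats::fft(frame)
    mag[, j] <- Mod(X[1:(nh + 1L)])
    times[j] <- (start - 1L + (window - 1L) / 2) / fs
  }
  structure(list(magnitude = mag, frequency = (0:nh) * fs / window,
                 time = times, window = window, hop = hop, fs = fs),
            class = "stft_grid")
}

hann_window <- function(n) {
  i <- seq_len(n) - 1L
  0.5 * (1 - cos(2 * pi * i / (n - 1L)))
}

#' Time-frequency features from an STFT grid
#'
#' Per-frame spectral centroid and spectral entropy (on the frame's power
#' distribution, as in [frequency_features()]), averaged over frames.
#' Frames with zero power are excluded from the averages.
#'
#' @param grid An `stft_grid` from [stft()].
#' @return Named list `mean_frequency` (Hz), `mean_spectral_entropy`
#'   (bits).
#' @export
timefreq_features <- function(grid) {
  stopifnot(inherits(grid, "stft_grid"))
  P <- grid$magnitude^2
  tot <- colSums(P)
  if (all(tot == 0)) stop("all-zero STFT grid has no features", call. = FALSE)
  keep <- which(tot > 0)
  f <- grid$frequency
  cents <- vapply(keep, function(j) sum(f * P[, j]) / tot[j], numeric(1))
  ents <- vapply(keep, function(j) {
    p <- P[, j] / tot[j]
    nz <- p > 0
    -sum(p[nz] * log2(p[nz]))
  }, numeric(1))
  list(mean_frequency = mean(cents), mean_spectral_entropy = mean(ents))
}
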