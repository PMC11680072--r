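#' Band-pass filter specification
#'
#' An FIR band-pass described by its corner frequencies and tap count. The
#' kernel realizes the ideal brick-wall band response as the difference of
#' two windowed-sinc low-pass impulse responses (cutoffs `f_high` and
#' `f_low`), Hamming-windowed. Defaults give the standard 0.5-40 Hz
#' diagnostic ECG band with 501 taps at 500 Hz.
#'
#' @param f_low Lower corner, Hz (`>= 0`).
#' @param f_high Upper corner, Hz (must satisfy `f_low < f_high < fs/2`).
#' @param taps Filter length; forced odd so the kernel is symmetric and the
#'   filter has exactly zero phase when applied centred.
#' @return A list of class `bandpass_spec`.
#' @export
bandpass_spec <- function(f_low = 0.5, f_high = 40, taps = 501L) {
  if (!is.finite(f_low) || f_low < 0) stop("`f_low` must be >= 0", call. = FALSE)
  if (!is.finite(f_high) || f_high <= f_low) {
    stop("`f_high` must exceed `f_low`", call. = FALSE)
  }
  taps <- as.integer(taps)
  if (taps < 3L) stop("`taps` must be at least 3", call. = FALSE)
  if (taps %% 2L == 0L) taps <- taps + 1L
  structure(list(f_low = f_low, f_high = f_high, taps = taps),
            class = "bandpass_spec")
}

# Windowed-sinc band-pass kernel: low-pass(f_high) minus low-pass(f_low),
# Hamming window. Symmetric, hence linear (here zero) phase.
fir_bandpass_kernel <- function(spec, fs) {
  m <- seq.int(-(spec$taps - 1L) / 2L, (spec$taps - 1L) / 2L)
  lp <- function(fc) {
    h <- ifelse(m == 0L, 2 * fc / fs, sin(2 * pi * fc * m / fs) / (pi * m))
    h
  }
  h <- lp(spec$f_high) - lp(spec$f_low)
  h * hamming_window(spec$taps)
}

hamming_window <- function(n) {
  i <- seq_len(n) - 1L
  0.54 - 0.46 * cos(2 * pi * i / (n - 1L))
}

#' Apply a zero-phase FIR band-pass filter
#'
#' Filters the signal with the symmetric windowed-sinc kernel from the
#' spec, applied centred with mirror-extension padding at both edges, so
#' the output has the same length as the input and fiducial points (R
#' peaks) are not shifted.
#'
#' @param signal An [ecg_signal()] or numeric vector.
#' @param spec A [bandpass_spec()].
#' @param fs Sampling rate; taken from `signal` when it is an
#'   [ecg_signal()].
#' @return Filtered signal of the same class and length as the input.
#' @export
bandpass_filter <- function(signal, spec = bandpass_spec(), fs = NULL) {
  fs <- signal_fs(signal, fs)
  if (spec$f_high >= fs / 2) {
    stop("`f_high` must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  x <- as_samples(signal)
  n <- length(x)
  h <- fir_bandpass_kernel(spec, fs)
  half <- (spec$taps - 1L) / 2L
  pad <- min(half, n - 1L)
  left <- if (pad > 0L) x[(pad + 1L):2L] else numeric(0)
  right <- if (pad > 0L) x[(n - 1L):(n - pad)] else numeric(0)
  xp <- c(left, x, right)
  if (pad < half) xp <- c(rep(xp[1L], half - pad), xp,
                          rep(xp[length(xp)], half - pad))
  y_full <- stats::filter(xp, h, method = "convolution", sides = 2L)
  y <- as.numeric(y_full[(half + 1L):(half + n)])
  if (inherits(signal, "ecg_signal")) {
    out <- signal
    out$samples <- y
    out
  } else {
    y
  }
}

#' Min-max normalization to [0, 1]
#'
#' Rescales values so the observed minimum maps to 0 and the maximum to 1:
#' `(x - min) / (max - min)`. Order-preserving.
#'
#' @param values Numeric vector, length >= 2, all finite.
#' @return Numeric vector in `[0, 1]` with both endpoints attained.
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    stop("degenerate range: all values are equal", call. = FALSE)
  }
  (values - rng[1L]) / (rng[2L] - rng[1L])
}

#' Preprocess an ECG signal
#'
#' Band-pass filters the raw recording, min-max normalizes it to `[0, 1]`,
#' then subtracts the mean so the downstream decomposition sees a
#' zero-baseline signal. Output lies in `[-1, 1]` with mean (numerically)
#' zero; R-peak timing is unchanged because the filter is zero-phase. The
#' applied spec is recorded in the `"preprocess"` attribute.
#'
#' @param signal An [ecg_signal()].
#' @param spec A [bandpass_spec()].
#' @return The preprocessed [ecg_signal()].
#' @export
preprocess <- function(signal, spec = bandpass_spec()) {
  stopifnot(inherits(signal, "ecg_signal"))
  filtered <- bandpass_filter(signal, spec)
  z <- minmax_normalize(filtered$samples)
  z <- z - mean(z)
  out <- signal
  out$samples <- z
  attr(out, "preprocess") <- list(bandpass = unclass(spec),
                                  normalization = "minmax + mean centering")
  out
}
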