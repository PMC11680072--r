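#' Empirical mode decomposition
#'
#' Classical sifting: cubic-spline envelopes are fitted through the local
#' maxima and minima (extrema mirrored across both ends for boundary
#' handling), the envelope mean is subtracted, and sifting stops when the
#' normalized squared difference between consecutive sifts drops below
#' `sd_tol` and the candidate satisfies the IMF count property (numbers of
#' extrema and zero crossings differ by at most one). Decomposition stops
#' when the residue is monotone or has fewer than two maxima or minima.
#' The identity `sum(imfs) + residue == input` holds to machine precision
#' because sifting is purely subtractive.
#'
#' @param signal An [ecg_signal()] or numeric vector (length >= 4 with at
#'   least two extrema to produce any IMF).
#' @param max_imfs Cap on the number of IMFs extracted (default 10).
#' @param sd_tol Sifting stop threshold on
#'   `sum((h_prev - h)^2) / sum(h_prev^2)` (default 0.3).
#' @param max_sifts Per-IMF sifting cap (default 100).
#' @param fs Sampling rate; taken from `signal` if it is an
#'   [ecg_signal()]; only stored, the sifting is rate-free.
#' @return A list of class `imf_set`: `imfs` (list, highest-frequency
#'   first), `residue`, `fs`, `source`.
#' @export
emd <- function(signal, max_imfs = 10L, sd_tol = 0.3, max_sifts = 100L,
                fs = NULL) {
  fs <- tryCatch(signal_fs(signal, fs), error = function(e) NA_real_)
  x <- as_samples(signal)
  if (length(x) < 4L) stop("signal too short for sifting", call. = FALSE)
  if (!all(is.finite(x))) stop("samples must be finite", call. = FALSE)

  imfs <- list()
  residue <- x
  for (i in seq_len(max_imfs)) {
    ext <- find_extrema(residue)
    if (length(ext$max_idx) < 2L || length(ext$min_idx) < 2L) break
    h <- residue
    for (s in seq_len(max_sifts)) {
      e <- find_extrema(h)
      if (length(e$max_idx) < 2L || length(e$min_idx) < 2L) break
      upper <- spline_envelope(e$max_idx, h[e$max_idx], length(h))
      lower <- spline_envelope(e$min_idx, h[e$min_idx], length(h))
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_crit <- sum(m^2) / (sum(h^2) + .Machine$double.eps)
      h <- h_new
      if (sd_crit < sd_tol && imf_property_holds(h)) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residue <- residue - h
    if (is_monotone(residue)) break
  }
  structure(list(imfs = imfs, residue = residue, fs = fs, source = x),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs over %d samples\n",
              length(x$imfs), length(x$source)))
  invisible(x)
}

#' First intrinsic mode function as the recovered signal
#'
#' @param imfset An `imf_set` from [emd()].
#' @return An [ecg_signal()] holding IMF 1 (the highest-frequency
#'   component).
#' @export
recover_first_imf <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  if (length(imfset$imfs) == 0L) {
    stop("no IMFs: the input had no oscillatory component", call. = FALSE)
  }
  fs <- if (is.na(imfset$fs)) 1 else imfset$fs
  ecg_signal(imfset$imfs[[1L]], fs, label = "EMD recovered (IMF 1)")
}

# Strict local extrema (plateau midpoints count once).
find_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  # collapse zero slopes to the sign of the next nonzero slope
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) == 0L) {
    return(list(max_idx = integer(0), min_idx = integer(0)))
  }
  # forward-fill signs over plateaus
  s_filled <- s
  last <- 0
  for (i in seq_len(n - 1L)) {
    if (s_filled[i] == 0) s_filled[i] <- last else last <- s_filled[i]
  }
  ds <- diff(s_filled)
  max_idx <- which(ds < 0) + 1L
  min_idx <- which(ds > 0) + 1L
  list(max_idx = max_idx, min_idx = min_idx)
}

# Cubic spline through (idx, val), extended by mirroring the two outermost
# extrema across each end so the envelope does not splay at the boundaries.
spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  if (k >= 2L) {
    left_idx <- 2L * 1L - idx[2L]
    right_idx <- 2L * n - idx[k - 1L]
    xs <- c(left_idx, idx, right_idx)
    ys <- c(val[2L], val, val[k - 1L])
  } else {
    xs <- idx
    ys <- val
  }
  f <- stats::splinefun(xs, ys, method = "natural")
  f(seq_len(n))
}

is_monotone <- function(x) {
  d <- diff(x)
  all(d >= 0) || all(d <= 0)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

imf_property_holds <- function(h) {
  e <- find_extrema(h)
  n_ext <- length(e$max_idx) + length(e$min_idx)
  abs(n_ext - count_zero_crossings(h)) <= 1L
}

#' One-sided periodogram power spectral density
#'
#' `P[k] = |X[k]|^2 / (N * fs)`, doubled on interior bins so that
#' `sum(P) * (fs / N)` equals the mean square of the input (one-sided
#' Parseval identity).
#'
#' @param sequence Numeric vector, length >= 8.
#' @param fs Sampling rate, Hz.
#' @return List with `frequency` (Hz, DC..Nyquist) and `power`.
#' @export
psd <- function(sequence, fs) {
  x <- as_samples(sequence)
  if (length(x) < 8L) stop("need at least 8 samples", call. = FALSE)
  n <- length(x)
  X <- stats::fft(x)
  nh <- floor(n / 2)
  p <- Mod(X[1:(nh + 1L)])^2 / (n * fs)
  dbl <- 2:(if (n %% 2L == 0L) nh else nh + 1L)
  p[dbl] <- 2 * p[dbl]
  list(frequency = (0:nh) * fs / n, power = p)
}
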