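#' Fuse per-domain features into a single vector
#'
#' Pure concatenation in the fixed, documented order
#' `time || freq || timefreq || hrv || zcr || mode_summary`; values are
#' copied, never transformed, so every named feature is recoverable
#' bit-exactly from its slot (see [split_features()]). Element names carry
#' a domain prefix (`time.mean`, `freq.spectral_centroid`,
#' `hrv.sdnn`, ...).
#'
#' @param time List from [time_domain_features()] (the `degenerate` flag
#'   is dropped).
#' @param freq List from [frequency_features()].
#' @param timefreq List from [timefreq_features()].
#' @param hrv List from [hrv_metrics()].
#' @param zcr List from [zcr()] (the per-sample `rate` is fused).
#' @param mode_summary Named numeric vector of decomposition summaries
#'   (per-mode energy and centre frequency, first-IMF energy and dominant
#'   frequency); see [mode_summary_features()].
#' @return Named numeric vector (the fused feature vector).
#' @export
fuse_features <- function(time, freq, timefreq, hrv, zcr, mode_summary) {
  need <- list(time = time, freq = freq, timefreq = timefreq, hrv = hrv,
               zcr = zcr, mode_summary = mode_summary)
  for (nm in names(need)) {
    if (is.null(need[[nm]]) || length(need[[nm]]) == 0L) {
      stop(sprintf("missing feature domain: %s", nm), call. = FALSE)
    }
  }
  take <- function(lst, keys, prefix) {
    miss <- setdiff(keys, names(lst))
    if (length(miss) > 0L) {
      stop(sprintf("domain `%s` is missing: %s", prefix,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    v <- vapply(keys, function(k) as.numeric(lst[[k]]), numeric(1))
    names(v) <- paste0(prefix, ".", keys)
    v
  }
  ms <- as.numeric(mode_summary)
  if (is.null(names(mode_summary))) {
    stop("`mode_summary` must be a named vector", call. = FALSE)
  }
  names(ms) <- paste0("mode.", names(mode_summary))
  fused <- c(
    take(time, c("mean", "std", "rms", "skewness", "kurtosis"), "time"),
    take(freq, c("dominant_frequency", "spectral_centroid",
                 "spectral_spread", "spectral_entropy", "spectral_rolloff"),
         "freq"),
    take(timefreq, c("mean_frequency", "mean_spectral_entropy"), "tf"),
    take(hrv, c("sdnn", "rmssd", "nn50", "pnn50", "mean_hr"), "hrv"),
    take(zcr, "rate", "zcr"),
    ms
  )
  if (!all(is.finite(fused))) {
    bad <- names(fused)[!is.finite(fused)]
    stop(sprintf("non-finite fused features: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fused
}

#' Split a fused vector back into its domains
#'
#' Inverse of [fuse_features()], keyed on the documented name prefixes.
#'
#' @param fused Named numeric vector from [fuse_features()].
#' @return List with elements `time`, `freq`, `timefreq`, `hrv`, `zcr`,
#'   `mode_summary`, each a named numeric vector with prefixes stripped.
#' @export
split_features <- function(fused) {
  stopifnot(is.numeric(fused), !is.null(names(fused)))
  pick <- function(prefix) {
    sel <- startsWith(names(fused), paste0(prefix, "."))
    v <- fused[sel]
    names(v) <- sub(paste0("^", prefix, "\\."), "", names(v))
    v
  }
  list(time = pick("time"), freq = pick("freq"), timefreq = pick("tf"),
       hrv = pick("hrv"), zcr = pick("zcr"), mode_summary = pick("mode"))
}

#' Decomposition summary features
#'
#' Per-VMD-mode energy (mean square) and centre frequency, plus the energy
#' and dominant frequency (periodogram argmax) of the first IMF.
#'
#' @param modeset A `mode_set` from [vmd()] or [adaptive_refine()].
#' @param imfset An `imf_set` from [emd()].
#' @return Named numeric vector of length `2 * K + 2`.
#' @export
mode_summary_features <- function(modeset, imfset) {
  stopifnot(inherits(modeset, "mode_set"), inherits(imfset, "imf_set"))
  K <- ncol(modeset$modes)
  out <- numeric(0)
  for (k in seq_len(K)) {
    out[sprintf("mode%d_energy", k)] <- mean(modeset$modes[, k]^2)
    out[sprintf("mode%d_center_frequency", k)] <-
      modeset$center_frequencies[k]
  }
  imf1 <- recover_first_imf(imfset)
  ps <- psd(imf1$samples, imf1$fs)
  out["imf1_energy"] <- mean(imf1$samples^2)
  out["imf1_dominant_frequency"] <- ps$frequency[which.max(ps$power)]
  out
}

#' Extract the full feature bundle for a signal
#'
#' Orchestrates the per-domain extractors on a (reconstructed) signal and
#' returns the bundle together with the fused vector.
#'
#' @param signal An [ecg_signal()] (typically the denoised
#'   reconstruction).
#' @param modeset,imfset Decomposition results for the mode summaries.
#' @param peaks R-peak indices; detected with [detect_r_peaks()] when
#'   `NULL`.
#' @param stft_window,stft_hop STFT frame parameters in samples (defaults:
#'   1 s Hann window, 50% hop).
#' @param energy_fraction Spectral rolloff fraction.
#' @return A list of class `feature_bundle` with elements `time`, `freq`,
#'   `timefreq`, `hrv`, `zcr`, `mode_summary`, `fused`, `peaks`.
#' @export
extract_feature_bundle <- function(signal, modeset, imfset, peaks = NULL,
                                   stft_window = NULL, stft_hop = NULL,
                                   energy_fraction = 0.85) {
  stopifnot(inherits(signal, "ecg_signal"))
  fs <- signal$fs
  if (is.null(peaks)) peaks <- detect_r_peaks(signal)
  time_f <- time_domain_features(signal$samples)
  freq_f <- frequency_features(as_one_sided(dft(signal$samples, fs)),
                               energy_fraction = energy_fraction)
  grid <- stft(signal$samples, window = stft_window, hop = stft_hop, fs = fs)
  tf_f <- timefreq_features(grid)
  hrv_f <- hrv_metrics(rr_intervals(peaks, fs))
  zcr_f <- zcr(signal$samples, fs)
  ms <- mode_summary_features(modeset, imfset)
  fused <- fuse_features(time_f, freq_f, tf_f, hrv_f, zcr_f, ms)
  structure(list(time = time_f, freq = freq_f, timefreq = tf_f,
                 hrv = hrv_f, zcr = zcr_f, mode_summary = ms,
                 fused = fused, peaks = peaks),
            class = "feature_bundle")
}

#' @export
print.feature_bundle <- function(x, ...) {
  cat(sprintf("<feature_bundle> fused length %d (%d R peaks)\n",
              length(x$fused), length(x$peaks)))
  print(round(x$fused, 4))
  invisible(x)
}

#' Export a fused feature vector as single-row CSV
#'
#' The header names every slot with its domain prefix, so the file is
#' self-describing and re-splittable.
#'
#' @param bundle A `feature_bundle` (or a named fused vector).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_csv <- function(bundle, path) {
  fused <- if (inherits(bundle, "feature_bundle")) bundle$fused else bundle
  df <- as.data.frame(as.list(fused), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a feature bundle as JSON
#'
#' @param bundle A `feature_bundle`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_json <- function(bundle, path) {
  stopifnot(inherits(bundle, "feature_bundle"))
  payload <- list(time = bundle$time, freq = bundle$freq,
                  timefreq = bundle$timefreq, hrv = bundle$hrv,
                  zcr = bundle$zcr,
                  mode_summary = as.list(bundle$mode_summary),
                  fused = as.list(bundle$fused),
                  peaks = bundle$peaks)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
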