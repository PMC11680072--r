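#' Construct an ECG signal object
#'
#' The basic container passed between pipeline stages: a real-valued sample
#' sequence, its sampling rate, and (optionally) ground-truth R-peak
#' annotations. Annotations are 1-based sample indices, strictly increasing
#' and within the signal; times are seconds and frequencies Hz throughout
#' the package.
#'
#' @param samples Numeric vector of samples (arbitrary amplitude units).
#' @param fs Sampling rate in Hz (single positive number).
#' @param annotations Optional integer vector of R-peak sample indices
#'   (1-based), strictly increasing, all within `[1, length(samples)]`.
#' @param label Free-text label.
#' @return An object of class `ecg_signal`: a list with elements `samples`,
#'   `fs`, `annotations`, `label`.
#' @examples
#' s <- ecg_signal(sin(2 * pi * 1 * seq(0, 2, by = 1 / 250)), fs = 250)
#' s
#' @export
ecg_signal <- function(samples, fs, annotations = NULL, label = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  fs <- as.numeric(fs)
  if (length(samples) > 0L && !all(is.finite(samples))) {
    stop("all samples must be finite", call. = FALSE)
  }
  if (!is.null(annotations)) {
    annotations <- as.integer(round(annotations))
    if (length(annotations) > 1L && is.unsorted(annotations, strictly = TRUE)) {
      stop("annotations must be strictly increasing", call. = FALSE)
    }
    if (length(annotations) > 0L &&
        (min(annotations) < 1L || max(annotations) > length(samples))) {
      stop("annotations must lie within the signal", call. = FALSE)
    }
  }
  structure(
    list(samples = samples, fs = fs, annotations = annotations,
         label = as.character(label)[1L]),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (nzchar(x$label)) paste0(" \"", x$label, "\"") else ""))
  if (!is.null(x$annotations)) {
    cat(sprintf("  %d annotated R peaks\n", length(x$annotations)))
  }
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

# Accept either an ecg_signal or a bare numeric vector; returns numeric.
as_samples <- function(x) {
  if (inherits(x, "ecg_signal")) x$samples else as.numeric(x)
}

signal_fs <- function(x, fs = NULL) {
  if (!is.null(fs)) return(fs)
  if (inherits(x, "ecg_signal")) return(x$fs)
  stop("`fs` is required when the input is a bare numeric vector",
       call. = FALSE)
}
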