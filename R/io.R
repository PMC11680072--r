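#' Read an ECG signal from disk
#'
#' Two on-disk layouts are supported. `"text"` is a single-column delimited
#' file, one sample per line; blank lines and lines starting with `#` are
#' ignored. If a JSON sidecar `<path>.json` exists (written by
#' [write_signal()]) the sampling rate, annotations and label are taken
#' from it, otherwise `fs` must be given. `"container"` is a key-to-array
#' JSON dictionary holding several labelled recordings (the portable
#' equivalent of a MAT-style dictionary file); `label` selects the entry.
#'
#' @param path File path.
#' @param format `"text"` or `"container"`.
#' @param fs Sampling rate in Hz; required for `"text"` without a sidecar.
#' @param label Entry label; required for `"container"`.
#' @return An [ecg_signal()].
#' @seealso [write_signal()], [read_container()]
#' @export
read_signal <- function(path, format = c("text", "container"), fs = NULL,
                        label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "container") {
    entries <- read_container(path)
    if (is.null(label)) {
      stop("`label` is required when reading from a container", call. = FALSE)
    }
    if (!label %in% names(entries)) {
      stop(sprintf("label not found in container: \"%s\" (available: %s)",
                   label, paste(names(entries), collapse = ", ")),
           call. = FALSE)
    }
    return(entries[[label]])
  }

  sidecar <- paste0(path, ".json")
  ann <- NULL
  lab <- ""
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(fs)) fs <- meta$fs
    if (!is.null(meta$annotations) && length(meta$annotations) > 0) {
      ann <- as.integer(meta$annotations)
    }
    if (!is.null(meta$label)) lab <- meta$label
  }
  if (is.null(fs)) {
    stop("`fs` is required for delimited-text signals without a sidecar",
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  data_lines <- lines[keep]
  if (length(data_lines) == 0L) {
    stop(sprintf("empty signal file: %s", path), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(data_lines))
  if (anyNA(vals)) {
    bad <- which(keep)[which(is.na(vals))[1L]]
    stop(sprintf("unparseable value at line %d of %s: \"%s\"",
                 bad, path, lines[bad]), call. = FALSE)
  }
  ecg_signal(vals, fs, annotations = ann, label = lab)
}

#' Write an ECG signal to disk
#'
#' The `"text"` format writes one sample per line with 15 significant
#' digits (so a read/write round trip preserves samples to better than
#' 1e-12 relative error) plus a JSON sidecar `<path>.json` carrying `fs`,
#' annotations and the label. Output bytes are deterministic for a fixed
#' input. The `"container"` format appends/replaces the signal's entry in a
#' JSON container (see [write_container()]); the signal's `label` is used
#' as the key and must be non-empty.
#'
#' @param signal An [ecg_signal()]; must be non-empty.
#' @param path Output path.
#' @param format `"text"` or `"container"`.
#' @return Invisibly, `path`.
#' @export
write_signal <- function(signal, path, format = c("text", "container")) {
  format <- match.arg(format)
  stopifnot(inherits(signal, "ecg_signal"))
  if (length(signal$samples) == 0L) {
    stop("refusing to write an empty signal", call. = FALSE)
  }
  if (format == "container") {
    if (!nzchar(signal$label)) {
      stop("container entries need a non-empty label", call. = FALSE)
    }
    entries <- if (file.exists(path)) read_container(path) else list()
    entries[[signal$label]] <- signal
    write_container(entries, path)
    return(invisible(path))
  }
  writeLines(sprintf("%.15g", signal$samples), path)
  meta <- list(fs = signal$fs, label = signal$label)
  if (!is.null(signal$annotations)) meta$annotations <- signal$annotations
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a signal container
#'
#' A container is a JSON dictionary mapping labels to recordings, each with
#' `fs`, `samples` and optional `annotations` -- the package's portable
#' stand-in for a MAT-style dictionary file.
#'
#' @param path Container path.
#' @return Named list of [ecg_signal()] objects.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  for (lab in names(raw)) {
    e <- raw[[lab]]
    ann <- if (!is.null(e$annotations) && length(e$annotations) > 0) {
      as.integer(e$annotations)
    } else NULL
    out[[lab]] <- ecg_signal(as.numeric(e$samples), e$fs,
                             annotations = ann, label = lab)
  }
  out
}

#' Write a signal container
#'
#' @param entries Named list of [ecg_signal()] objects; names are the
#'   container labels and must be unique and non-empty.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_container <- function(entries, path) {
  stopifnot(is.list(entries))
  labs <- names(entries)
  if (is.null(labs) || any(!nzchar(labs)) || anyDuplicated(labs)) {
    stop("container entries must have unique non-empty labels",
         call. = FALSE)
  }
  payload <- lapply(entries, function(s) {
    stopifnot(inherits(s, "ecg_signal"))
    e <- list(fs = s$fs, samples = s$samples)
    if (!is.null(s$annotations)) e$annotations <- s$annotations
    e
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
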