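#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: input (a path or an
#' in-memory signal), per-stage parameters, the cipher scheme, the output
#' directory and the master seed.
#'
#' @param input An [ecg_signal()], or a path readable by [read_signal()].
#' @param format,fs,label Passed to [read_signal()] when `input` is a
#'   path.
#' @param bandpass A [bandpass_spec()].
#' @param vmd A [vmd_settings()].
#' @param adaptive An [adaptive_vmd_params()], or `NULL` to skip the
#'   refinement stage.
#' @param stft_window,stft_hop STFT frame parameters (samples).
#' @param kestrel A [kestrel_params()]; its seed is overridden by `seed`.
#' @param scheme Cipher scheme for the final encryption.
#' @param output_dir Directory for the run artifacts.
#' @param seed Master seed, recorded in every output.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, format = "text", fs = NULL, label = NULL,
                            bandpass = bandpass_spec(),
                            vmd = vmd_settings(),
                            adaptive = adaptive_vmd_params(),
                            stft_window = NULL, stft_hop = NULL,
                            kestrel = kestrel_params(),
                            scheme = c("chacha20", "chacha12", "salsa20"),
                            output_dir = tempfile("ecgcrypt-run-"),
                            seed = 1L) {
  scheme <- match.arg(scheme)
  kestrel$seed <- as.integer(seed)
  structure(list(input = input, format = format, fs = fs, label = label,
                 bandpass = bandpass, vmd = vmd, adaptive = adaptive,
                 stft_window = stft_window, stft_hop = stft_hop,
                 kestrel = kestrel, scheme = scheme,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Serialize samples to bytes (IEEE double, little-endian) and back; the
# payload actually encrypted, so decryption recovers the signal exactly.
signal_to_bytes <- function(signal) {
  writeBin(signal$samples, raw(), size = 8L, endian = "little")
}

bytes_to_samples <- function(bytes) {
  readBin(bytes, "double", n = length(bytes) %/% 8L, size = 8L,
          endian = "little")
}

#' Run the full encryption pipeline
#'
#' Executes preprocess -> decompose (VMD, optional adaptive refinement,
#' reconstruction) -> feature extraction and fusion on the reconstructed
#' signal -> bio-key generation -> encryption of the raw signal bytes.
#' Writes the fused feature CSV, the feature-bundle JSON, the key files,
#' the ciphertext container, and a JSON run log carrying every parameter
#' and the seed. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with `signal`, `preprocessed`, `modeset`,
#'   `reconstruction`, `imfset`, `features` (a `feature_bundle`),
#'   `biokey`, `message`, and `paths` to all written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  signal <- stage("input", {
    if (inherits(config$input, "ecg_signal")) config$input
    else read_signal(config$input, format = config$format, fs = config$fs,
                     label = config$label)
  })
  pre <- stage("preprocess", preprocess(signal, config$bandpass))
  modeset <- stage("decompose", vmd(pre, config$vmd))
  if (!is.null(config$adaptive)) {
    modeset <- stage("decompose", adaptive_refine(modeset, config$adaptive))
  }
  recon <- stage("decompose", reconstruct(modeset))
  recon$annotations <- pre$annotations
  imfset <- stage("decompose", emd(pre))
  bundle <- stage("features",
                  extract_feature_bundle(recon, modeset, imfset,
                                         stft_window = config$stft_window,
                                         stft_hop = config$stft_hop))
  biokey <- stage("keygen", generate_biokey(bundle$fused, config$kestrel))
  message <- stage("encrypt",
                   encrypt(signal_to_bytes(signal), biokey, config$scheme))

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    features_csv = file.path(config$output_dir, "features.csv"),
    features_json = file.path(config$output_dir, "features.json"),
    key = file.path(config$output_dir, "key.bin"),
    ciphertext = file.path(config$output_dir, "signal.enc"),
    run_log = file.path(config$output_dir, "run.json")
  )
  stage("write", {
    write_feature_csv(bundle, paths$features_csv)
    write_feature_json(bundle, paths$features_json)
    write_key(biokey, paths$key)
    write_cipher_message(message, paths$ciphertext)
    log <- list(
      seed = config$seed,
      scheme = config$scheme,
      n_samples = length(signal$samples),
      fs = signal$fs,
      bandpass = unclass(config$bandpass),
      vmd = unclass(config$vmd),
      adaptive = if (is.null(config$adaptive)) NULL
                 else unclass(config$adaptive),
      stft = list(window = config$stft_window, hop = config$stft_hop),
      kestrel = unclass(config$kestrel),
      vmd_converged = modeset$converged,
      n_r_peaks = length(bundle$peaks),
      fused_length = length(bundle$fused)
    )
    jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE,
                         digits = NA, null = "null")
  })

  invisible(list(signal = signal, preprocessed = pre, modeset = modeset,
                 reconstruction = recon, imfset = imfset,
                 features = bundle, biokey = biokey, message = message,
                 paths = paths))
}

#' Decrypt a pipeline run's ciphertext back to samples
#'
#' Reads the ciphertext container and key files written by
#' [run_pipeline()] and recovers the original signal samples exactly.
#'
#' @param ciphertext_path Path to the `signal.enc` container.
#' @param key_path Path to the `key.bin` file.
#' @return Numeric vector of recovered samples.
#' @export
decrypt_run <- function(ciphertext_path, key_path) {
  message <- read_cipher_message(ciphertext_path)
  biokey <- read_key(key_path)
  bytes_to_samples(decrypt(message, biokey))
}
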