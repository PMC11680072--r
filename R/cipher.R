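scheme_info <- function(scheme) {
  switch(scheme,
    chacha20 = list(rounds = 20L, nonce_len = 12L),
    chacha12 = list(rounds = 12L, nonce_len = 12L),
    salsa20  = list(nonce_len = 8L),
    stop(sprintf("unknown scheme: %s", scheme), call. = FALSE)
  )
}

#' Stream-cipher keystream
#'
#' Generates the raw keystream of a ChaCha-family or Salsa20 cipher.
#' `chacha20` and `chacha12` use the 16-word state, quarter-round core and
#' 96-bit-nonce / 32-bit-block-counter layout of the public ChaCha
#' standard with 20 and 12 rounds respectively; `salsa20` uses the Salsa20
#' core with a 64-bit nonce and 64-bit counter. The counter advances per
#' 64-byte block, so
#' `keystream(len = 128) == c(keystream(len = 64), keystream(counter + 1,
#' len = 64))`.
#'
#' @param scheme `"chacha20"`, `"chacha12"` or `"salsa20"`.
#' @param key 32 raw bytes.
#' @param nonce 12 raw bytes (8 for salsa20).
#' @param counter Starting block counter (>= 0).
#' @param length Number of keystream bytes.
#' @return Raw vector of `length` bytes.
#' @export
keystream <- function(scheme = c("chacha20", "chacha12", "salsa20"),
                      key, nonce, counter = 0, length) {
  scheme <- match.arg(scheme)
  info <- scheme_info(scheme)
  if (!is.raw(key) || base::length(key) != 32L) {
    stop("key must be exactly 32 bytes (256 bits)", call. = FALSE)
  }
  if (!is.raw(nonce) || base::length(nonce) != info$nonce_len) {
    stop(sprintf("%s requires a %d-byte nonce", scheme, info$nonce_len),
         call. = FALSE)
  }
  if (counter < 0) stop("counter must be >= 0", call. = FALSE)
  if (length < 0) stop("length must be >= 0", call. = FALSE)
  if (length == 0) return(raw(0))
  if (scheme == "salsa20") {
    .salsa_keystream(key, nonce, counter, length)
  } else {
    .chacha_keystream(key, nonce, counter, length, info$rounds)
  }
}

#' Encrypt bytes with a bio-key
#'
#' Pure stream encryption `C_i = P_i XOR K_i` with the keystream of the
#' requested scheme, keyed by the bio-key's 256-bit final key and its
#' stored nonce (truncated to 8 bytes for salsa20). No authentication tag
#' is added: the scheme models the raw stream XOR, so ciphertexts are
#' malleable and an AEAD wrapper should be used where integrity matters.
#'
#' @param plaintext Raw vector.
#' @param biokey A `bio_key` (or any list with `final_key` and `nonce`).
#' @param scheme Cipher scheme.
#' @param counter Starting block counter (default 0).
#' @return A list of class `cipher_message`: `scheme`, `nonce`, `counter`,
#'   `ciphertext`.
#' @export
encrypt <- function(plaintext, biokey,
                    scheme = c("chacha20", "chacha12", "salsa20"),
                    counter = 0) {
  scheme <- match.arg(scheme)
  if (!is.raw(plaintext)) stop("plaintext must be raw bytes", call. = FALSE)
  info <- scheme_info(scheme)
  nonce <- biokey$nonce[seq_len(info$nonce_len)]
  ks <- keystream(scheme, biokey$final_key, nonce, counter,
                  length(plaintext))
  structure(list(scheme = scheme, nonce = nonce, counter = counter,
                 ciphertext = .xor_bytes(plaintext, ks)),
            class = "cipher_message")
}

#' Decrypt a cipher message
#'
#' Applies the identical keystream (`P_i = C_i XOR K_i`); an exact
#' involution, so `decrypt(encrypt(p, k), k)` returns `p` byte for byte.
#'
#' @param message A `cipher_message`.
#' @param biokey The `bio_key` used to encrypt.
#' @return Raw plaintext bytes.
#' @export
decrypt <- function(message, biokey) {
  stopifnot(inherits(message, "cipher_message"))
  info <- scheme_info(message$scheme)
  expected_nonce <- biokey$nonce[seq_len(info$nonce_len)]
  if (!identical(as.raw(message$nonce), as.raw(expected_nonce))) {
    stop("nonce mismatch between message and key", call. = FALSE)
  }
  ks <- keystream(message$scheme, biokey$final_key, message$nonce,
                  message$counter, length(message$ciphertext))
  .xor_bytes(message$ciphertext, ks)
}

CIPHER_MAGIC <- charToRaw("ECGX")
SCHEME_IDS <- c(chacha20 = 1L, chacha12 = 2L, salsa20 = 3L)

#' Write and read cipher-message containers
#'
#' Fixed binary layout so files interoperate across implementations:
#' magic `"ECGX"` (4 bytes), format version (1 byte, 0x01), scheme id
#' (1 byte: 1 chacha20, 2 chacha12, 3 salsa20), nonce length (1 byte),
#' nonce, counter (8 bytes little-endian), payload length (8 bytes
#' little-endian), payload.
#'
#' @param message A `cipher_message`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cipher_message <- function(message, path) {
  stopifnot(inherits(message, "cipher_message"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(CIPHER_MAGIC, con)
  writeBin(as.raw(1L), con)
  writeBin(as.raw(SCHEME_IDS[[message$scheme]]), con)
  writeBin(as.raw(length(message$nonce)), con)
  writeBin(as.raw(message$nonce), con)
  writeBin(uint64_le(message$counter), con)
  writeBin(uint64_le(length(message$ciphertext)), con)
  writeBin(message$ciphertext, con)
  invisible(path)
}

#' @rdname write_cipher_message
#' @export
read_cipher_message <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 7L || !identical(bytes[1:4], CIPHER_MAGIC)) {
    stop("not a cipher-message file (bad magic)", call. = FALSE)
  }
  if (bytes[5L] != as.raw(1L)) stop("unsupported format version", call. = FALSE)
  scheme <- names(SCHEME_IDS)[match(as.integer(bytes[6L]), SCHEME_IDS)]
  if (is.na(scheme)) stop("unknown scheme id", call. = FALSE)
  nlen <- as.integer(bytes[7L])
  pos <- 8L
  nonce <- bytes[pos:(pos + nlen - 1L)]
  pos <- pos + nlen
  counter <- le_uint64(bytes[pos:(pos + 7L)])
  pos <- pos + 8L
  plen <- le_uint64(bytes[pos:(pos + 7L)])
  pos <- pos + 8L
  ciphertext <- if (plen > 0) bytes[pos:(pos + plen - 1L)] else raw(0)
  structure(list(scheme = scheme, nonce = nonce, counter = counter,
                 ciphertext = ciphertext),
            class = "cipher_message")
}

uint64_le <- function(x) {
  out <- raw(8)
  x <- as.numeric(x)
  for (i in 1:8) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

le_uint64 <- function(bytes) {
  sum(as.numeric(bytes) * 256^(0:7))
}

#' Time the cipher schemes
#'
#' Measures median wall times for key generation, encryption and
#' decryption per scheme on a random message of `size` bytes, reported in
#' microseconds. Timings are hardware-dependent and are reported, never
#' asserted.
#'
#' @param fused Fused feature vector used for key generation.
#' @param schemes Schemes to time.
#' @param size Message size in bytes (default 4096).
#' @param repetitions Repetitions per measurement (>= 1, default 5).
#' @param params [kestrel_params()] for the timed key generation.
#' @return Data frame with one row per scheme and columns `scheme`,
#'   `encryption_time_us`, `decryption_time_us`, `keygen_time_us`,
#'   `total_time_us`.
#' @export
benchmark <- function(fused,
                      schemes = c("chacha20", "chacha12", "salsa20"),
                      size = 4096L, repetitions = 5L,
                      params = kestrel_params(population_size = 20L,
                                              iterations = 5L)) {
  if (repetitions < 1L) stop("need at least 1 repetition", call. = FALSE)
  med_time <- function(f) {
    ts <- vapply(seq_len(repetitions), function(i) {
      t0 <- as.numeric(Sys.time())
      f()
      as.numeric(Sys.time()) - t0
    }, numeric(1))
    stats::median(ts) * 1e6
  }
  plaintext <- as.raw(sample(0:255, size, replace = TRUE))
  rows <- lapply(schemes, function(sc) {
    kg <- med_time(function() generate_biokey(fused, params))
    key <- generate_biokey(fused, params)
    enc <- med_time(function() encrypt(plaintext, key, sc))
    msg <- encrypt(plaintext, key, sc)
    dec <- med_time(function() decrypt(msg, key))
    data.frame(scheme = sc, encryption_time_us = enc,
               decryption_time_us = dec, keygen_time_us = kg,
               total_time_us = enc + dec + kg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
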