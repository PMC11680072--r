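#' Parameters of the kestrel-inspired key search
#'
#' A population search with two moves: flight (probability 0.8, a large
#' exploratory perturbation) and perch (probability 0.2, a small local
#' one). Perturbation sizes are scaled by a light intensity that decays
#' with the half-life law `gamma_t = gamma0 * exp(-phi * t)`,
#' `phi = ln(2) / t_half`; when the decay constant exceeds 1 (i.e.
#' `t_half < ln 2`) the trail is considered new each round and candidates
#' re-randomize fully.
#'
#' @param population_size Number of candidates (default 200).
#' @param flight_prob,perch_prob Move probabilities; must sum to 1
#'   (defaults 0.8 / 0.2).
#' @param iterations Search rounds (default 50).
#' @param t_half Half-life period in round units (default 1.0).
#' @param gamma0 Initial light intensity in (0, 1] (default 1.0).
#' @param seed Integer seed driving every random draw of the key pipeline.
#' @return A list of class `kestrel_params`.
#' @export
kestrel_params <- function(population_size = 200L, flight_prob = 0.8,
                           perch_prob = 0.2, iterations = 50L,
                           t_half = 1.0, gamma0 = 1.0, seed = 1L) {
  population_size <- as.integer(population_size)
  if (population_size < 2L) stop("`population_size` must be >= 2", call. = FALSE)
  if (abs(flight_prob + perch_prob - 1) > 1e-12) {
    stop("`flight_prob` + `perch_prob` must equal 1", call. = FALSE)
  }
  if (!is.finite(t_half) || t_half <= 0) {
    stop("`t_half` must be > 0", call. = FALSE)
  }
  if (!is.finite(gamma0) || gamma0 <= 0 || gamma0 > 1) {
    stop("`gamma0` must be in (0, 1]", call. = FALSE)
  }
  structure(list(population_size = population_size,
                 flight_prob = flight_prob, perch_prob = perch_prob,
                 iterations = as.integer(iterations), t_half = t_half,
                 gamma0 = gamma0, seed = as.integer(seed)),
            class = "kestrel_params")
}

#' Half-life intensity decay
#'
#' `gamma_t = gamma0 * exp(-phi * t)` with decay constant
#' `phi = ln(0.5) / (-t_half) = ln(2) / t_half`, so the intensity halves
#' every `t_half`.
#'
#' @param gamma0 Initial intensity (> 0).
#' @param t_half Half-life period (> 0).
#' @param t Elapsed time (>= 0); vectorized.
#' @return `gamma_t`.
#' @examples
#' half_life_decay(1, 2, c(0, 2, 4))
#' @export
half_life_decay <- function(gamma0, t_half, t) {
  if (!is.finite(gamma0) || gamma0 <= 0) {
    stop("`gamma0` must be > 0", call. = FALSE)
  }
  if (!is.finite(t_half) || t_half <= 0) {
    stop("`t_half` must be > 0", call. = FALSE)
  }
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  phi <- log(2) / t_half
  gamma0 * exp(-phi * t)
}

#' Trail freshness indicator
#'
#' Returns 1 when the decay constant strictly exceeds 1 (the trail decays
#' within a single round and is treated as new), else 0. The boundary
#' `phi = 1` maps to 0 (strict inequality).
#'
#' @param phi Decay constant (finite); vectorized.
#' @return Integer 0/1.
#' @export
trail_is_new <- function(phi) {
  if (any(!is.finite(phi))) stop("`phi` must be finite", call. = FALSE)
  as.integer(phi > 1)
}

# Binarize gamma values (>= 0.5 -> 1) and mix in the candidate's random
# bitstream, keeping the bit length at m.
candidate_bits <- function(gamma, rand_bits) {
  as.integer(xor(gamma >= 0.5, rand_bits == 1L))
}

bits_to_bytes <- function(bits) {
  stopifnot(length(bits) %% 8L == 0L)
  packBits(as.integer(bits), type = "raw")
}

new_candidate <- function(m) {
  gamma <- stats::runif(m)
  rand_bits <- sample(0:1, m, replace = TRUE)
  bits <- candidate_bits(gamma, rand_bits)
  fitness <- shannon_entropy(bits_to_bytes(bits))
  list(gamma = gamma, rand_bits = rand_bits, bits = bits, fitness = fitness)
}

#' Initialize a kestrel population
#'
#' Each candidate holds `m` light-intensity values drawn uniformly from
#' `[0, 1]` plus a random bitstream; its key bits are the binarized
#' intensities mixed with the bitstream, and its fitness is the Shannon
#' entropy (bits/byte) of the packed key bytes. Deterministic given the
#' R random-number generator state; callers seed via
#' [generate_biokey()] or `set.seed()`.
#'
#' @param params A [kestrel_params()].
#' @param m Bits per candidate (>= 8, multiple of 8; default 256).
#' @return List of `population_size` candidates.
#' @export
init_population <- function(params, m = 256L) {
  stopifnot(inherits(params, "kestrel_params"))
  m <- as.integer(m)
  if (m < 8L || m %% 8L != 0L) {
    stop("`m` must be a multiple of 8, at least 8", call. = FALSE)
  }
  lapply(seq_len(params$population_size), function(i) new_candidate(m))
}

#' Run the kestrel search
#'
#' For each of `iterations` rounds every candidate moves in flight mode
#' (probability `flight_prob`: a large uniform perturbation of its
#' intensity values, scaled by the current half-life-decayed light
#' intensity) or perch mode (small local perturbation); when
#' [trail_is_new()] of the decay constant is 1, the candidate
#' re-randomizes completely. Fitness is the Shannon entropy of the
#' candidate's key bytes. The best candidate ever seen is retained
#' (elitism), with ties broken by the lowest candidate index, so the
#' winner's fitness never falls below the initial population maximum.
#'
#' @param population From [init_population()].
#' @param params A [kestrel_params()].
#' @return The winning candidate (list with `gamma`, `bits`, `fitness`).
#' @export
kestrel_search <- function(population, params) {
  if (length(population) == 0L) stop("empty population", call. = FALSE)
  stopifnot(inherits(params, "kestrel_params"))
  m <- length(population[[1L]]$gamma)
  phi <- log(2) / params$t_half
  renew <- trail_is_new(phi) == 1L

  best <- population[[1L]]
  for (cand in population) if (cand$fitness > best$fitness) best <- cand

  for (t in seq_len(params$iterations)) {
    intensity <- half_life_decay(params$gamma0, params$t_half, t)
    for (i in seq_along(population)) {
      cand <- population[[i]]
      if (renew) {
        cand <- new_candidate(m)
      } else {
        if (stats::runif(1) < params$flight_prob) {
          step <- intensity * stats::runif(m, -0.5, 0.5)
        } else {
          step <- intensity * stats::runif(m, -0.05, 0.05)
        }
        cand$gamma <- pmin(pmax(cand$gamma + step, 0), 1)
        cand$bits <- candidate_bits(cand$gamma, cand$rand_bits)
        cand$fitness <- shannon_entropy(bits_to_bytes(cand$bits))
      }
      population[[i]] <- cand
      if (cand$fitness > best$fitness) best <- cand
    }
  }
  best
}

#' Deterministic unique key from a fused feature vector
#'
#' The vector is serialized canonically (each value fixed-point with six
#' decimals, `|`-separated) and hashed with SHA-256, so identical feature
#' vectors always give identical digests while a 1e-6 change in any slot
#' flips on average half the digest bits.
#'
#' @param fused Non-empty finite numeric vector.
#' @return 32 raw bytes (256-bit digest).
#' @export
unique_feature_key <- function(fused) {
  fused <- as.numeric(fused)
  if (length(fused) == 0L) stop("empty feature vector", call. = FALSE)
  if (!all(is.finite(fused))) {
    stop("feature vector must be finite", call. = FALSE)
  }
  serialized <- paste(sprintf("%.6f", fused), collapse = "|")
  .sha256(charToRaw(serialized))
}

#' Assemble the final 256-bit key
#'
#' `final_key = SHA-256(unique_key || winner_bits)`: hashing the
#' concatenation compresses the biometric digest and the search's random
#' component down to the 256 bits a ChaCha20 key requires. A fresh 96-bit
#' nonce is drawn from the seeded generator and stored with the key.
#'
#' @param unique_key 32 raw bytes from [unique_feature_key()].
#' @param winner Winning candidate from [kestrel_search()].
#' @param params The [kestrel_params()] used (stored as provenance).
#' @return A list of class `bio_key`: `unique_feature_key`,
#'   `random_component` (winner bits), `final_key` (32 raw bytes),
#'   `nonce` (12 raw bytes), `provenance`.
#' @export
generate_final_key <- function(unique_key, winner, params) {
  stopifnot(is.raw(unique_key), length(unique_key) == 32L)
  final_key <- .sha256(c(unique_key, bits_to_bytes(winner$bits)))
  nonce <- as.raw(sample(0:255, 12L, replace = TRUE))
  structure(
    list(unique_feature_key = unique_key,
         random_component = winner$bits,
         final_key = final_key,
         nonce = nonce,
         provenance = list(params = unclass(params),
                           winner_fitness = winner$fitness)),
    class = "bio_key"
  )
}

#' @export
print.bio_key <- function(x, ...) {
  cat("<bio_key> 256-bit key:",
      paste(format(x$final_key[1:8]), collapse = ""), "...\n")
  cat("  nonce:", paste(format(x$nonce), collapse = ""),
      sprintf(" winner fitness %.4f bits/byte\n",
              x$provenance$winner_fitness))
  invisible(x)
}

#' Generate a bio-key from a fused feature vector
#'
#' End-to-end key generation: seeds the generator, initializes and runs
#' the kestrel search, hashes the fused vector into the unique feature
#' key, and assembles the final 256-bit key plus nonce. The pair
#' (fused vector, seed) fully determines the result.
#'
#' @param fused Fused feature vector (named numeric).
#' @param params A [kestrel_params()]; its `seed` drives all randomness.
#' @param m Bits per candidate (default 256).
#' @return A `bio_key`.
#' @export
generate_biokey <- function(fused, params = kestrel_params(), m = 256L) {
  set.seed(params$seed)
  population <- init_population(params, m)
  winner <- kestrel_search(population, params)
  uk <- unique_feature_key(fused)
  key <- generate_final_key(uk, winner, params)
  key$provenance$fused_vector_sha256 <-
    paste(format(unique_feature_key(fused)), collapse = "")
  key
}

#' Write and read key files
#'
#' The binary file holds the 32-byte key followed by the 12-byte nonce;
#' a JSON sidecar `<path>.json` records the provenance (search
#' parameters, seed, fused-vector hash).
#'
#' @param biokey A `bio_key`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_key <- function(biokey, path) {
  stopifnot(inherits(biokey, "bio_key"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(biokey$final_key, biokey$nonce), con)
  jsonlite::write_json(biokey$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_key
#' @return `read_key` returns a list with `final_key` (32 raw bytes),
#'   `nonce` (12 raw bytes) and any provenance found in the sidecar.
#' @export
read_key <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) != 44L) {
    stop("key file must be exactly 44 bytes (32 key + 12 nonce)",
         call. = FALSE)
  }
  prov <- NULL
  if (file.exists(paste0(path, ".json"))) {
    prov <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
  }
  structure(list(unique_feature_key = NULL, random_component = NULL,
                 final_key = bytes[1:32], nonce = bytes[33:44],
                 provenance = prov),
            class = "bio_key")
}

#' Shannon entropy of a byte sequence
#'
#' `-sum(p_i log2 p_i)` over the empirical distribution of byte values;
#' the randomness score used as kestrel fitness and for key evaluation.
#' Maximum 8 bits/byte for uniformly distributed bytes.
#'
#' @param bytes Raw vector (non-empty).
#' @return Bits per symbol.
#' @export
shannon_entropy <- function(bytes) {
  if (!is.raw(bytes)) bytes <- as.raw(bytes)
  if (length(bytes) == 0L) stop("empty byte sequence", call. = FALSE)
  counts <- tabulate(as.integer(bytes) + 1L, nbins = 256L)
  p <- counts[counts > 0] / length(bytes)
  -sum(p * log2(p))
}

#' Min-entropy of a byte sequence
#'
#' `-log2(max_i p_i)`: the worst-case randomness of the most likely byte.
#'
#' @param bytes Raw vector (non-empty).
#' @return Bits.
#' @export
min_entropy <- function(bytes) {
  if (!is.raw(bytes)) bytes <- as.raw(bytes)
  if (length(bytes) == 0L) stop("empty byte sequence", call. = FALSE)
  counts <- tabulate(as.integer(bytes) + 1L, nbins = 256L)
  -log2(max(counts) / length(bytes))
}
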