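# Independent oracles: explicit-loop or naive implementations used only to
# check the package's vectorized code paths.

hrv_oracle <- function(iv) {
  n <- length(iv)
  mean_rr <- sum(iv) / n
  acc <- 0
  for (i in seq_len(n)) acc <- acc + (iv[i] - mean_rr)^2
  sdnn <- sqrt(acc / (n - 1))
  acc2 <- 0
  nn50 <- 0
  for (i in seq_len(n - 1)) {
    d <- iv[i + 1] - iv[i]
    acc2 <- acc2 + d^2
    if (abs(d) > 0.050) nn50 <- nn50 + 1
  }
  list(sdnn = sdnn, rmssd = sqrt(acc2 / (n - 1)), nn50 = nn50,
       pnn50 = 100 * nn50 / (n - 1), mean_hr = 60 / mean_rr)
}

entropy_oracle <- function(bytes) {
  vals <- as.integer(bytes)
  h <- 0
  for (b in unique(vals)) {
    p <- sum(vals == b) / length(vals)
    h <- h - p * log2(p)
  }
  h
}

min_entropy_oracle <- function(bytes) {
  vals <- as.integer(bytes)
  pmax <- max(table(vals)) / length(vals)
  -log2(pmax)
}

# O(n^2) textbook DFT for small n.
dft_naive <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
}

# RFC 8439 section 2.3.2 keystream block (key 00..1f, nonce
# 000000090000004a00000000, counter 1) and section 2.4.2 ciphertext.
rfc8439_keyblock_hex <- paste0(
  "10f1e7e4d13b5915500fdd1fa32071c4c7d1f4c733c068030422aa9ac3d46c4e",
  "d2826446079faa0914c2d705d98b02a2b5129cd1de164eb9cbd083e8a2503c4e")

rfc8439_ct_hex <- paste0(
  "6e2e359a2568f98041ba0728dd0d6981e97e7aec1d4360c20a27afccfd9fae0b",
  "f91b65c5524733ab8f593dabcd62b3571639d624e65152ab8f530c359f0861d8",
  "07ca0dbf500d6a6156a38e088a22b65e52bc514d16ccf806818ce91ab7793736",
  "5af90bbf74a35be6b40b8eedf2785e42874d")

hex_to_raw <- function(h) {
  as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)),
                base = 16L))
}

raw_to_hex <- function(r) paste(format(r), collapse = "")

hamming_bits <- function(a, b) {
  sum(as.integer(xor(rawToBits(a) == as.raw(1), rawToBits(b) == as.raw(1))))
}
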