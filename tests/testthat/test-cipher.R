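test_that("chacha20 reproduces the published standard test vectors", {
  key <- as.raw(0:31)
  nonce <- hex_to_raw("000000090000004a00000000")
  ks <- keystream("chacha20", key, nonce, counter = 1, length = 64)
  expect_identical(raw_to_hex(ks), rfc8439_keyblock_hex)

  nonce2 <- hex_to_raw("000000000000004a00000000")
  pt <- charToRaw(paste0("Ladies and Gentlemen of the class of '99: ",
                         "If I could offer you only one tip for the ",
                         "future, sunscreen would be it."))
  ks2 <- keystream("chacha20", key, nonce2, counter = 1,
                   length = length(pt))
  ct <- ecgcrypt:::.xor_bytes(pt, ks2)
  expect_identical(raw_to_hex(ct), rfc8439_ct_hex)
})

test_that("the block counter is consistent across call boundaries", {
  key <- as.raw(sample(0:255, 32, TRUE))
  for (sc in c("chacha20", "chacha12", "salsa20")) {
    nlen <- if (sc == "salsa20") 8L else 12L
    nonce <- as.raw(sample(0:255, nlen, TRUE))
    whole <- keystream(sc, key, nonce, 0, 192)
    parts <- c(keystream(sc, key, nonce, 0, 64),
               keystream(sc, key, nonce, 1, 64),
               keystream(sc, key, nonce, 2, 64))
    expect_identical(whole, parts)
    expect_identical(keystream(sc, key, nonce, 0, 0), raw(0))
  }
})

test_that("key and nonce sizes are enforced with a named expectation", {
  key <- as.raw(1:32)
  expect_error(keystream("chacha20", as.raw(1:16), as.raw(1:12), 0, 8),
               "32 bytes")
  expect_error(keystream("chacha20", key, as.raw(1:8), 0, 8), "12-byte")
  expect_error(keystream("salsa20", key, as.raw(1:12), 0, 8), "8-byte")
})

test_that("encryption is a byte-exact involution across schemes", {
  k <- generate_biokey(c(f = 3.14), kestrel_params(population_size = 4,
                                                   iterations = 1,
                                                   seed = 12))
  set.seed(55)
  for (sc in c("chacha20", "chacha12", "salsa20")) {
    for (n in c(1, 63, 64, 65, 4096)) {
      p <- random_bytes(n)
      msg <- encrypt(p, k, sc)
      expect_identical(decrypt(msg, k), p)
      expect_length(msg$ciphertext, n)
      # C xor P recovers the keystream
      ks <- keystream(sc, k$final_key,
                      k$nonce[seq_len(if (sc == "salsa20") 8 else 12)],
                      0, n)
      expect_identical(ecgcrypt:::.xor_bytes(msg$ciphertext, p), ks)
    }
    # all-zero plaintext exposes the keystream directly
    z <- encrypt(as.raw(rep(0, 128)), k, sc)
    ks <- keystream(sc, k$final_key,
                    k$nonce[seq_len(if (sc == "salsa20") 8 else 12)],
                    0, 128)
    expect_identical(z$ciphertext, ks)
  }
})

test_that("a tampered nonce is rejected at decryption", {
  k <- generate_biokey(c(f = 1), kestrel_params(population_size = 4,
                                                iterations = 1, seed = 3))
  msg <- encrypt(as.raw(1:10), k, "chacha20")
  msg$nonce[1] <- xor(msg$nonce[1], as.raw(1))
  expect_error(decrypt(msg, k), "nonce mismatch")
})

test_that("cipher-message containers round trip bit-exactly", {
  k <- generate_biokey(c(f = 2), kestrel_params(population_size = 4,
                                                iterations = 1, seed = 8))
  p <- random_bytes(1000)
  msg <- encrypt(p, k, "salsa20", counter = 5)
  path <- withr::local_tempfile(fileext = ".enc")
  write_cipher_message(msg, path)
  back <- read_cipher_message(path)
  expect_identical(back$scheme, "salsa20")
  expect_identical(back$nonce, msg$nonce)
  expect_identical(back$counter, 5)
  expect_identical(back$ciphertext, msg$ciphertext)
  expect_identical(decrypt(back, k), p)
})

test_that("long keystreams look uniformly random", {
  k <- generate_biokey(c(f = 7), kestrel_params(population_size = 4,
                                                iterations = 1, seed = 4))
  for (sc in c("chacha20", "chacha12", "salsa20")) {
    nonce <- k$nonce[seq_len(if (sc == "salsa20") 8 else 12)]
    ks <- keystream(sc, k$final_key, nonce, 0, 1e5)
    expect_gte(shannon_entropy(ks), 7.98)
  }
})

test_that("the benchmark harness reports an additive row per scheme", {
  rep <- benchmark(c(f = 1, g = 2), size = 1024L, repetitions = 2L)
  expect_identical(nrow(rep), 3L)
  expect_setequal(rep$scheme, c("chacha20", "chacha12", "salsa20"))
  expect_equal(rep$total_time_us,
               rep$encryption_time_us + rep$decryption_time_us +
                 rep$keygen_time_us)
  expect_error(benchmark(c(f = 1), repetitions = 0), "repetition")
})
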