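test_that("time-domain moments match closed forms and a library oracle", {
  f <- time_domain_features(c(1, -1, 1, -1))
  expect_equal(f$mean, 0)
  expect_equal(f$rms, 1)

  z <- time_domain_features(rep(0, 10))
  expect_true(z$degenerate)
  expect_equal(z$skewness, 0)
  expect_equal(z$kurtosis, 0)

  set.seed(123)
  x <- rnorm(1e5)
  f <- time_domain_features(x)
  expect_lt(abs(f$skewness), 0.05)
  expect_lt(abs(f$kurtosis), 0.1)
  skip_if_not_installed("e1071")
  expect_equal(f$skewness, e1071::skewness(x, type = 1), tolerance = 1e-12)
  expect_equal(f$kurtosis, e1071::kurtosis(x, type = 1), tolerance = 1e-12)
  fp <- time_domain_features(x, kurtosis = "pearson")
  expect_equal(fp$kurtosis, f$kurtosis + 3)
})

test_that("dft matches a naive transform and inverts exactly", {
  set.seed(5)
  x <- rnorm(32)
  sp <- dft(x, fs = 32)
  expect_equal(sp$coefficients, dft_naive(x), tolerance = 1e-10)
  expect_equal(idft(sp), x, tolerance = 1e-9)
  # constant maps to a single DC coefficient
  spc <- dft(rep(3, 16))
  expect_equal(Mod(spc$coefficients[1]), 48)
  expect_lt(max(Mod(spc$coefficients[-1])), 1e-12)
  # cosine pair: two bins of magnitude N/2
  n <- 64
  k <- 5
  spk <- dft(cos(2 * pi * k * (0:(n - 1)) / n))
  mags <- Mod(spk$coefficients)
  expect_equal(sort(which(mags > 1e-8)), c(k + 1, n - k + 1))
  expect_equal(unname(mags[k + 1]), n / 2, tolerance = 1e-9)
})

test_that("frequency features follow their definitions", {
  # single active bin: a degenerate distribution
  co <- complex(real = rep(0, 33))
  co[11] <- 4   # 10 Hz bin on a 0..32 Hz one-sided grid
  sp <- structure(list(coefficients = co, frequency = 0:32, N = 64,
                       fs = 64, side = "one-sided"),
                  class = "ecg_spectrum")
  f <- frequency_features(sp)
  expect_equal(f$dominant_frequency, 10)
  expect_equal(f$spectral_centroid, 10)
  expect_equal(f$spectral_spread, 0)
  expect_equal(f$spectral_entropy, 0)
  expect_equal(f$spectral_rolloff, 10)

  # two equal-power bins average to the midpoint
  co2 <- complex(real = rep(0, 33))
  co2[c(11, 21)] <- 2
  sp2 <- sp; sp2$coefficients <- co2
  expect_equal(frequency_features(sp2)$spectral_centroid, 15)

  # flat spectrum: entropy log2(bins)
  sp3 <- sp; sp3$coefficients <- complex(real = rep(1, 33))
  expect_equal(frequency_features(sp3)$spectral_entropy, log2(33))

  sp4 <- sp; sp4$coefficients <- complex(real = rep(0, 33))
  expect_error(frequency_features(sp4), "all-zero")
})

test_that("stft framing and stationary-tone behaviour", {
  fs <- 500
  x <- tone(10, fs, 5000)
  g <- stft(x, fs = fs)
  expect_identical(ncol(g$magnitude), (5000L - 500L) %/% 250L + 1L)
  # every frame peaks within one bin of 10 Hz (grid step 1 Hz)
  peak_freqs <- g$frequency[apply(g$magnitude, 2, which.max)]
  expect_true(all(abs(peak_freqs - 10) <= 1))

  tf <- timefreq_features(g)
  expect_lt(abs(tf$mean_frequency - 10), 1)

  gz <- stft(rep(0, 2000), fs = fs)
  expect_true(all(gz$magnitude == 0))
  expect_error(timefreq_features(gz), "all-zero")
  expect_error(stft(x, hop = 0, fs = fs), "hop")

  # frame count formula on random geometry
  set.seed(9)
  for (i in 1:20) {
    n <- sample(100:2000, 1)
    win <- sample(10:min(200, n), 1)
    hop <- sample(1:win, 1)
    g <- stft(rnorm(n), window = win, hop = hop, fs = 100)
    expect_identical(ncol(g$magnitude), (n - win) %/% hop + 1L)
  }
})

test_that("zero-crossing counting follows the sign-transition rule", {
  expect_equal(zcr(rep(2, 50))$count, 0L)
  expect_equal(zcr(c(1, -1, 1, -1))$rate, 1.0)
  # zero sample bridging opposite signs counts once
  expect_equal(zcr(c(1, 0, -1))$count, 1L)
  # sine over m integer periods crosses 2m times
  fs <- 100
  for (m in c(3, 7, 12)) {
    n <- m * fs  # 1 Hz tone, m seconds
    x <- tone(1, fs, n, phase = pi / 7)  # avoid samples landing on zero
    expect_equal(zcr(x)$count, 2L * m)
  }
})

test_that("mse/rmse comparison matches closed forms and a loop oracle", {
  a <- rnorm(100)
  expect_equal(compare_signals(a, a), list(mse = 0, rmse = 0))
  d <- 0.3
  expect_equal(compare_signals(a, a - d)$mse, d^2, tolerance = 1e-12)
  expect_equal(compare_signals(a, a - d)$rmse, d, tolerance = 1e-12)
  set.seed(2)
  b <- rnorm(100)
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(compare_signals(a, b)$mse, acc / 100, tolerance = 1e-12)
  expect_error(compare_signals(a, b[1:50]), "equal length")
})

test_that("fusion is a canonical, lossless concatenation", {
  time_f <- time_domain_features(rnorm(100))
  co <- complex(real = runif(33) + 0.1)
  sp <- structure(list(coefficients = co, frequency = 0:32, N = 64,
                       fs = 64, side = "one-sided"),
                  class = "ecg_spectrum")
  freq_f <- frequency_features(sp)
  g <- stft(tone(5, 100, 500), fs = 100)
  tf_f <- timefreq_features(g)
  hrv_f <- hrv_metrics(c(0.8, 0.85, 0.79, 0.9))
  zcr_f <- zcr(rnorm(100))
  ms <- c(mode1_energy = 0.5, mode1_center_frequency = 4,
          imf1_energy = 0.1, imf1_dominant_frequency = 30)
  fused <- fuse_features(time_f, freq_f, tf_f, hrv_f, zcr_f, ms)
  expect_length(fused, 5 + 5 + 2 + 5 + 1 + 4)
  # round trip through the documented layout
  parts <- split_features(fused)
  expect_false("sdnn" %in% names(parts$time))
  expect_identical(unname(parts$hrv["sdnn"]), hrv_f$sdnn)
  expect_identical(unname(parts$time["kurtosis"]), time_f$kurtosis)
  expect_identical(unname(parts$mode_summary["imf1_energy"]), 0.1)
  expect_identical(unname(parts$zcr["rate"]), zcr_f$rate)
  # missing domain errors by name
  expect_error(fuse_features(time_f, freq_f, tf_f, hrv_f, zcr_f, NULL),
               "mode_summary")
})
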