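test_that("band-pass keeps in-band tones and attenuates out-of-band ones", {
  fs <- 500
  n <- 5000
  spec <- bandpass_spec(0.5, 40)
  amp_at <- function(freq) {
    y <- bandpass_filter(tone(freq, fs, n), spec, fs = fs)
    sp <- Mod(fft(y))[1:(n / 2)]
    2 * max(sp) / n
  }
  expect_lt(abs(amp_at(10) - 1), 0.05)
  # stop band: >= 20 dB down
  expect_lt(amp_at(100), 10^(-20 / 20))
  # zero in, zero out
  expect_equal(bandpass_filter(rep(0, 1000), spec, fs = fs), rep(0, 1000))
})

test_that("filtering is zero-phase (no lag on a clean fixture)", {
  ecg <- clean_ecg(seed = 2, duration = 10)
  y <- bandpass_filter(ecg)
  cc <- ccf(ecg$samples, y$samples, lag.max = 25, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
})

test_that("band edges are validated against Nyquist", {
  expect_error(bandpass_filter(tone(10, 100, 500),
                               bandpass_spec(0.5, 60), fs = 100),
               "Nyquist")
  expect_error(bandpass_spec(5, 5), "exceed")
})

test_that("min-max scaling maps extremes to 0 and 1 and preserves order", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 1)), c(0, 1))
  expect_error(minmax_normalize(c(5, 5, 5)), "degenerate")
  set.seed(42)
  x <- rnorm(200)
  z <- minmax_normalize(x)
  expect_true(all(z >= 0 & z <= 1))
  expect_equal(min(z), 0)
  expect_equal(max(z), 1)
  expect_identical(order(z), order(x))
})

test_that("preprocess centres the signal and keeps R-peak locations", {
  ecg <- clean_ecg(seed = 3)
  pre <- preprocess(ecg)
  expect_lt(abs(mean(pre$samples)), 1e-9)
  expect_true(all(pre$samples >= -1 & pre$samples <= 1))
  # R-peak argmax positions unchanged within one sample
  for (a in ecg$annotations[2:19]) {
    win <- (a - 50):(a + 50)
    before <- win[which.max(ecg$samples[win])]
    after <- win[which.max(pre$samples[win])]
    expect_lte(abs(before - after), 1)
  }
  expect_error(preprocess(ecg_signal(rep(1, 1000), 500)), "degenerate")
})
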