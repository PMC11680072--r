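test_that("all beats of a clean recording are recovered exactly", {
  ecg <- clean_ecg(seed = 7)
  pre <- preprocess(ecg)
  peaks <- detect_r_peaks(pre)
  expect_length(peaks, length(ecg$annotations))
  expect_true(all(abs(peaks - ecg$annotations) <= round(0.010 * 500)))
})

test_that("detection stays reliable under variable rhythm and noise", {
  ecg <- noisy_ecg(seed = 21, snr_db = 10, hr_mean = 75, hr_sd = 4)
  pre <- preprocess(ecg)
  peaks <- detect_r_peaks(pre)
  frac <- peak_match_fraction(peaks, ecg$annotations, 500)
  expect_gte(frac, 0.95)
})

test_that("degenerate detector inputs behave as specified", {
  expect_identical(detect_r_peaks(rep(0, 2000), fs = 500), integer(0))
  expect_error(detect_r_peaks(rnorm(100), fs = 500), "2 s")
})

test_that("RR intervals are plain successive differences", {
  rr <- rr_intervals(c(1L, 501L, 1001L), 500)
  expect_equal(rr$intervals, c(1, 1))
  expect_error(rr_intervals(42L, 500), "at least 2")
  expect_error(rr_intervals(c(10L, 5L), 500), "increasing")
  set.seed(31)
  for (i in 1:50) {
    peaks <- sort(sample(1:100000, sample(2:50, 1)))
    rr <- rr_intervals(peaks, 500)
    oracle <- numeric(length(peaks) - 1)
    for (j in seq_along(oracle)) oracle[j] <- (peaks[j + 1] - peaks[j]) / 500
    expect_identical(rr$intervals, oracle)
  }
})

test_that("HRV metrics agree with an explicit-loop oracle", {
  # hand-checked cases
  h <- hrv_metrics(c(0.8, 0.8, 0.8, 0.8))
  expect_equal(h$sdnn, 0)
  expect_equal(h$rmssd, 0)
  expect_equal(h$nn50, 0)
  expect_equal(h$pnn50, 0)
  expect_equal(h$mean_hr, 75)

  h2 <- hrv_metrics(c(0.7, 0.9))
  expect_equal(h2$sdnn, sqrt(0.02), tolerance = 1e-12)
  expect_equal(h2$rmssd, 0.2, tolerance = 1e-12)

  h3 <- hrv_metrics(c(0.80, 0.86))
  expect_equal(h3$nn50, 1)
  expect_equal(h3$pnn50, 100)

  set.seed(41)
  for (i in 1:200) {
    iv <- runif(sample(2:40, 1), 0.4, 1.4)
    got <- hrv_metrics(iv)
    want <- hrv_oracle(iv)
    for (k in names(want)) {
      expect_equal(got[[k]], want[[k]], tolerance = 1e-12)
    }
  }
  expect_error(hrv_metrics(0.8), "at least 2")
})

test_that("IBI histogram bins cover the observed range with fixed width", {
  rr <- rr_intervals(c(1L, 400L, 850L, 1300L, 1800L), 500)
  h <- ibi_histogram(rr)
  expect_equal(sum(h$counts), length(rr$intervals))
  expect_equal(diff(h$breaks)[1], 0.025, tolerance = 1e-12)
  expect_lte(h$breaks[1], min(rr$intervals))
  expect_gte(h$breaks[length(h$breaks)], max(rr$intervals))
})
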