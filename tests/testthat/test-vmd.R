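test_that("two well-separated tones are recovered as two modes", {
  fs <- 500
  t <- (0:9999) / fs
  x <- sin(2 * pi * 5 * t) + sin(2 * pi * 50 * t)
  ms <- vmd(x, vmd_settings(K = 2, alpha = 2000, tol = 1e-7), fs = fs)
  expect_true(ms$converged)
  expect_lt(abs(ms$center_frequencies[1] - 5), 1)
  expect_lt(abs(ms$center_frequencies[2] - 50), 1)
  rec <- rowSums(ms$modes)
  expect_lt(sqrt(sum((rec - x)^2) / sum(x^2)), 0.05)
})

test_that("mode bookkeeping: conservation, ordering, dimensions", {
  ecg <- preprocess(clean_ecg(seed = 5, duration = 4))
  ms <- vmd(ecg)
  expect_identical(dim(ms$modes), c(2000L, 5L))
  expect_lt(max(abs(rowSums(ms$modes) + ms$residual - ecg$samples)), 1e-8)
  expect_true(!is.unsorted(ms$center_frequencies))
  expect_true(all(ms$center_frequencies >= 0 &
                    ms$center_frequencies <= ecg$fs / 2))
})

test_that("degenerate inputs are handled", {
  ms <- vmd(rep(0, 100), vmd_settings(K = 3), fs = 100)
  expect_true(all(ms$modes == 0))
  expect_true(all(ms$center_frequencies == 0))
  expect_true(all(ms$residual == 0))
  expect_error(vmd(c(1, NA, 3, 4), vmd_settings(K = 1), fs = 10), "finite")
  expect_error(vmd(rnorm(5), vmd_settings(K = 5), fs = 10), "short")
  # odd-length input pads and trims transparently
  x <- tone(10, 100, 501)
  ms2 <- vmd(x, vmd_settings(K = 1), fs = 100)
  expect_length(ms2$residual, 501L)
})

test_that("adaptive refinement lowers the objective monotonically", {
  set.seed(7)
  fs <- 500
  t <- (0:1999) / fs
  x <- sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 30 * t) + rnorm(2000, 0, 0.1)
  ms <- vmd(x, vmd_settings(K = 3), fs = fs)
  ref <- adaptive_refine(ms)
  tr <- attr(ref, "objective_trajectory")
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) <= 0))
})

test_that("refinement is a no-op on an exact decomposition with no penalty", {
  ecg <- preprocess(clean_ecg(seed = 6, duration = 4))
  ms <- vmd(ecg)
  ref <- adaptive_refine(ms, adaptive_vmd_params(lambda = 0, gamma_reg = 0))
  expect_identical(ref$modes, ms$modes[, order(ms$center_frequencies),
                                       drop = FALSE])
  expect_identical(ref$residual, ms$residual)
})

test_that("a pathologically large learning rate raises a divergence error", {
  ecg <- preprocess(clean_ecg(seed = 8, duration = 4))
  ms <- vmd(ecg)
  expect_error(adaptive_refine(ms, adaptive_vmd_params(eta = 10)),
               "diverged")
})

test_that("reconstruction sums the selected modes only", {
  ecg <- preprocess(clean_ecg(seed = 9, duration = 4))
  ms <- vmd(ecg)
  all_modes <- reconstruct(ms)
  expect_equal(all_modes$samples, rowSums(ms$modes))
  one <- reconstruct(ms, 3)
  expect_identical(one$samples, ms$modes[, 3])
  expect_error(reconstruct(ms, integer(0)), "at least one")
  expect_error(reconstruct(ms, 9), "out of range")
  # exact decomposition of a band-limited signal reconstructs closely
  x <- tone(5, 500, 2000) + tone(40, 500, 2000)
  ms2 <- vmd(x, vmd_settings(K = 2), fs = 500)
  rec <- reconstruct(ms2)
  expect_lt(sqrt(sum((rec$samples - x)^2) / sum(x^2)), 0.05)
})
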