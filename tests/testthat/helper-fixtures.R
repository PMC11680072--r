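# Fixtures are generated in code, never stored: the synthetic generator is
# itself part of the package under test.

clean_ecg <- function(seed = 1L, duration = 20, hr_mean = 60, hr_sd = 0) {
  generate_ecg(synthetic_ecg_config(duration = duration, hr_mean = hr_mean,
                                    hr_sd = hr_sd, seed = seed))
}

# White noise scaled to the requested SNR relative to the clean signal power.
noisy_ecg <- function(seed = 1L, snr_db = 10, duration = 20, hr_mean = 60,
                      hr_sd = 0) {
  ref <- generate_ecg(synthetic_ecg_config(duration = duration,
                                           hr_mean = hr_mean, hr_sd = hr_sd,
                                           seed = seed))
  noise_sd <- sqrt(mean(ref$samples^2) / 10^(snr_db / 10))
  generate_ecg(synthetic_ecg_config(duration = duration, hr_mean = hr_mean,
                                    hr_sd = hr_sd, seed = seed,
                                    noise = list(white_sd = noise_sd)))
}

tone <- function(freq, fs, n, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * freq * (0:(n - 1)) / fs + phase)
}

# Fraction of true beats matched by a detection within tol_s seconds.
peak_match_fraction <- function(detected, truth, fs, tol_s = 0.010) {
  if (length(truth) == 0L) return(NA_real_)
  tol <- round(tol_s * fs)
  mean(vapply(truth, function(a) any(abs(detected - a) <= tol), logical(1)))
}

random_bytes <- function(n) as.raw(sample(0:255, n, replace = TRUE))
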