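# ecgcrypt

Turn a single-lead electrocardiogram into a 256-bit encryption key.

`ecgcrypt` is for researchers and engineers prototyping biometric
encryption on physiological time series — for instance securing data from
wearable or Internet-of-Medical-Things ECG sensors — who need every stage
of the chain to be inspectable and reproducible: signal conditioning,
mode decomposition, multi-domain feature fusion, bio-inspired key
derivation, and stream-cipher encryption.

## The method

Given a recording `x(t)` sampled at `fs` Hz:

1. **Preprocess** — zero-phase FIR band-pass (windowed-sinc, default
   0.5–40 Hz), min–max scaling `F_norm = (F − F_min)/(F_max − F_min)`,
   mean centring.
2. **Decompose** — variational mode decomposition
   `x(t) = Σᵢ Sᵢ(t) + n(t)` into `K = 5` band-limited modes
   (bandwidth constraint α = 2000, tolerance 1e-7), then gradient
   refinement of modes and noise under
   `Obj(s, n) = ‖x − Σ sᵢ − n‖² + Σ λᵢ‖sᵢ‖_p + γ‖n‖_q`,
   and reconstruction by summing modes (dropping the residual noise).
   Empirical mode decomposition runs alongside; its first IMF is the
   recovered high-frequency component.
3. **Extract & fuse features** — time-domain moments; spectral
   dominant frequency, centroid, spread, entropy, rolloff (via the DFT
   `X[k] = Σₙ x[n]e^{−j2πkn/N}`); STFT mean frequency and entropy; HRV
   metrics `SDNN = √(Σ(RRᵢ − meanRR)²/(N−1))`,
   `RMSSD = √(Σ(RRᵢ₊₁ − RRᵢ)²/(N−1))`, NN50, pNN50 from Pan–Tompkins
   R-peak detection; zero-crossing rate; per-mode summaries. All are
   concatenated into one fused vector
   `f_fused = [f_time ‖ f_freq ‖ f_timefreq ‖ f_hrv ‖ f_zcr ‖ f_modes]`.
4. **Generate the key** — `UniqueFeatureKey = SHA-256(f_fused)`, plus a
   random component from a kestrel-inspired population search (flight
   0.8 / perch 0.2 moves, half-life intensity decay
   `γ_t = γ₀e^{−t·ln2/t½}`, entropy fitness);
   `F_key = SHA-256(UniqueFeatureKey ‖ winner bits)`, 256 bits, with a
   96-bit nonce.
5. **Encrypt** — stream cipher `Cᵢ = Pᵢ ⊕ Kᵢ` with ChaCha20 (or
   ChaCha12 / Salsa20), decryption `Pᵢ = Cᵢ ⊕ Kᵢ`.

A synthetic ECG generator (Gaussian P-QRS-T morphology, programmable
heart rate, HRV and noise, known R-peak ground truth) makes the whole
chain testable without clinical data.

## Worked example

```r
library(ecgcrypt)

ecg <- generate_ecg(synthetic_ecg_config(duration = 20, hr_mean = 72,
                                         hr_sd = 3,
                                         noise = list(white_sd = 0.01),
                                         seed = 42))
ecg
#> <ecg_signal> 10000 samples @ 500 Hz (20.000 s) "synthetic hr=72 fs=500"
#>   24 annotated R peaks

res <- run_pipeline(pipeline_config(ecg, seed = 42,
                                    output_dir = tempfile()))
round(res$features$fused[c("hrv.sdnn", "hrv.rmssd", "hrv.mean_hr",
                           "zcr.rate", "freq.dominant_frequency")], 4)
#>                hrv.sdnn               hrv.rmssd             hrv.mean_hr
#>                  0.0450                  0.0601                 71.7927
#>                zcr.rate freq.dominant_frequency
#>                  0.0144                  4.7000

res$biokey
#> <bio_key> 256-bit key: d00254fc66c9feef ...
#>   nonce: 02a072df67cf83de2565970f  winner fitness 5.0000 bits/byte

recovered <- decrypt_run(res$paths$ciphertext, res$paths$key)
identical(recovered, ecg$samples)
#> [1] TRUE
```

Reading the numbers: the detected rhythm averages 71.8 bpm (the
generator was programmed at 72 with 3 bpm jitter), SDNN/RMSSD quantify
that beat-to-beat variability in seconds, the dominant spectral
component of the reconstructed signal sits at 4.7 Hz, and roughly 1.4%
of consecutive sample pairs change sign. The 30-element fused vector
plus the seed deterministically yield the printed 256-bit key, and
decrypting the run's ciphertext returns the original samples bit-exactly.

The same pipeline is scriptable from a shell via the thin CLI in
`inst/cli/ecgcrypt.R` (subcommands `simulate`, `preprocess`,
`decompose`, `features`, `keygen`, `encrypt`, `decrypt`, `entropy`,
`benchmark`, `run`).

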