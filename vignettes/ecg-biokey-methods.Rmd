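---
title: "From ECG to encryption key: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ECG to encryption key: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgcrypt)
```

## The problem

Biometric signals make attractive key material: an electrocardiogram is
hard to forge, easy to acquire from wearables, and person-specific.
`ecgcrypt` implements a complete pipeline from a single-lead ECG to a
256-bit stream-cipher key: clean the signal, decompose it into
band-limited modes, summarize it as a fused multi-domain feature vector,
hash that vector into a unique key, mix in randomness from a bio-inspired
population search, and encrypt with a ChaCha20-family cipher.

This vignette explains each stage's model, its tunable parameters, and
the design decisions taken where the procedure admitted more than one
reasonable reading. Every empirical claim here is one the package's test
suite or `scripts/acceptance.R` actually computes.

## Synthetic recordings as ground truth

Real single-lead recordings carry no certain beat annotations, so all
testing is built on a synthetic generator (`generate_ecg()`) whose R-peak
positions are known by construction. Each beat is the sum of five
Gaussian bumps (P, Q, R, S, T) at fixed offsets from the beat's R time --
the simplest morphology with analytically known peak locations, which is
exactly what R-peak detector tests need. The defaults emulate a 20-s,
500 Hz limb-lead recording (10,000 samples) whose raw amplitude spans
roughly ±0.35 units.

RR intervals are drawn i.i.d. as `60/hr_mean` plus zero-mean Gaussian
jitter of sd `60·hr_sd/hr_mean²` s, truncated below at 0.2 s; no
published generative HRV model is assumed. Noise is additive and comes
last: sinusoidal baseline wander, sinusoidal powerline interference, and
white Gaussian noise.

What the generator does *not* emulate: ectopic beats and arrhythmia,
motion artifacts, electrode pop, respiration-modulated morphology, and
inter-subject morphology variation. Tests passing on these fixtures
demonstrate algorithmic correctness, not clinical robustness.

## Preprocessing

The band-pass filter realizes the ideal band response as a difference of
two Hamming-windowed sinc low-pass kernels (cutoffs `f_high` and
`f_low`). Defaults: 0.5–40 Hz, the standard diagnostic ECG band, with
501 taps at 500 Hz (about 1 s of support, enough for a sharp 0.5 Hz
corner). The kernel is symmetric and applied centred with mirror padding,
so the filter is exactly zero-phase: the test suite checks that the
cross-correlation lag between input and output of a clean fixture is 0
samples, and that R-peak argmax positions move by at most one sample.

After filtering, samples are min–max scaled to [0, 1] and then mean
centred. The scaling and centring order was an open choice; scaling
first makes the amplitude range reproducible across recordings, and the
subsequent centring gives the zero-baseline signal that the spectral
decomposition stages expect. A constant (degenerate-range) signal is an
error, not a silent zero.

## Variational mode decomposition and its refinement

Stage one is canonical VMD: each of `K` modes is updated in the
frequency domain by a Wiener filter centred on its current centre
frequency, centre frequencies are re-estimated as power-weighted mean
frequencies, and a dual variable ascends with slack `noise_tolerance`.
The signal is mirror-extended by half its length on each side before the
spectral iteration, the standard boundary treatment. Defaults follow the
study conditions: `K = 5`, `alpha = 2000`, `tol = 1e-7`,
`noise_tolerance = 0`. Modes are returned sorted by ascending centre
frequency and the residual is defined as `signal - sum(modes)`, so
conservation holds to machine precision regardless of convergence.

Stage two is a gradient refinement under the noise-regularized objective

```
Obj(s, n) = ||x - sum_i s_i - n||^2 + sum_i lambda_i ||s_i||_p
            + gamma_reg ||n||_q
```

with plain gradient steps of rate `eta` on each mode and on the noise
estimate. The probabilistic reading of the decomposition (a likelihood
over modes and noise) motivates this objective but is not itself
implemented; the refinement optimizes `Obj` directly. Norm orders
default to `p = q = 2` (1 is also supported); weights default to
`lambda_i = gamma_reg = 1e-3`, small enough to act as a tie-breaker
toward low-energy noise rather than a distortion of the modes. With
`eta = 0.01` and `K = 5` the step size is far below the `2/L` stability
bound of the quadratic term (`L = 2(K+1)`), so the objective decreases
monotonically; the refinement stops when the per-step decrease falls
below `tol = 1e-9` and aborts with a divergence error after five
consecutive increases (which a pathological `eta` such as 10 triggers
immediately). When the decomposition is already exact and the penalty
weights are zero the gradient vanishes and the modes are returned
unchanged.

The study leaves open whether "reconstruction" sums all modes or a
subset; `reconstruct()` defaults to all modes (dropping only the
residual, which is the denoising step) and takes an index set for
subset reconstruction.

Note on symbols: the decay intensity of the key-generation stage and the
noise-regularization weight are both conventionally written as gamma;
they are unrelated, and the package names them `gamma0`/`gamma_t` and
`gamma_reg` respectively.

## Empirical mode decomposition

`emd()` implements classical sifting: cubic-spline envelopes through the
local maxima and minima (natural splines, with the two outermost extrema
mirrored across each boundary), subtract the envelope mean, repeat.
Sifting stops when the normalized squared sift-to-sift change falls
below 0.3 *and* the candidate satisfies the IMF count property (extrema
and zero crossings differing by at most one); requiring both keeps the
classical stop criterion while guaranteeing that every returned IMF is a
proper IMF. Decomposition stops at a monotone residue. Because sifting
is purely subtractive, `sum(imfs) + residue` equals the input to machine
precision. The first IMF carries the highest-frequency content and is
exposed as the "recovered" signal (`recover_first_imf()`); a monotone
input has no IMFs and recovery is an error.

## Feature extraction and fusion

All features are computed on the denoised reconstruction:

* **Time domain** (5): mean, sample sd, RMS, Fisher–Pearson skewness,
  and kurtosis. Kurtosis defaults to the *excess* convention
  (normal → 0); published kurtosis values do not always disambiguate the
  convention, so a flag switches to Pearson (normal → 3).
* **Frequency domain** (5): dominant frequency, spectral centroid,
  spread, entropy (bits), and rolloff at an energy fraction of 0.85
  (configurable; no standard value exists). Computed by default on the
  one-sided spectrum; a two-sided axis is available since centroid and
  rolloff on a symmetric two-sided spectrum land near zero or at
  negative frequencies, which reproduces the sign conventions seen in
  some published feature tables.
* **Time–frequency** (2): per-frame spectral centroid and entropy of an
  STFT (1 s Hann window, 50% hop at 500 Hz by default; a 1 s window
  resolves 1 Hz while still giving ~39 frames on a 20 s record),
  averaged over frames.
* **HRV** (5): SDNN, RMSSD, NN50, pNN50 and mean heart rate from the
  detected R peaks. The NN50 threshold is the standard 50 ms, strict
  inequality. Mean heart rate is `60/meanRR` in bpm.
* **ZCR** (1): sign transitions between consecutive nonzero-signed
  samples divided by `N - 1`; a zero sample bridging opposite signs
  counts once. The continuous-time definition via the derivative of the
  sign function does not discretize uniquely; this convention is the
  package's documented choice, with the per-second rate also reported.
* **Mode summaries** (2K + 2): per-VMD-mode energy and centre
  frequency, plus first-IMF energy and dominant frequency.

R peaks come from a Pan–Tompkins style detector (5–15 Hz band, centred
five-point derivative, squaring, 150 ms centred integration window,
adaptive SPKI/NPKI thresholds, 200 ms refractory period), with each
detection refined to the local signal maximum within ±75 ms. Every
internal filter is centred, so the chain introduces no systematic lag.

`fuse_features()` concatenates the domains in the fixed order
`time ‖ freq ‖ timefreq ‖ hrv ‖ zcr ‖ mode_summary` — 30 values at the
default `K = 5` — copying values untransformed, so the fused vector
re-splits losslessly by its documented names.

## Key generation

The fused vector is serialized canonically (fixed-point, six decimals,
`|`-separated) and hashed with SHA-256 into the *unique feature key*.
Six decimals resolve every feature scale in the fused vector while
making key regeneration tolerant of sub-1e-6 arithmetic noise;
a change of 1e-6 in any slot flips on average half the digest bits
(the avalanche measurement in the acceptance script).

The random component comes from a kestrel-inspired population search.
Each of 200 candidates holds 256 intensity values in [0, 1]; its key
bits are the binarized intensities mixed (XOR) with a per-candidate
random bitstream — the "random bit generator" appended to the
population, kept at 256 bits so every candidate is key-sized. Each
round, a candidate takes a flight move (probability 0.8, large uniform
perturbation) or a perch move (probability 0.2, small one), scaled by a
light intensity that decays with the half-life law
`gamma_t = gamma0 · exp(-t · ln2 / t_half)`; if the decay constant
exceeds 1 (half-life shorter than ln 2 rounds) the trail is treated as
new and the candidate re-randomizes fully. The search needs a fitness
the source procedure never specifies; the package uses the Shannon
entropy (bits/byte) of the candidate's packed key bytes, since entropy
is exactly how the generated keys are evaluated. The best candidate ever
seen is retained, so the winner is never worse than the initial
population's best.

The final key is `SHA-256(unique_key ‖ winner_bits)`: concatenating a
256-bit digest with a 256-bit random component yields 512 bits, and
hashing compresses them to the 256 bits a ChaCha20 key requires while
mixing both sources into every output bit. A fresh 96-bit nonce is drawn
per key from the same seeded generator — nonce management is essential
for stream-cipher security and is therefore explicit here even though
the key-derivation procedure alone does not require it. All randomness
flows through R's seeded generator, so (fused vector, seed) determines
the key bit-for-bit.

## Encryption

`chacha20`, `chacha12` and `salsa20` keystream cores are implemented in
C++ from the public algorithm specifications (quarter-round state
mixing; 96-bit nonce/32-bit counter layout for the ChaCha pair, 64-bit
nonce/64-bit counter for Salsa20), and the ChaCha20 output is pinned to
the published standard's test vectors in the test suite. The
"12-round ChaCha" reading of the unqualified "ChaCha" scheme is a
documented choice; the core is round-parameterized. Implementing the
cores in-package (rather than binding a crypto library) keeps key
generation and per-scheme keystream timing uniform in the benchmark
harness; the test vectors serve as the independent cross-check.
Encryption is the pure stream XOR `C_i = P_i ⊕ K_i` — deliberately
unauthenticated, matching the modelled scheme; ciphertexts are malleable
and real deployments should add an AEAD layer. The benchmark harness
reports median key-generation, encryption and decryption wall times per
scheme; timings are hardware-dependent and are never asserted.

## Numerical choices and degenerate inputs

* VMD on an all-zero signal returns zero modes with centre frequencies 0
  by convention; odd-length inputs are padded by one sample and trimmed.
* Ties in the kestrel search resolve to the lowest candidate index;
  `trail_is_new` uses a strict inequality at its boundary.
* Constant signals: min–max normalization and hence `preprocess()`
  raise a degenerate-range error; `time_domain_features()` reports
  skewness/kurtosis 0 with a `degenerate` flag.
* Text signal files store 15 significant digits, so write/read round
  trips are exact to well below 1e-12 relative error.
* Problem sizes in the test suite: full-length (10,000-sample) fixtures
  where the contract is about the study shape (R-peak recovery, the
  end-to-end run), 1,000–4,000-sample fixtures for decomposition
  property checks, which exercise identical code paths at lower cost.

## Known limitations

* The feature vector is not error-corrected: key regeneration from a
  *re-measured* ECG requires the same fused vector to six decimals,
  which real repeated measurements will not give. Fuzzy extractors /
  error-tolerant biometric binding are out of scope.
* No authentication or key-exchange layer.
* The R-peak detector is tuned for single-lead resting rhythms;
  arrhythmic or heavily artifacted signals are outside the validated
  envelope.
* WFDB/EDF ingestion is future work; delimited text and the JSON
  container are the supported formats.
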