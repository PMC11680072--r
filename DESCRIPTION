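Package: ecgcrypt
Title: ECG Feature Fusion and Bio-Inspired Key Generation for Lightweight
    Encryption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning a single-lead electrocardiogram into a
    256-bit encryption key. The pipeline band-pass filters and normalizes
    the raw signal, decomposes it with variational mode decomposition plus
    a gradient-based noise-regularized refinement stage, extracts and fuses
    time-domain, frequency-domain, time-frequency, heart-rate-variability
    and zero-crossing features into a single vector, derives a key from the
    fused vector with a kestrel-inspired half-life randomized search, and
    encrypts data with ChaCha20-family stream ciphers. Includes a synthetic
    ECG generator with known R-peak ground truth, empirical mode
    decomposition, a Pan-Tompkins style QRS detector, and entropy-based key
    quality measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
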