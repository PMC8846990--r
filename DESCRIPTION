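Package: pulsentropy
Title: Refined Composite Multiscale Entropy Analysis of Wrist-Pulse Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Complexity analysis of single-channel wrist-pulse (pressure pulse
    wave) recordings. Implements sample, fuzzy, permutation and dispersion
    entropy together with their refined composite multiscale versions
    (RC-MSE, RC-MFE, RC-MPE, RC-MDE), a pulse preprocessing chain (zero-phase
    low-pass denoising, wavelet energy-ratio baseline-wander removal,
    incomplete-cycle trimming, z-score normalization), a synthetic pulse-cohort
    generator with a controllable between-group complexity difference, and the
    cohort-level two-group comparison (per-scale means, SDs and two-sample
    t-tests with a Shapiro-Wilk normality gate) that produces the standard
    per-scale summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
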