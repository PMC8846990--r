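---
title: "Methods: refined composite multiscale entropy analysis of wrist-pulse signals"
author: "pulsentropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: refined composite multiscale entropy analysis of wrist-pulse signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsentropy)
```

## What this package computes

Wrist-pulse (pressure pulse wave) recordings are quasi-periodic physiological
signals driven by cardiac activity. A standard way to quantify their
irregularity is through entropy statistics computed over a range of time
scales, and a standard study design compares two groups (for example male
vs. female subjects, one hand at a time) scale by scale. `pulsentropy`
implements that complete pipeline:

1. **Preprocessing** -- zero-phase low-pass denoising, wavelet-based
   baseline-wander removal, incomplete-cycle trimming, z-score normalization;
2. **Four single-scale entropy estimators** -- sample (SaEn), fuzzy (FuEn),
   permutation (PeEn) and dispersion (DiEn) entropy;
3. **Refined composite multiscale (RC) versions** of all four (RC-MSE,
   RC-MFE, RC-MPE, RC-MDE) over scales $\tau = 1..10$;
4. **Cohort statistics** -- per-scale group means, SDs and pooled two-sample
   t-tests with a Shapiro--Wilk normality gate, formatted as the familiar
   mean $\pm$ SD summary tables;
5. A **synthetic cohort generator**, because studies of this kind rarely
   deposit raw recordings: it provides pulse-like records with known
   structure and a controllable between-group complexity difference, so the
   whole pipeline is testable end to end.

## The estimators

All Shannon sums use natural logarithms and the convention
$0 \cdot \ln 0 = 0$.

**Sample entropy.** With embedding dimension $m$ and tolerance $r$, form
templates $X_i^m = (x_i, \dots, x_{i+m-1})$ for $i = 1..N-m$ (the same index
range is used at length $m+1$, so the two pair sets are comparable). Let $B$
be the number of pairs $i < j$ with Chebyshev distance
$d(X_i^m, X_j^m) \le r$, and $A$ the same count at length $m+1$. Then
$\mathrm{SaEn} = -\ln(A/B)$. If either count is zero the estimate is
*undefined*; this is returned as a first-class `NA`, not an error, because
the refined composite framework below exists precisely to make that outcome
rare on short records.

**Fuzzy entropy** replaces the hard threshold with a graded membership
$D_{ij} = \exp(-(d_{ij}/r)^n)$ summed over pairs, and is therefore always
finite and continuous in $r$. Following the estimator definitions used in
the pulse literature, no per-template local-mean subtraction is applied:
the membership acts on the raw template distance.

**Permutation entropy** is the Shannon entropy of the relative frequencies
of ordinal patterns over all $N - (m-1)d$ delay-embedded windows, normalized
by $\ln(m!)$ so values lie in $[0, 1]$. Ties are broken by original index
order (stable sort) -- a deterministic convention; the choice only matters
for heavily quantized data.

**Dispersion entropy** maps amplitudes through the normal CDF fitted by the
series mean and SD, assigns $z_j = \mathrm{round}(c\,y_j + 0.5)$ (half away
from zero, clipped to $1..c$), embeds the class series, and normalizes the
pattern entropy by $\ln(c^m)$.

Defaults are the standard recommendations for pulse analysis: $m = 3$,
$r = 0.15\,\sigma$, $n = 2$, $c = 6$, delay $1$. With z-scored input
($\sigma = 1$) the relative tolerance is an absolute $0.15$.

One note on window counts: some printed definitions of dispersion entropy
give the number of embedded windows ambiguously; this package uses
$N - (m-1)d$ windows for both pattern estimators, which reduces to the usual
$N - m + 1$ at delay 1.

## Refined composite multiscale framework

At scale $\tau$ there are $\tau$ coarse-grained series
$y^{(\tau)}_{k,j} = \frac{1}{\tau}\sum_{i=(j-1)\tau+k}^{j\tau+k-1} x_i$, one
per offset $k = 1..\tau$, each of length $\lfloor (N-k+1)/\tau \rfloor$
(only complete windows are used). The *refined composite* estimate at scale
$\tau$:

* for SaEn/FuEn, pools the match counts over all $\tau$ offset series before
  taking $-\ln(\sum_k A_k / \sum_k B_k)$;
* for PeEn/DiEn, averages the pattern distributions over offsets with equal
  weight, then takes the Shannon entropy of the average.

At $\tau = 1$ every RC measure equals its single-scale estimator exactly
(this is asserted in the tests, to identity). Pooling is what stabilizes
deep scales: a 2000-sample record leaves only 200 coarse samples at
$\tau = 10$, where a single-offset estimate is noisy and, for crisp
counting, sometimes undefined.

Two conventions deserve emphasis:

* **The tolerance $r$ is computed once from the full-resolution series and
  held fixed across scales.** Coarse-graining shrinks the variance of
  irregular signals, so a fixed $r$ makes the white-noise profile decrease
  with scale -- the classic multiscale signature. Recomputing $r$ per scale
  would erase it.
* **Pattern profiles are normalized** by $\ln(m!)$ and $\ln(c^m)$ at every
  scale so they stay in $[0,1]$, consistent with how per-scale summary
  tables report them; raw nats are available via `normalize_patterns = FALSE`.

## Preprocessing

Pulse energy lives essentially below 10 Hz. The denoising low-pass is a
linear-phase FIR (order 100, Hamming design) with 40 Hz cutoff, applied
forward and backward with odd-reflection padding: exactly zero phase, with
passband flat to well under 1% below 32 Hz and mains interference at 60 Hz
attenuated far beyond 40 dB. Zero-phase filtering matters here because
phase distortion would alter template distances and hence the entropy
estimates.

Baseline wander (slow drift below about 0.5 Hz) is detected and removed
with a multilevel Meyer-type wavelet decomposition in its undecimated
(à-trous) form: the approximation band at level $L$ is the cascade of the
62-tap discretized Meyer scaling filter dilated by $2^0..2^{L-1}$, applied
zero-phase in the frequency domain. The undecimated form is used because a
truncated Meyer filter loses orthogonality once a decimated dyadic band
becomes shorter than the filter, while the à-trous cascade is exact and
shift-invariant at any depth. The *drift level* is the energy of the
approximation-band reconstruction divided by the total energy of the
mean-removed signal (so a pure DC offset does not count as drift); if it
exceeds the threshold (default 0.05), the baseline -- a natural cubic
spline through the approximation band sampled every $2^{L-2}$ samples, plus
the signal mean -- is subtracted. The depth is
$L = \lfloor \log_2(f_s/0.5) \rfloor - 1$ ($L = 7$ at 200 Hz), which puts
the cascade's flat passband edge $f_s/(3 \cdot 2^L) \approx 0.52$ Hz just
above the conventional wander band; one level deeper would leave drift
between 0.26 and 0.5 Hz undetected.

Incomplete leading/trailing cycles are trimmed by locating beat onsets (the
local minimum preceding each prominent maximum, with peaks at least 0.3 s
apart and prominence judged against the 5th--95th percentile range), and
the retained segment is z-scored. Records in which fewer than two onsets
can be found raise a typed quality error (`pulse_quality_error`) and are
excluded and logged by `run_study()` -- an automated, reproducible stand-in
for the manual visual artifact rejection such studies describe.

## The synthetic cohort generator

`generate_pulse()` emulates what matters for entropy analysis of a resting
wrist-pulse record, not hemodynamics:

* each beat is three positive Gaussian lobes (percussion, tidal, dicrotic
  waves) with amplitude ratios 1 : 0.4 : 0.25, centers at 15%, 40% and 65%
  of the beat interval, widths 5--8% of it -- a shape chosen to resemble
  published pressure-pulse waveforms while keeping every constant explicit
  and configurable;
* beat intervals are $60/\mathrm{HR} + \varepsilon_i$,
  $\varepsilon_i \sim N(0, \sigma_{RR}^2)$, truncated at 0.3 s;
* additive white Gaussian sensor noise and a sinusoidal baseline wander
  with frequency drawn in 0.05--0.5 Hz.

Defaults describe a resting young-adult recording session: 10 s at 200 Hz
(2000 samples), 72 bpm, $\sigma_{RR} = 30$ ms, noise SD 5% of the
percussion amplitude, wander amplitude 0.5. The two-group design labels
group A male and group B female; a single knob `effect` multiplies group
B's jitter and noise SDs by $(1+\mathrm{effect})$ -- the simplest mechanism
that measurably shifts all four entropy measures at once. `effect = 0`
makes the groups exchangeable by construction, which is exactly what the
type-I-error calibration needs. Per-record seeds derive from the root seed
through a counter, so cohorts are bit-reproducible and extending one never
reshuffles existing records.

What the generator deliberately does *not* reproduce: real inter-subject
morphology differences, respiration-locked wander, sensor contact
artifacts, non-stationarity over the recording, or any true physiological
sex difference. Passing the pipeline's tests on synthetic cohorts therefore
demonstrates statistical correctness of the machinery (calibration, power,
invariances), not a claim about real pulse physiology.

## Cohort statistics

For every (measure, hand, scale) cell, `run_study()` reports male and
female means and SDs and the p-value of the pooled-variance two-sample
t-test -- the literal reading of the independent two-sample t-test used in
this literature (Welch's form is a flag away). A Shapiro--Wilk check is
logged per group and cell; an optional Mann--Whitney fallback can replace
the t-test when normality fails, off by default since the pooled test is
the primary analysis. Per-scale p-values are reported unadjusted, mirroring
the field's convention of testing each scale separately; because that
convention is a known weakness, a clearly separated Holm-corrected column
(adjusted across the 10 scales within each table) is emitted alongside.
Degenerate cells follow explicit conventions: both groups constant and
equal gives $p = 1$; both constant but different is an error rather than a
fake zero p-value.

## Numerical and design choices

* Natural logs throughout; normalization makes PeEn/DiEn base-independent.
* Template index range $i \le N - m$ for both template lengths (the common
  convention that keeps pair sets comparable).
* Undefined SaEn is `NA`, serialized as the literal token `NA` in CSV.
* Sample SDs use the $n-1$ denominator everywhere.
* The fuzzy kernels skip template pairs whose membership would be below
  $e^{-60} \approx 9 \times 10^{-27}$ -- far beneath double-precision
  resolution of the pooled sums -- which roughly triples throughput on
  typical records.
* Cycle trimming uses a relative (quantile-based) prominence threshold, so
  onset detection is invariant to affine amplitude changes; together with
  z-scoring this makes the full pipeline amplitude-scale invariant, which
  the tests assert explicitly.

## Problem sizes used in the test suite

The packaged tests exercise the study design at sizes chosen to keep the
full suite comfortably runnable on a laptop while leaving the Monte-Carlo
conclusions sharp: oracle-equivalence checks on 50 random series per
estimator ($N \le 200$, $\tau \le 3$, tolerance $10^{-10}$); multiscale
signatures on 30 replicates of 2000-sample reference noise; and the
pipeline calibration on cohorts of 30 subjects per sex with 5 s (1000
sample) records -- 100 exchangeable cohorts for the null rejection rate,
50 at `effect = 1` for power, 20 each at intermediate effects for
monotonicity of the power curve. Record length is the one knob reduced
relative to the 10 s study setting; the calibration properties being tested
(test level under exchangeability, power ordering) do not depend on it.
The analysis scripts under `analysis/` and `scripts/acceptance.R` run the
full 10 s records, with 2 × 100 subjects per sex in the acceptance study.

## Known limitations

* The generator's "complexity difference" is a single mechanism (jitter +
  noise inflation); real group differences could act on morphology or
  autonomic variability in ways it does not emulate.
* Baseline estimation assumes wander below ~0.5 Hz; respiration-locked
  drift overlapping the cardiac band would not be separable this way.
* The quality gate only checks that two beat onsets exist; it does not
  grade waveform fidelity.
* The pooled t-test is applied per cell without cross-measure correction,
  by design mirroring the field's reporting convention; the Holm column is
  provided for readers who want the stricter view.
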