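# pulsentropy

Complexity analysis of wrist-pulse (pressure pulse wave) recordings with
refined composite multiscale entropy, for researchers studying whether two
groups of subjects -- for example male vs. female cohorts, recorded on each
hand -- differ in the nonlinear irregularity of their pulse signals.

The package implements the full analysis chain used in pulse-complexity
studies:

* **Preprocessing**: zero-phase 40 Hz FIR low-pass denoising, wavelet
  energy-ratio baseline-wander removal (Meyer-type multilevel decomposition
  plus cubic-spline baseline estimation), incomplete-cycle trimming by beat
  onset detection, and z-score normalization.
* **Entropy estimators**: sample entropy (SaEn), fuzzy entropy (FuEn),
  permutation entropy (PeEn) and dispersion entropy (DiEn), with the
  standard parameterization *m* = 3, *r* = 0.15 σ, *n* = 2, *c* = 6,
  delay 1.
* **Refined composite multiscale framework** (RC-MSE, RC-MFE, RC-MPE,
  RC-MDE) over scales τ = 1..10: match counts pooled (or pattern
  distributions averaged) across all τ offset coarse-grained series per
  scale, which stabilizes estimates on short (~2000 sample) records.
* **Cohort statistics**: per-scale group means ± SD and pooled two-sample
  t-tests with a Shapiro–Wilk normality gate, written as the familiar
  per-scale summary tables (plus a separated Holm-corrected column).
* **A synthetic pulse-cohort generator** (three-Gaussian-lobe beats, RR
  jitter, baseline wander, sensor noise, and a controllable between-group
  complexity difference), so the pipeline can be exercised and calibrated
  without access to clinical recordings.

The core statistic, for a series coarse-grained at scale τ into the τ
offset series `y_k`:

    RC-MSE(x, τ, m, r) = -ln( Σ_k A_k / Σ_k B_k )

where `B_k` and `A_k` count template pairs of `y_k` within Chebyshev
distance `r` at lengths `m` and `m+1` (fuzzy counting replaces the hard
threshold by `exp(-(d/r)^n)`), and for the pattern measures the Shannon
entropy of the offset-averaged ordinal/dispersion pattern distribution,
normalized to [0, 1] by `ln(m!)` or `ln(c^m)`.

## Worked example

```r
library(pulsentropy)

# one synthetic 10 s record at 200 Hz, then the cleaning chain
rec <- generate_pulse(fs = 200, duration_s = 10, heart_rate_bpm = 72, seed = 42)
pp  <- preprocess_record(rec)
pp$drift_detected
#> [1] TRUE            # baseline wander found (energy ratio 0.662) and removed

# four refined composite multiscale profiles, scales 1..10
prof <- profile_record(pp$record, entropy_params(), tau_max = 10)
prof$rc_mfe
#> RC_MFE profile for 'synthetic' (unknown hand), tau = 1..10
#>      1      2      3      4      5      6      7      8      9     10
#> 0.3457 0.4895 0.5077 0.5082 0.5101 0.5239 0.5237 0.4994 0.4685 0.4598

# a small two-group study: 10 subjects per sex, exchangeable groups
coh   <- generate_cohort(cohort_spec(n_per_group = 10, effect = 0, seed = 7))
study <- run_study(coh$manifest, coh$records, tau_max = 5)
round(study$tables[["rc_mde.left"]][, 1:6], 4)
#>   tau male_mean male_sd female_mean female_sd p_value
#> 1   1    0.5245  0.0056      0.5263    0.0039  0.4212
#> 2   2    0.6077  0.0069      0.6106    0.0050  0.2848
#> 3   3    0.6478  0.0049      0.6501    0.0075  0.4357
#> 4   4    0.6681  0.0056      0.6705    0.0082  0.4648
#> 5   5    0.6846  0.0058      0.6847    0.0107  0.9676
```

Each table row is one time scale: group means and SDs of the dispersion
entropy profile and the pooled t-test p-value. With exchangeable groups
(`effect = 0`), no scale is significant -- the expected null behaviour.
`write_study_tables()` renders these as 4-decimal CSV tables, one per
measure and hand.

The `analysis/` directory holds the same pipeline as a numbered workflow
(simulate → preprocess → profile → compare → reference signatures), each
step a thin script over the package functions that writes its tables under
`results/`.

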