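# ssveprca

Reliable Components Analysis and apparent-latency estimation for
frequency-tagged EEG (steady-state visual evoked potentials, SSVEP).

## The problem

In an SSVEP oddball design, stimuli update at a base rate (e.g. 10 Hz)
and every *k*-th item is a deviant, tagging deviant-specific neural
processing at the deviant rate (e.g. 2 Hz) and its harmonics. Because the
response is periodic and phase-locked, each 1-s epoch yields one complex
Fourier coefficient per sensor and harmonic; everything downstream —
spatial filtering, statistics, latency — operates on those coefficients.
This package is for researchers who want that full analysis chain as
tested, scriptable R, together with a synthetic-data generator with known
ground truth so every stage can be validated without raw recordings.

The core pieces, in the field's standard notation:

- **RCA**: spatial filters solving the generalized eigenproblem
  `R_across w = λ R_within w`, maximizing trial-to-trial covariance
  relative to within-trial covariance of the stacked (re, im) coefficient
  features; components are ranked by reliability explained
  `100·λᵢ / Σ λ⁺`, and visualized via forward models
  `A = R_within W (Wᵀ R_within W)⁻¹`.
- **Hotelling T²** against the origin on the per-subject mean (re, im)
  pair at each harmonic, Benjamini–Hochberg FDR within the analysis
  family.
- **Apparent latency**: the group delay `τ = −slope/(2π)·1000` ms of the
  line fitted through unwrapped phases of the significant harmonics,
  since a fixed delay gives `φ(f) = φ₀ − 2πfτ`.

## Worked example

Simulate a scaled replica of a 10 Hz / 2 Hz word-oddball condition with
two planted deviant sources (group delays 180 ms and 260 ms, orthogonal
topographies) and run the full pipeline:

```r
library(ssveprca)
w  <- condition1_world(n_sensors = 64, n_trials = 8)
ds <- simulate_recording(w$truth, w$schedule, w$montage, fs = 500,
                         n_subjects = 12, seed = 2024)
res <- run_condition(ds$recordings, study_config(w$schedule))

res$deviant$model
#> RCA model: 2 components over 64 sensors (rank 63)
#>   reliability explained: 57.9%, 39.4%

subset(res$deviant$tests, significant,
       select = c(component, harmonic, statistic, p_fdr))
#>   component harmonic statistic        p_fdr
#> 1         1        2  180.4508 1.001839e-06
#> 2         2        2  389.6499 6.240194e-08
#> 3         1        4  189.3013 9.990213e-07
#> 4         2        4  578.0534 1.816686e-08
#> 5         1        6  215.6508 7.180360e-07

res$latency[[1]]
#> latency 189.06 ms +/- 0.81 over harmonics 2, 4, 6 Hz
res$latency[[2]]
#> latency 262.41 ms (SE unavailable) over harmonics 2, 4 Hz

res$phase_comparison[, c("harmonic", "latency_diff_ms", "p_fdr")]
#>   harmonic latency_diff_ms        p_fdr
#> 1        2       103.73067 4.02898e-300
#> 2        4        89.87203  0.00000e+00

cor(res$deviant$model$A[, 1], w$topographies[, 1])  # 0.989
cor(res$deviant$model$A[, 2], w$topographies[, 2])  # 0.980
```

Reading the output: the first reliable component recovers the fast
source's topography (r = 0.99) and is significant at its three planted
harmonics, giving a 3-point phase-slope latency with a standard error;
the second recovers the slow source (r = 0.98), is significant at its two
planted harmonics, so its latency has no standard error (two points fit
exactly). Latencies track the *realized* group means, which jitter ±10 ms
SD per subject around 180/260 ms. The paired circular test converts the
RC2−RC1 phase differences at the shared significant harmonics into
latency differences in milliseconds.

`write_report(res, "out/")` exports the tests, latencies, topographies,
phase comparisons and provenance as CSV/JSON.

## Layout

- `R/schedule.R`, `R/montage.R`, `R/simulate.R`, `R/study.R` — stimulus
  schedules, spherical montage with neighbor adjacency, the ground-truth
  generator and the default synthetic world.
- `R/preprocess.R` — bandpass, resampling, repair, reference, epoching.
- `R/spectral.R` — harmonic enumeration and complex coefficients.
- `R/rca.R` — training, forward models, sign alignment, projection.
- `R/inferential.R`, `R/latency.R` — T², FDR, ellipses, circular tests,
  phase unwrapping and group-delay fits.
- `R/pipeline.R` — per-condition and joint-condition orchestration,
  report writer.
- `vignettes/ssvep-rca-methods.Rmd` — the model, numerical choices, the
  synthetic world's assumptions and known limitations.
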