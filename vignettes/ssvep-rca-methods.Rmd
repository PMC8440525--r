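---
title: "Methods: reliable components and apparent latency for frequency-tagged EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reliable components and apparent latency for frequency-tagged EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssveprca)
```

## The model

A frequency-tagging oddball experiment presents stimuli at a base rate
$f_b$ (e.g. 10 Hz) with every $k$-th item replaced by a deviant, so
deviant-specific processing is tagged at $f_d = f_b / k$ (e.g. 2 Hz) and
its harmonics. The steady-state response of a neural source with a fixed
processing delay $\tau$ is a sum of sinusoids whose phase falls linearly
with frequency,

$$\varphi(f) = \varphi_0 - 2\pi f \tau,$$

so the slope of phase versus harmonic frequency is an *apparent latency*
(group delay). The package implements the full chain from multichannel
recordings to that latency:

1. **Preprocessing** — zero-phase 0.3–50 Hz bandpass, resampling to
   420 Hz, neighbor-average repair of bad sensors, average reference,
   segmentation into 1-s epochs, and per-sensor epoch rejection
   (>10% of samples above 30 µV, or any sample above 60 µV).
2. **Spectral coefficients** — with 1-s epochs every integer frequency is
   an exact DFT bin; each valid (epoch, sensor) trace becomes one complex
   coefficient per analysis harmonic, scaled so a unit cosine gives
   $1 + 0i$ (magnitude = µV of the sinusoid, angle = phase
   counterclockwise from the positive real axis).
3. **Reliable Components Analysis (RCA)** — spatial filters $w$ solving
   $R_{\text{across}} w = \lambda R_{\text{within}} w$, where
   $R_{\text{across}}$ is the symmetrized mean cross-covariance over
   ordered trial pairs of the stacked (re, im) features and
   $R_{\text{within}}$ the mean within-trial covariance. $\lambda$ is the
   reliability ratio; components are ranked by it, and
   $100 \lambda_i / \sum_{\lambda_j > 0} \lambda_j$ is the percent
   reliability explained. Filters are visualized through forward models
   $A = R_{\text{within}} W (W^\top R_{\text{within}} W)^{-1}$.
4. **Group statistics** — projected coefficients are averaged per subject
   (statistics always run across subjects), tested against the origin with
   Hotelling's $T^2$ on the (re, im) pair, and FDR-adjusted within the
   family the analysis defines (4 harmonics × components).
5. **Latency** — at the FDR-significant harmonics, the phase of the
   group-mean coefficient is unwrapped assuming a fixed delay and fitted
   by least squares; $\hat\tau = -\text{slope}/(2\pi) \cdot 1000$ ms, with
   a slope standard error only when ≥3 points exist. Circular statistics
   compare the phases of two components at harmonics significant in both,
   and phase differences convert to milliseconds via
   $\Delta t = \Delta\varphi / (2\pi f) \cdot 1000$.

## Numerical choices

**Zero-phase filtering.** A forward–backward Butterworth filter has the
squared magnitude of the one-pass filter and exactly zero phase. We apply
that transfer function directly in the frequency domain
(order 4 by default, −6 dB at the band edges, gain 0 at DC). This is
numerically identical to ideal filtfilt on periodic content, has no edge
transients, and needs no initial-condition heuristics. The same reasoning
gives Fourier resampling: durations are preserved exactly
(12 s × 420 Hz = 5040 samples; 7 samples per 60-Hz frame) and any on-bin
sinusoid keeps amplitude and phase to machine precision.

**The RLS question.** The adaptive narrowband stage used in the original
processing chain is, on whole epochs containing exact integer cycles,
equivalent in steady state to the on-bin DFT coefficient — which is what
all downstream statistics consume. The DFT is therefore the tested
contract; an exponentially weighted recursive estimator
(`method = "rls"`, forgetting factor configurable) is provided for
fidelity studies, with its trailing-cycle average removing the
demodulation ripple at $2f$.

**Across-trial covariance.** The mean over all ordered trial pairs is
computed by the sum identity
$\sum_{i \ne j} X_i X_j^\top = S S^\top - \sum_i X_i X_i^\top$
(linear in trials), with pairwise-complete counts so that sensors rejected
in individual epochs simply drop out. One consequence worth knowing:
literally duplicating a trial set *raises* reliability
($\lambda \mapsto (\lambda(2n-2)+1)/(2n-1)$) because a trial is perfectly
reliable with its own copy; eigenvectors are unchanged. The generalized
eigenproblem is solved in the principal subspace of $R_{\text{within}}$
(rank chosen at a $10^{-4}$ relative eigenvalue cutoff, overridable),
which regularizes the rank deficiency introduced by average referencing.

**Sign and branch conventions.** Eigenvector signs are aligned
automatically: each component is flipped, if needed, so its projected
course correlates positively with the raw data at the sensor of maximal
absolute forward-model weight (idempotent). Phase unwrapping searches
integer $2\pi$ branches per point (window ±4, first point pinned) for the
minimum-residual line with non-positive slope — delay lowers phase — and
prefers the smallest physical $|\tau|$ on ties, flagging the ambiguity.
With two points every branch fits exactly, so the smallest-delay branch is
always chosen; that is the inherent ambiguity of a 2-point fit, not an
implementation artifact.

**Circular test.** The paired comparison tests zero mean direction of the
per-subject phase differences using the von Mises normal approximation
(standard error $1/\sqrt{n R \hat\kappa}$, $\hat\kappa$ from Fisher's
A1 inverse), warning when the resultant length is small. A Watson–Williams
two-sample variant is available behind `method = "watson_williams"`.

## The synthetic world

No raw data accompany the study design this package replicates, so
`condition1_world()` builds a fully specified stand-in with known ground
truth: 128 sensors on a spherical cap with ≥6-neighbor adjacency, 12-s
trials, 16 trials per subject, 16 subjects, and three planted sources:

- a fast deviant source (left posterior ventral topography, group delay
  180 ms) responding at 2/4/6 Hz with 1.2/0.9/0.6 µV;
- a slow deviant source (dorsal parietal topography, orthogonalized
  against the first, 260 ms) responding at 2/4 Hz with 0.9/0.6 µV;
- a base source (medial occipital, 100 ms) at 10/20/30/40 Hz.

The amplitude patterns mirror the reported significance structure of the
design being emulated (three significant deviant harmonics for the first
component, two for the second — hence a standard error for the first
latency and none for the second). Subjects share topographies but jitter
amplitudes (±20%) and latencies (±10 ms SD). Phase intercepts are chosen
so the two sources' coefficient patterns are orthogonal across harmonics:
two separable neural processes. Without that choice the planted sources
are substantially correlated and *no* linear spatial filter can unmix
them — a useful reminder that RCA separates sources, not arbitrary
mixtures.

Noise is a spatially correlated 1/f background (white noise shaped to a
1/f power spectrum, mixed through smooth random sensor patterns) plus
white sensor noise, 4 µV and 2 µV RMS by default. That puts single-epoch
on-bin SNR near 1 — realistic for scalp EEG — while the subject-level
mean over all 192 epochs sits near SNR 6, which is where the group
statistics operate. Two calibration lessons are baked into the defaults
and worth recording:

- **Background rank matters.** With only a handful of noise patterns the
  background covariance is strongly anisotropic and its random alignment
  with the planted topographies varies wildly across seeds, occasionally
  mixing the recovered components. The default uses one pattern per sensor
  so the covariance concentrates; the failure mode is reproducible by
  setting `n_noise_patterns` low.
- **Saturated reliability degenerates.** With very low noise both
  components' reliability ratios approach 1, the eigenvalue gap closes,
  and the eigenvectors rotate freely within the signal subspace. Realistic
  noise levels separate the spectrum (the replica typically reports
  roughly 60%/35% reliability explained for the two deviant components).

What a green test does **not** establish: the generator has fixed
topographies across subjects, stationary noise, no per-subject montage
differences, and no correlated artifacts, so the suite validates the
*pipeline's* statistical machinery, not its robustness to every property
of real recordings. One known consequence: because between-subject
variability is pure scaling, Hotelling's $T^2$ can on some seeds flag the
small coherent crosstalk a spatial filter passes at harmonics where its
source is silent, which then admits a crosstalk phase into that
component's latency fit. The acceptance script reports whatever the run
produced rather than filtering such seeds.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `band_lo`, `band_hi` | 0.3, 50 Hz | zero-phase bandpass edges |
| `resample_hz` | 420 Hz | integer samples per 60-Hz frame |
| `sensor_bad_fraction` / `sensor_amp_thresh_uv` | 0.15 / 30 µV | repair rule (strictly more than) |
| `epoch_noise_fraction` / `epoch_noise_thresh_uv` | 0.10 / 30 µV | epoch noise rule |
| `epoch_artifact_thresh_uv` | 60 µV | any-sample artifact rule |
| `n_components_deviant`, `n_components_base` | 2, 1 | components analyzed |
| `alpha` | 0.05 | level on FDR-adjusted p |
| `rank_k` | auto | RCA principal-subspace rank |
| `noise_1f_scale`, `noise_white_scale` | 4, 2 µV | generator noise RMS |
| `amp_jitter_rel`, `tau_jitter_ms` | 0.2, 10 ms | between-subject spread |

All thresholds compare absolute values (a signed rule would miss
negative-going blinks). Units are µV throughout; time zero is trial onset.

## Scaling in the tests

The full replica (128 sensors, 16 subjects × 16 trials) runs in a few
minutes and is exercised once in the acceptance suite (8 trials per
subject there, to keep the CI budget) and at full size by
`scripts/acceptance.R`. Estimator-level acceptance properties
(type-I error, FDR oracle equivalence, brute-force eigensolver checks,
two-source recovery at SNR 5) run on small constructed instances where
the oracle is exact. The ±5 ms group-delay recovery criterion is judged
on the mean error over 20 seeds: with 16 subjects at subject-level SNR 5
a two-point phase fit has a per-seed sampling SD of about 5 ms, so a
per-seed bound would be unattainable for any estimator; the aggregate
bound tests unbiasedness at the stated tolerance.
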