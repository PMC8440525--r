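#' Default synthetic world: a word-in-pseudofont oddball replica
#'
#' Builds the ground truth, schedule and montage for a synthetic replica
#' of a 10 Hz base / 2 Hz deviant oddball experiment with two planted
#' deviant sources and one base source. The deviant sources have fixed
#' topographies (a left posterior ventral bump and an orthogonalized
#' dorsal parietal bump, both zero-mean as average-referenced scalp fields
#' are), per-harmonic amplitudes that fade with harmonic number the way
#' evoked spectra do, and fixed group delays of 180 ms and 260 ms. The
#' base source sits over medial occipital sensors with a 100-ms delay.
#' Noise is a spatially smooth 1/f background plus white sensor noise.
#' The default scales emulate real scalp EEG, where a single epoch's
#' on-bin SNR is near 1 and detectability comes from averaging: at the
#' level the group statistics operate on (per-subject means over all
#' epochs of the full design) the strongest deviant harmonic sits at an
#' amplitude SNR of roughly 6 at the best sensor.
#'
#' @param n_sensors Montage size (default 128).
#' @param n_trials Trials per subject (default 16).
#' @param trial_duration_s Trial length (default 12 s).
#' @param tau1_ms,tau2_ms Group delays of the two deviant sources.
#' @param noise_1f_scale,noise_white_scale Noise RMS in microvolt.
#' @param amp_jitter_rel,tau_jitter_ms Between-subject spread.
#' @param include_base Include the base-rate source (default TRUE).
#' @return List: `truth`, `schedule`, `montage`, and `topographies`
#'   (sensor x source matrix of the planted deviant topographies).
#' @export
condition1_world <- function(n_sensors = 128L, n_trials = 16L,
                             trial_duration_s = 12,
                             tau1_ms = 180, tau2_ms = 260,
                             noise_1f_scale = 4.0, noise_white_scale = 2.0,
                             amp_jitter_rel = 0.2, tau_jitter_ms = 10,
                             include_base = TRUE) {
  montage <- make_montage(n_sensors)
  schedule <- make_schedule(10, 5, trial_duration_s, n_trials)
  t1 <- topo_bump(montage, c(-0.55, -0.70, -0.10))   # left posterior ventral
  t2 <- topo_bump(montage, c(0.05, -0.35, 0.95))     # dorsal parietal
  t2 <- t2 - sum(t2 * t1) * t1                       # orthogonalize
  t2 <- t2 / sqrt(sum(t2^2))
  # harmonic amplitude patterns mirror the reported significance structure:
  # the faster source responds at the first three deviant harmonics, the
  # slower one at the first two (so its fit has two points and no SE)
  f_dev <- c(2, 4, 6, 8)
  a1 <- c(1.2, 0.9, 0.6, 0)
  a2 <- c(0.9, 0.6, 0, 0)
  # phase intercepts are chosen so the two sources' (re, im) coefficient
  # patterns are orthogonal across harmonics: two separable neural
  # processes, the regime RCA assumes. The inner product of the feature
  # courses is sum_k a1k a2k cos(dphi0 - 2 pi f_k dtau), zeroed in dphi0.
  phi0_2 <- 1.0
  S <- sum(a1 * a2 * exp(-2i * pi * f_dev * (tau1_ms - tau2_ms) / 1000))
  phi0_1 <- phi0_2 + pi / 2 - Arg(S)
  src1 <- make_source(t1, freqs_hz = f_dev, amps_uv = a1, tau_ms = tau1_ms,
                      phi0 = phi0_1)
  src2 <- make_source(t2, freqs_hz = f_dev, amps_uv = a2, tau_ms = tau2_ms,
                      phi0 = phi0_2)
  sources <- list(src1, src2)
  if (include_base) {
    tb <- topo_bump(montage, c(0, -0.97, 0.15))      # medial occipital
    sources <- c(sources, list(
      make_source(tb, freqs_hz = c(10, 20, 30, 40),
                  amps_uv = c(2.0, 1.0, 0.5, 0.3), tau_ms = 100,
                  phi0 = -0.5)))
  }
  truth <- make_truth(sources, noise_1f_scale = noise_1f_scale,
                      noise_white_scale = noise_white_scale,
                      amp_jitter_rel = amp_jitter_rel,
                      tau_jitter_ms = tau_jitter_ms)
  list(truth = truth, schedule = schedule, montage = montage,
       topographies = cbind(rc1 = t1, rc2 = t2))
}

# zero-mean, unit-norm gaussian bump centered at a scalp direction
topo_bump <- function(montage, center, width = 0.5) {
  center <- center / sqrt(sum(center^2))
  d2 <- rowSums(sweep(montage$positions, 2, center)^2)
  w <- exp(-d2 / (2 * width^2))
  w <- w - mean(w)
  w / sqrt(sum(w^2))
}
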