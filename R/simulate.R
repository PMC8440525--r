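#' Define ground truth for a simulated SSVEP experiment
#'
#' A planted source has a fixed sensor topography and emits a sum of
#' cosines at given harmonic frequencies. Its phase at frequency f is
#' `phi0 - 2*pi*f*tau_ms/1000`: a fixed group delay `tau_ms` produces the
#' linear phase-versus-frequency relationship the latency estimator relies
#' on, plus a frequency-independent intercept `phi0`.
#'
#' @param topography Unit-norm numeric vector, one weight per sensor.
#' @param freqs_hz Harmonic frequencies (Hz).
#' @param amps_uv Amplitudes (microvolt) at each frequency.
#' @param tau_ms Group delay (latency) in milliseconds.
#' @param phi0 Phase intercept in radians (default 0).
#' @return A list of class `ssvep_source`.
#' @export
make_source <- function(topography, freqs_hz, amps_uv, tau_ms, phi0 = 0) {
  stopifnot(length(freqs_hz) == length(amps_uv), all(freqs_hz > 0),
            all(amps_uv >= 0), is.numeric(tau_ms), length(tau_ms) == 1L)
  nrm <- sqrt(sum(topography^2))
  if (nrm == 0) stop("topography must be non-zero")
  structure(list(topography = topography / nrm, freqs_hz = freqs_hz,
                 amps_uv = amps_uv, tau_ms = tau_ms, phi0 = phi0),
            class = "ssvep_source")
}

#' Assemble a ground-truth specification
#'
#' @param sources List of [make_source()] objects.
#' @param noise_1f_scale RMS (microvolt) of the spatially-correlated 1/f
#'   background per sensor. The background is white noise shaped to a
#'   1/f power spectrum and mixed through smooth random topographies, the
#'   minimal structure that makes reliability-based filtering non-trivial.
#' @param noise_white_scale RMS (microvolt) of independent white sensor noise.
#' @param amp_jitter_rel Relative between-subject amplitude spread (SD, default
#'   0.2 = +/-20%).
#' @param tau_jitter_ms Between-subject latency spread (SD in ms, default 10).
#' @return A list of class `ssvep_truth`.
#' @export
make_truth <- function(sources, noise_1f_scale = 0, noise_white_scale = 0,
                       amp_jitter_rel = 0.2, tau_jitter_ms = 10) {
  stopifnot(length(sources) >= 1,
            all(vapply(sources, inherits, TRUE, "ssvep_source")),
            noise_1f_scale >= 0, noise_white_scale >= 0)
  structure(list(sources = sources, noise_1f_scale = noise_1f_scale,
                 noise_white_scale = noise_white_scale,
                 amp_jitter_rel = amp_jitter_rel,
                 tau_jitter_ms = tau_jitter_ms),
            class = "ssvep_truth")
}

# g independent unit-RMS 1/f (pink) noise series of length n, as g x n
pink_matrix <- function(n, g) {
  nf <- n %/% 2
  amp <- 1 / sqrt(seq_len(nf))                 # power ~ 1/f, DC removed
  ph <- matrix(stats::runif(nf * g, 0, 2 * pi), nf, g)
  spec <- matrix(0+0i, n, g)
  spec[1L + seq_len(nf), ] <- amp * exp(1i * ph)
  if (n %% 2 == 0) spec[nf + 1L, ] <- Re(spec[nf + 1L, ])
  if (nf >= 2) {
    spec[n + 2L - (2:nf), ] <- Conj(spec[2:nf, ])
  }
  X <- Re(stats::mvfft(spec, inverse = TRUE))
  X <- sweep(X, 2, apply(X, 2, stats::sd), "/")
  t(X)
}

# smooth random spatial patterns: gaussian weights relaxed over the adjacency
smooth_patterns <- function(montage, n_patterns, passes = 1L) {
  n <- montage$n_sensors
  P <- matrix(stats::rnorm(n * n_patterns), n, n_patterns)
  for (pass in seq_len(passes)) {
    Pn <- P
    for (s in seq_len(n)) {
      nb <- montage$adjacency[[s]]
      Pn[s, ] <- 0.5 * P[s, ] + 0.5 * colMeans(P[nb, , drop = FALSE])
    }
    P <- Pn
  }
  sweep(P, 2, sqrt(colSums(P^2)), "/")
}

# noiseless sensor x time signal for one subject realization
source_signal <- function(sources, n_sensors, n_samp, fs) {
  t <- (seq_len(n_samp) - 1L) / fs
  X <- matrix(0, n_sensors, n_samp)
  for (src in sources) {
    ts <- rep(0, n_samp)
    for (k in seq_along(src$freqs_hz)) {
      f <- src$freqs_hz[k]
      ph <- src$phi0 - 2 * pi * f * src$tau_ms / 1000
      ts <- ts + src$amps_uv[k] * cos(2 * pi * f * t + ph)
    }
    X <- X + outer(src$topography, ts)
  }
  X
}

#' Simulate multichannel SSVEP recordings with known ground truth
#'
#' Each trial is the deterministic forward-projected sum of the planted
#' sources plus fresh noise. Subjects get independent noise and (optionally)
#' jittered amplitudes and latencies; topographies are shared across
#' subjects. With both noise scales zero the output equals the forward
#' projection exactly.
#'
#' @param truth An `ssvep_truth`.
#' @param schedule An `ssvep_schedule` (sets trial duration and count).
#' @param montage An `ssvep_montage`.
#' @param fs Sampling rate in Hz; must exceed twice the highest planted
#'   harmonic.
#' @param n_subjects Number of subjects.
#' @param seed RNG seed; the full output is bit-identical for a fixed seed.
#' @param condition_id Label attached to every recording.
#' @param n_noise_patterns Number of smooth spatial patterns carrying the
#'   1/f background. The default (one per sensor) makes the background
#'   covariance full rank and stable across seeds; small values produce
#'   strongly anisotropic noise whose alignment with the planted
#'   topographies varies wildly from seed to seed.
#' @param noise_smooth_passes Neighbor-averaging passes applied to the
#'   noise patterns (default 1). More passes make the background smoother
#'   and more aligned with scalp-sized topographies, which increases
#'   source-to-component crosstalk.
#' @return A list of class `ssvep_dataset`: `recordings` (flat list of
#'   `ssvep_recording`, each with `data` sensor x time in microvolt, `fs`,
#'   `subject_id`, `trial`, `condition_id`, plus shared `montage` and
#'   `schedule`), and `subject_truth` (per-subject realized amplitudes and
#'   latencies for recovery checks).
#' @export
simulate_recording <- function(truth, schedule, montage, fs = 420,
                               n_subjects = 16L, seed = 1L,
                               condition_id = "cond1",
                               n_noise_patterns = NULL,
                               noise_smooth_passes = 1L) {
  stopifnot(inherits(truth, "ssvep_truth"),
            inherits(schedule, "ssvep_schedule"),
            inherits(montage, "ssvep_montage"))
  fmax <- max(unlist(lapply(truth$sources, `[[`, "freqs_hz")))
  if (fmax >= fs / 2) {
    stop("harmonic at ", fmax, " Hz is at or above the Nyquist frequency ",
         fs / 2, " Hz")
  }
  set.seed(as.integer(seed))
  n_samp <- as.integer(round(schedule$trial_duration_s * fs))
  n_sens <- montage$n_sensors
  if (is.null(n_noise_patterns)) n_noise_patterns <- n_sens
  patterns <- smooth_patterns(montage, n_noise_patterns,
                              noise_smooth_passes)
  recordings <- list()
  subject_truth <- vector("list", n_subjects)
  for (sub in seq_len(n_subjects)) {
    srcs <- lapply(truth$sources, function(src) {
      src$amps_uv <- src$amps_uv *
        pmax(0.05, 1 + stats::rnorm(1, 0, truth$amp_jitter_rel))
      src$tau_ms <- src$tau_ms + stats::rnorm(1, 0, truth$tau_jitter_ms)
      src
    })
    subject_truth[[sub]] <- lapply(srcs, function(s)
      list(amps_uv = s$amps_uv, tau_ms = s$tau_ms))
    clean <- source_signal(srcs, n_sens, n_samp, fs)
    for (tr in seq_len(schedule$n_trials)) {
      X <- clean
      if (truth$noise_1f_scale > 0) {
        pink <- pink_matrix(n_samp, n_noise_patterns)
        bg <- patterns %*% pink
        bg <- bg / sqrt(mean(bg^2))
        X <- X + truth$noise_1f_scale * bg
      }
      if (truth$noise_white_scale > 0) {
        X <- X + matrix(stats::rnorm(n_sens * n_samp,
                                     sd = truth$noise_white_scale),
                        n_sens, n_samp)
      }
      recordings[[length(recordings) + 1L]] <- structure(
        list(data = X, fs = fs, montage = montage, schedule = schedule,
             condition_id = condition_id,
             subject_id = sprintf("S%02d", sub), trial = tr),
        class = "ssvep_recording")
    }
  }
  structure(list(recordings = recordings, subject_truth = subject_truth,
                 montage = montage, schedule = schedule,
                 condition_id = condition_id),
            class = "ssvep_dataset")
}

#' @export
print.ssvep_recording <- function(x, ...) {
  cat(sprintf("SSVEP recording %s trial %d: %d sensors x %d samples @ %g Hz\n",
              x$subject_id, x$trial, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Inject blink-like transient artifacts into a recording
#'
#' Adds half-sine transients of the given amplitude at random (sensor, time)
#' locations, returning both the modified recording and the exact spans
#' altered so rejection stages can be tested by exact count. Each transient
#' is placed wholly inside one 1-s epoch.
#'
#' @param rec An `ssvep_recording`.
#' @param rate_per_min Expected number of transients per minute (the realized
#'   count is `round(rate * duration / 60)`).
#' @param amplitude_uv Peak amplitude; must exceed 60 microvolt so that the
#'   injected events are rejectable by the standard artifact threshold.
#' @param seed RNG seed for placement.
#' @param width_s Transient width in seconds (default 0.1).
#' @return List with `recording` (modified copy) and `events` (data.frame:
#'   sensor, start_sample, end_sample, epoch assuming 1-s epochs).
#' @export
inject_artifacts <- function(rec, rate_per_min, amplitude_uv, seed = 1L,
                             width_s = 0.1) {
  stopifnot(inherits(rec, "ssvep_recording"), rate_per_min >= 0)
  if (rate_per_min > 0 && amplitude_uv <= 60) {
    stop("amplitude_uv must exceed 60 microvolt (the artifact threshold) ",
         "so injected events are rejectable by design")
  }
  n_samp <- ncol(rec$data)
  dur_s <- n_samp / rec$fs
  n_events <- as.integer(round(rate_per_min * dur_s / 60))
  events <- data.frame(sensor = integer(), start_sample = integer(),
                       end_sample = integer(), epoch = integer())
  if (n_events == 0) return(list(recording = rec, events = events))
  set.seed(as.integer(seed))
  w <- max(3L, as.integer(round(width_s * rec$fs)))
  ep_len <- as.integer(round(rec$fs))            # 1-s epochs
  n_ep <- n_samp %/% ep_len
  pulse <- amplitude_uv * sin(pi * seq_len(w) / (w + 1))
  for (e in seq_len(n_events)) {
    sens <- sample.int(nrow(rec$data), 1L)
    ep <- sample.int(n_ep, 1L)
    off <- sample.int(ep_len - w, 1L)
    i0 <- (ep - 1L) * ep_len + off
    idx <- i0:(i0 + w - 1L)
    rec$data[sens, idx] <- rec$data[sens, idx] + pulse
    events <- rbind(events, data.frame(sensor = sens, start_sample = i0,
                                       end_sample = i0 + w - 1L, epoch = ep))
  }
  list(recording = rec, events = events)
}
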