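#' Preprocessing configuration
#'
#' Defaults reproduce the standard SSVEP preprocessing chain: a 0.3-50 Hz
#' zero-phase bandpass, resampling to 420 Hz (an integer number of samples
#' per 60-Hz video frame), repair of sensors with more than 15% of samples
#' above 30 microvolt by the average of their six nearest neighbors,
#' average re-referencing, segmentation into 1-s epochs, and per-sensor
#' rejection of epochs with more than 10% of samples above a 30-microvolt
#' noise threshold or any sample above a 60-microvolt artifact threshold.
#'
#' @param band_lo,band_hi Bandpass edges in Hz.
#' @param filter_order Butterworth order of the underlying one-pass filter;
#'   the applied zero-phase filter has its squared magnitude response.
#' @param resample_hz Target sampling rate in Hz.
#' @param sensor_bad_fraction Fraction of samples that must *strictly
#'   exceed* `sensor_amp_thresh_uv` for a sensor to be repaired.
#' @param sensor_amp_thresh_uv Amplitude threshold (microvolt) for repair,
#'   compared against absolute values.
#' @param n_repair_neighbors Number of nearest neighbors averaged into the
#'   replacement trace.
#' @param epoch_s Epoch length (seconds).
#' @param epoch_noise_fraction,epoch_noise_thresh_uv Reject an (epoch,
#'   sensor) pair when more than this fraction of samples exceeds this
#'   noise threshold.
#' @param epoch_artifact_thresh_uv Reject when any sample exceeds this.
#' @return A list of class `ssvep_preproc_config`.
#' @export
preproc_config <- function(band_lo = 0.3, band_hi = 50, filter_order = 4L,
                           resample_hz = 420,
                           sensor_bad_fraction = 0.15,
                           sensor_amp_thresh_uv = 30,
                           n_repair_neighbors = 6L,
                           epoch_s = 1,
                           epoch_noise_fraction = 0.10,
                           epoch_noise_thresh_uv = 30,
                           epoch_artifact_thresh_uv = 60) {
  stopifnot(band_lo > 0, band_lo < band_hi, band_hi < resample_hz / 2,
            sensor_bad_fraction > 0, sensor_bad_fraction < 1,
            epoch_noise_fraction > 0, epoch_noise_fraction < 1,
            sensor_amp_thresh_uv > 0, epoch_noise_thresh_uv > 0,
            epoch_artifact_thresh_uv > 0, epoch_s > 0)
  structure(as.list(environment()), class = "ssvep_preproc_config")
}

# squared-magnitude response of an order-n digital Butterworth bandpass
# (bilinear transform); this is the net gain of forward-backward filtering
butter_bp_gain2 <- function(f, lo, hi, fs, order) {
  W <- tan(pi * abs(f) / fs)
  W1 <- tan(pi * lo / fs); W2 <- tan(pi * hi / fs)
  g <- numeric(length(f))
  nz <- W > 0
  Om <- abs((W[nz]^2 - W1 * W2) / (W[nz] * (W2 - W1)))
  g[nz] <- 1 / (1 + Om^(2 * order))
  g
}

fft_freqs <- function(n, fs) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Zero-phase bandpass filter
#'
#' Applies the squared magnitude response of a Butterworth bandpass with
#' exactly zero phase, via the FFT — the deterministic equivalent of
#' forward-backward (filtfilt) filtering without edge transients. DC is
#' removed exactly.
#'
#' @param rec An `ssvep_recording`.
#' @param cfg A [preproc_config()].
#' @return The filtered recording.
#' @export
bandpass <- function(rec, cfg = preproc_config()) {
  stopifnot(inherits(rec, "ssvep_recording"))
  if (rec$fs <= 2 * cfg$band_hi) {
    stop("sampling rate ", rec$fs, " Hz must exceed twice the upper band ",
         "edge ", cfg$band_hi, " Hz")
  }
  n <- ncol(rec$data)
  gain <- butter_bp_gain2(fft_freqs(n, rec$fs), cfg$band_lo, cfg$band_hi,
                          rec$fs, cfg$filter_order)
  F <- stats::mvfft(t(rec$data))                 # freq x sensor
  rec$data <- t(Re(stats::mvfft(F * gain, inverse = TRUE)) / n)
  rec
}

# Fourier-domain resampling of a sensor x time matrix (exact for on-bin
# band-limited content; duration is preserved)
fft_resample <- function(X, n_new) {
  n <- ncol(X)
  if (n_new == n) return(X)
  F <- stats::mvfft(t(X))                        # n x sensors
  G <- matrix(0+0i, n_new, nrow(X))
  kc <- min(n, n_new) %/% 2
  G[1, ] <- F[1, ]
  if (kc >= 1) {
    ks <- seq_len(max(kc - 1L, 0L))
    if (length(ks)) {
      G[1L + ks, ] <- F[1L + ks, ]
      G[n_new + 1L - ks, ] <- F[n + 1L - ks, ]
    }
    # edge bin at k = kc: fold when truncating to even n_new, split the
    # (real) Nyquist bin when extending from even n, copy both otherwise
    if (n_new < n && n_new %% 2 == 0) {
      G[1L + kc, ] <- 2 * Re(F[1L + kc, ])
    } else if (n_new > n && n %% 2 == 0) {
      G[1L + kc, ] <- F[1L + kc, ] / 2
      G[n_new + 1L - kc, ] <- F[1L + kc, ] / 2
    } else {
      G[1L + kc, ] <- F[1L + kc, ]
      G[n_new + 1L - kc, ] <- F[n + 1L - kc, ]
    }
  }
  t(Re(stats::mvfft(G, inverse = TRUE)) / n)
}

#' Resample a recording
#'
#' Fourier resampling to `target_hz`; trial duration is preserved and any
#' on-bin sinusoid below the new Nyquist keeps its amplitude and phase.
#'
#' @param rec An `ssvep_recording`.
#' @param target_hz New sampling rate; `target_hz * duration` must be an
#'   integer.
#' @return The resampled recording with `fs = target_hz`.
#' @export
resample <- function(rec, target_hz = 420) {
  stopifnot(inherits(rec, "ssvep_recording"), target_hz > 0)
  dur <- ncol(rec$data) / rec$fs
  n_new <- target_hz * dur
  if (abs(n_new - round(n_new)) > 1e-9) {
    stop("target_hz * duration must be an integer number of samples")
  }
  rec$data <- fft_resample(rec$data, as.integer(round(n_new)))
  rec$fs <- target_hz
  rec
}

#' Repair bad sensors by neighbor averaging
#'
#' A sensor whose absolute amplitude exceeds the threshold on strictly more
#' than `sensor_bad_fraction` of samples is replaced, sample by sample, by
#' the mean of its `n_repair_neighbors` nearest neighbors' original traces
#' (all replacements use pre-repair data, so the result does not depend on
#' sensor order).
#'
#' @param rec An `ssvep_recording` (montage required).
#' @param cfg A [preproc_config()].
#' @return List with `recording` and `repaired` (integer sensor indices).
#' @export
repair_bad_sensors <- function(rec, cfg = preproc_config()) {
  stopifnot(inherits(rec, "ssvep_recording"))
  frac <- rowMeans(abs(rec$data) > cfg$sensor_amp_thresh_uv)
  flagged <- which(frac > cfg$sensor_bad_fraction)
  if (length(flagged) > 0.25 * nrow(rec$data)) {
    warning(sprintf("quality gate: %d of %d sensors flagged for repair",
                    length(flagged), nrow(rec$data)))
  }
  if (length(flagged)) {
    orig <- rec$data
    for (s in flagged) {
      nb <- rec$montage$adjacency[[s]][seq_len(cfg$n_repair_neighbors)]
      rec$data[s, ] <- colMeans(orig[nb, , drop = FALSE])
    }
  }
  list(recording = rec, repaired = flagged)
}

#' Re-reference to the average reference
#'
#' Subtracts the across-sensor mean at every time sample; idempotent.
#'
#' @param rec An `ssvep_recording`.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "ssvep_recording"))
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Segment into epochs and reject on a sensor-by-sensor basis
#'
#' Cuts the trial into consecutive non-overlapping epochs starting at trial
#' onset. An (epoch, sensor) pair is marked invalid when more than
#' `epoch_noise_fraction` of its samples exceed `epoch_noise_thresh_uv` in
#' absolute value, or when any sample exceeds `epoch_artifact_thresh_uv`.
#' Invalid entries are excluded from all downstream averages and
#' covariances.
#'
#' @param rec An `ssvep_recording`.
#' @param cfg A [preproc_config()].
#' @return An `ssvep_epochs` object: `data` (epoch x sensor x time array),
#'   `fs`, `valid` (epoch x sensor logical), `provenance` (rejection
#'   counts), plus the recording's identifiers.
#' @export
epoch_and_reject <- function(rec, cfg = preproc_config()) {
  stopifnot(inherits(rec, "ssvep_recording"))
  len <- cfg$epoch_s * rec$fs
  if (abs(len - round(len)) > 1e-9) {
    stop("epoch_s * fs must be an integer number of samples")
  }
  len <- as.integer(round(len))
  n_ep <- ncol(rec$data) %/% len
  if (n_ep < 1) stop("recording shorter than one epoch")
  n_sens <- nrow(rec$data)
  data <- array(NA_real_, c(n_ep, n_sens, len))
  valid <- matrix(TRUE, n_ep, n_sens)
  for (e in seq_len(n_ep)) {
    seg <- rec$data[, ((e - 1L) * len + 1L):(e * len), drop = FALSE]
    data[e, , ] <- seg
    a <- abs(seg)
    noisy <- rowMeans(a > cfg$epoch_noise_thresh_uv) > cfg$epoch_noise_fraction
    art <- apply(a, 1, max) > cfg$epoch_artifact_thresh_uv
    valid[e, ] <- !(noisy | art)
  }
  dead <- which(colSums(valid) == 0)
  if (length(dead)) {
    warning("sensor(s) ", paste(dead, collapse = ", "),
            " have no valid epochs and are dropped downstream")
  }
  structure(
    list(data = data, fs = rec$fs, valid = valid,
         provenance = list(n_rejected_pairs = sum(!valid),
                           n_epochs = n_ep, n_sensors = n_sens),
         subject_id = rec$subject_id, trial = rec$trial,
         condition_id = rec$condition_id, montage = rec$montage,
         schedule = rec$schedule),
    class = "ssvep_epochs")
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed order: bandpass, resample, bad-sensor repair, average reference,
#' epoch and reject.
#'
#' @param rec An `ssvep_recording`.
#' @param cfg A [preproc_config()].
#' @return An `ssvep_epochs` object; repaired sensors recorded in
#'   `provenance$repaired`.
#' @export
preprocess <- function(rec, cfg = preproc_config()) {
  rec <- bandpass(rec, cfg)
  rec <- resample(rec, cfg$resample_hz)
  rep <- repair_bad_sensors(rec, cfg)
  rec <- rereference_average(rep$recording)
  ep <- epoch_and_reject(rec, cfg)
  ep$provenance$repaired <- rep$repaired
  ep
}
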