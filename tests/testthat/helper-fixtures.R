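# shared fixture builders; everything is generated in code at test time

tiny_montage <- function(n = 16L) make_montage(n)

# wrap a bare sensor x time matrix as a recording
as_recording <- function(data, fs, montage = NULL,
                         schedule = make_schedule(10, 5, 12)) {
  if (is.null(montage)) montage <- make_montage(max(nrow(data), 8L))
  structure(list(data = data, fs = fs, montage = montage,
                 schedule = schedule, condition_id = "test",
                 subject_id = "S01", trial = 1L),
            class = "ssvep_recording")
}

# epochs object holding given epoch x sensor x time data, all valid
as_epochs <- function(data, fs, subject_id = "S01") {
  structure(list(data = data, fs = fs,
                 valid = matrix(TRUE, dim(data)[1], dim(data)[2]),
                 provenance = list(n_rejected_pairs = 0,
                                   n_epochs = dim(data)[1],
                                   n_sensors = dim(data)[2]),
                 subject_id = subject_id, trial = 1L,
                 condition_id = "test", montage = NULL, schedule = NULL),
            class = "ssvep_epochs")
}

# coefficients object from an epoch x sensor x freq complex array
as_coeffs <- function(coeffs, freqs, subject_id = "S01") {
  structure(list(coeffs = coeffs, freqs = freqs,
                 valid = matrix(TRUE, dim(coeffs)[1], dim(coeffs)[2]),
                 convention = "unit cosine -> 1+0i", fs = 420,
                 subject_id = subject_id, condition_id = "test"),
            class = "ssvep_coefficients")
}

# feature-space trials with two planted orthogonal sources; returns the
# trials plus the planted topographies. SNR = amplitude of the strongest
# feature of source 1 over the white-noise sd per feature entry.
plant_two_source_trials <- function(n_sensors = 24L, n_trials = 60L,
                                    snr = 5, seed = 1L,
                                    tau_ms = c(180, 260)) {
  set.seed(seed)
  freqs <- c(2, 4, 6, 8)
  amps <- rbind(c(1.2, 0.9, 0.6, 0), c(0.9, 0.6, 0, 0))
  t1 <- rnorm(n_sensors); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- rnorm(n_sensors); t2 <- t2 - sum(t2 * t1) * t1
  t2 <- t2 / sqrt(sum(t2^2))
  # intercepts chosen so the two sources' feature courses are orthogonal
  # (separable processes); same construction as condition1_world()
  phi0 <- c(pi / 2 - Arg(sum(amps[1, ] * amps[2, ] *
                               exp(-2i * pi * freqs *
                                     (tau_ms[1] - tau_ms[2]) / 1000))), 0)
  feat <- function(k) {
    ph <- phi0[k] - 2 * pi * freqs * tau_ms[k] / 1000
    as.vector(rbind(amps[k, ] * cos(ph), amps[k, ] * sin(ph)))
  }
  f1 <- feat(1); f2 <- feat(2)
  sigma <- max(amps) / snr
  trials <- lapply(seq_len(n_trials), function(i) {
    outer(t1, f1) + outer(t2, f2) +
      matrix(rnorm(n_sensors * 8, sd = sigma), n_sensors, 8)
  })
  list(trials = structure(list(trials = trials,
                               subject = rep("S01", n_trials),
                               freqs = freqs, n_sensors = n_sensors),
                          class = "ssvep_trials"),
       topographies = cbind(t1, t2))
}

# per-subject component-space coefficients for planted group delays;
# subject-level amplitude SNR = amps / noise sd of a subject's coefficient
plant_component_coefficients <- function(n_subjects = 16L, amps, freqs,
                                         tau_ms, phi0 = 0, snr = 5,
                                         seed = 1L) {
  set.seed(seed)
  sigma <- max(amps) / snr
  z <- sapply(seq_along(freqs), function(k) {
    mu <- amps[k] * exp(1i * (phi0 - 2 * pi * freqs[k] * tau_ms / 1000))
    mu + complex(real = rnorm(n_subjects, sd = sigma / sqrt(2)),
                 imaginary = rnorm(n_subjects, sd = sigma / sqrt(2)))
  })
  matrix(z, n_subjects, length(freqs))
}
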