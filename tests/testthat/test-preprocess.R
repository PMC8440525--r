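test_that("bandpass keeps passband sinusoids and kills drift and DC", {
  fs <- 500
  t <- (0:(12 * fs - 1)) / fs
  rec <- as_recording(rbind(sin(2 * pi * 5 * t),
                            cos(2 * pi * 0.05 * t),
                            rep(3, length(t))), fs)
  out <- bandpass(rec, preproc_config())
  ep <- as_epochs(array(out$data[, 1:fs], c(1, 3, fs)), fs)
  co <- spectral_coefficients(ep, 5)
  expect_equal(Mod(co$coeffs[1, 1, 1]), 1, tolerance = 0.01)
  expect_equal(Arg(co$coeffs[1, 1, 1]), -pi / 2, tolerance = 1e-3)
  # designed response: >= 20 dB down at 0.05 Hz, >= 40 dB at DC
  g <- ssveprca:::butter_bp_gain2(c(0.05, 0), 0.3, 50, fs, 4)
  expect_lt(10 * log10(g[1]), -20)
  expect_equal(g[2], 0)
  expect_lt(max(abs(rowMeans(out$data))), 1e-10)   # DC gone empirically
  expect_error(bandpass(as_recording(matrix(0, 2, 90), fs = 90)),
               "twice the upper band edge")
})

test_that("resampling preserves duration, amplitude, and phase", {
  fs <- 500
  t <- (0:(12 * fs - 1)) / fs
  rec <- as_recording(matrix(3 * cos(2 * pi * 2 * t + 0.7), 1), fs)
  out <- resample(rec, 420)
  expect_equal(ncol(out$data), 5040)               # 12 s x 420 Hz
  expect_equal(out$fs, 420)
  ep <- as_epochs(array(out$data[, 1:420], c(1, 1, 420)), 420)
  co <- spectral_coefficients(ep, 2)
  expect_equal(co$coeffs[1, 1, 1], 3 * exp(0.7i), tolerance = 1e-6)
  expect_identical(resample(out, 420)$data, out$data)   # identity
  expect_equal(420 / 60, 7)  # exact samples per 60-Hz video frame
})

test_that("bad sensors are replaced by the mean of six neighbors", {
  mon <- make_montage(16)
  X <- matrix(rnorm(16 * 1000, sd = 3), 16, 1000)
  X[5, 1:200] <- 50                                # 20% of samples at 50 uV
  rec <- as_recording(X, 500, mon)
  out <- repair_bad_sensors(rec, preproc_config())
  expect_equal(out$repaired, 5L)
  nb <- mon$adjacency[[5]][1:6]
  expect_equal(out$recording$data[5, ], colMeans(X[nb, ]), tolerance = 1e-12)
  expect_equal(out$recording$data[-5, ], X[-5, ])  # others untouched

  # exactly 15% exceeding: strictly "more than 15%" means no repair
  Y <- matrix(0, 16, 1000)
  Y[3, 1:150] <- 50
  outy <- repair_bad_sensors(as_recording(Y, 500, mon), preproc_config())
  expect_length(outy$repaired, 0)
  expect_identical(outy$recording$data, Y)

  # quality gate: many flagged sensors trigger a warning, not an error
  Z <- matrix(50, 16, 100)
  expect_warning(repair_bad_sensors(as_recording(Z, 500, mon)),
                 "quality gate")
})

test_that("average re-reference zeroes every time sample and is idempotent", {
  rec <- as_recording(matrix(rnorm(64 * 500), 64, 500) + 5, 500)
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  expect_equal(rereference_average(out)$data, out$data, tolerance = 1e-14)
  const <- rereference_average(as_recording(matrix(5, 8, 100), 100))
  expect_equal(const$data, matrix(0, 8, 100))
})

test_that("epoch rejection applies both rules sensor-by-sensor", {
  fs <- 420
  X <- matrix(rnorm(8 * 3 * fs, sd = 2), 8, 3 * fs)
  X[7, fs + 10] <- 100                             # artifact in epoch 2
  ep <- epoch_and_reject(as_recording(X, fs), preproc_config())
  expect_false(ep$valid[2, 7])
  expect_equal(sum(!ep$valid), 1)                  # only that pair
  expect_equal(ep$provenance$n_rejected_pairs, 1)

  # noise rule: 11% of samples at 35 uV (none above 60)
  Y <- matrix(0, 4, 2 * fs)
  n_noisy <- ceiling(0.11 * fs)
  Y[2, seq_len(n_noisy)] <- -35.5                  # negative: abs() applies
  epy <- epoch_and_reject(as_recording(Y, fs), preproc_config())
  expect_false(epy$valid[1, 2])
  expect_equal(sum(!epy$valid), 1)

  clean <- epoch_and_reject(as_recording(matrix(rnorm(8 * fs), 8), fs))
  expect_true(all(clean$valid))

  dead <- matrix(100, 4, 2 * fs)
  expect_warning(epoch_and_reject(as_recording(dead, fs)), "no valid epochs")
})

test_that("the chain runs in the documented order", {
  # repair-before-rereference is observable: construct a recording where a
  # bad sensor shifts the common average, so permuting the stages changes
  # the output
  mon <- make_montage(16)
  set.seed(3)
  X <- matrix(rnorm(16 * 2 * 420, sd = 2), 16, 2 * 420)
  # bad sensor: large in-band oscillation (a DC offset would be filtered)
  X[4, ] <- X[4, ] + 45 * sin(2 * pi * 5 * (0:839) / 420)
  cfg <- preproc_config(band_lo = 0.3, band_hi = 50, resample_hz = 420)
  rec <- as_recording(X, 420, mon, make_schedule(10, 5, 2))
  ref <- preprocess(rec, cfg)
  manual <- bandpass(rec, cfg)
  manual <- resample(manual, cfg$resample_hz)
  manual <- repair_bad_sensors(manual, cfg)$recording
  manual <- rereference_average(manual)
  manual <- epoch_and_reject(manual, cfg)
  expect_equal(ref$data, manual$data, tolerance = 1e-12)
  # permuted order gives a different result
  perm <- bandpass(rec, cfg)
  perm <- resample(perm, cfg$resample_hz)
  perm <- rereference_average(perm)
  perm <- repair_bad_sensors(perm, cfg)$recording
  expect_gt(max(abs(perm$data[, 1:420] - manual$data[1, , ])), 0.1)
})
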