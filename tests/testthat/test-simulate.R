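test_that("noise-free simulation is exactly the forward projection", {
  mon <- tiny_montage(16)
  sch <- make_schedule(10, 5, 2, 1)
  topo <- rep(0, 16); topo[c(3, 7)] <- c(0.8, 0.6)
  truth <- make_truth(list(make_source(topo, 2, 1, 0)),
                      amp_jitter_rel = 0, tau_jitter_ms = 0)
  ds <- simulate_recording(truth, sch, mon, fs = 420, n_subjects = 1,
                           seed = 1)
  t <- (0:(2 * 420 - 1)) / 420
  expected <- outer(c(rep(0, 2), 0.8, rep(0, 3), 0.6, rep(0, 9)),
                    cos(2 * pi * 2 * t))
  expect_equal(ds$recordings[[1]]$data, expected, tolerance = 1e-12)
})

test_that("a group delay plants the phase -2*pi*f*tau/1000", {
  mon <- tiny_montage(8)
  sch <- make_schedule(10, 5, 1, 1)
  topo <- c(1, rep(0, 7))
  truth <- make_truth(list(make_source(topo, 2, 1, 125)),  # -pi/2 at 2 Hz
                      amp_jitter_rel = 0, tau_jitter_ms = 0)
  ds <- simulate_recording(truth, sch, mon, fs = 420, n_subjects = 1,
                           seed = 1)
  ep <- epoch_and_reject(ds$recordings[[1]])
  co <- spectral_coefficients(ep, 2)
  expect_equal(Arg(co$coeffs[1, 1, 1]), -pi / 2, tolerance = 1e-9)
  expect_equal(Mod(co$coeffs[1, 1, 1]), 1, tolerance = 1e-9)
})

test_that("simulation is bit-identical under a fixed seed", {
  mon <- tiny_montage(12)
  sch <- make_schedule(10, 5, 2, 2)
  topo <- c(rep(1, 4), rep(0, 8)) / 2
  truth <- make_truth(list(make_source(topo, c(2, 4), c(1, 0.5), 180)),
                      noise_1f_scale = 2, noise_white_scale = 1)
  ds1 <- simulate_recording(truth, sch, mon, fs = 420, n_subjects = 2,
                            seed = 42)
  ds2 <- simulate_recording(truth, sch, mon, fs = 420, n_subjects = 2,
                            seed = 42)
  expect_identical(ds1$recordings[[3]]$data, ds2$recordings[[3]]$data)
  expect_identical(ds1$subject_truth, ds2$subject_truth)
})

test_that("harmonics at or above Nyquist are rejected", {
  mon <- tiny_montage(8)
  sch <- make_schedule(10, 5, 1, 1)
  truth <- make_truth(list(make_source(rep(1, 8), 210, 1, 0)))
  expect_error(simulate_recording(truth, sch, mon, fs = 420), "Nyquist")
})

test_that("1/f background power decreases across octaves", {
  # expected spectral power halves per octave; check the empirical trend
  set.seed(5)
  octave_power <- replicate(30, {
    x <- ssveprca:::pink_matrix(4096, 1)[1, ]
    sp <- Mod(fft(x))[2:2049]^2
    bands <- findInterval(1:2048, c(2, 8, 32, 128, 512))
    tapply(sp, bands, mean)
  })
  avg <- rowMeans(octave_power)
  expect_true(all(diff(avg) < 0))
})

test_that("artifact injection is exact, seeded, and optional", {
  mon <- tiny_montage(8)
  sch <- make_schedule(10, 5, 4, 1)
  rec <- as_recording(matrix(0, 8, 4 * 420), 420, mon, sch)
  expect_identical(inject_artifacts(rec, 0, 100)$recording$data, rec$data)
  a1 <- inject_artifacts(rec, 30, 100, seed = 9)
  a2 <- inject_artifacts(rec, 30, 100, seed = 9)
  expect_identical(a1$recording$data, a2$recording$data)
  expect_identical(a1$events, a2$events)
  expect_equal(nrow(a1$events), 2)  # 30/min for 4 s
  # each event stays inside its 1-s epoch
  expect_true(all(a1$events$end_sample <= a1$events$epoch * 420))
  expect_true(all(a1$events$start_sample > (a1$events$epoch - 1) * 420))
  expect_error(inject_artifacts(rec, 10, 50), "exceed 60")
})
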