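test_that("T2 statistic is phase-rotation invariant and powerful", {
  set.seed(2)
  z <- complex(real = rnorm(16, 2), imaginary = rnorm(16, -1))
  t2 <- hotelling_t2_zero(z)
  rot <- hotelling_t2_zero(z * exp(1i * 1.3))
  expect_equal(rot$statistic, t2$statistic, tolerance = 1e-10)
  expect_equal(rot$p, t2$p, tolerance = 1e-10)
  expect_equal(t2$df, c(2, 14))

  # mean offset 10x the sample SD: overwhelming evidence
  z10 <- complex(real = rnorm(16, sd = 0.1) + 1,
                 imaginary = rnorm(16, sd = 0.1))
  expect_lt(hotelling_t2_zero(z10)$p, 1e-3)

  expect_error(hotelling_t2_zero(z[1:2]), "at least 3")
  expect_error(hotelling_t2_zero(complex(real = 1:10, imaginary = 1:10) *
                                   (1 + 0i)), "singular")
})

test_that("T2 null p-values are approximately uniform", {
  set.seed(4)
  ps <- replicate(500, {
    hotelling_t2_zero(complex(real = rnorm(12), imaginary = rnorm(12)))$p
  })
  # rejection rate at 0.05 within the binomial 99% band for 500 draws
  expect_gt(mean(ps < 0.05), 0.05 - 2.58 * sqrt(0.05 * 0.95 / 500))
  expect_lt(mean(ps < 0.05), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 500))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("FDR adjustment is the Benjamini-Hochberg step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  # family larger than the computed tests
  expect_equal(fdr_adjust(c(0.01, 0.04), m = 8), c(0.08, 0.16))
  # never more discoveries than unadjusted thresholding
  set.seed(6)
  for (i in 1:20) {
    p <- runif(8)
    adj <- fdr_adjust(p)
    expect_true(all(adj >= p))
    expect_lte(sum(adj <= 0.05), sum(p <= 0.05))
    expect_equal(adj, p.adjust(p, "BH"))   # reference implementation
  }
  expect_error(fdr_adjust(numeric(0)), "empty")
})

test_that("error ellipses summarize the (re, im) covariance of the mean", {
  set.seed(8)
  iso <- complex(real = rnorm(4000), imaginary = rnorm(4000))
  e <- error_ellipse(iso)
  expect_gt(e$axes[2] / e$axes[1], 0.9)           # near-circular
  expect_false(e$degenerate)
  e3 <- error_ellipse(3 * iso)
  expect_equal(e3$axes, 3 * e$axes, tolerance = 1e-10)

  flat <- complex(real = rnorm(50), imaginary = 0)
  ef <- error_ellipse(flat)
  expect_true(ef$degenerate)
  expect_equal(abs(ssveprca::wrap_pi(ef$orientation)) %% pi, 0,
               tolerance = 1e-8)
  expect_lt(ef$axes[2], 1e-12)
})

test_that("paired circular test recovers planted phase shifts", {
  ph <- runif(16, -pi, pi)
  same <- circular_phase_test(ph, ph)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)

  set.seed(10)
  jit <- rnorm(16, sd = 0.1)
  shifted <- circular_phase_test(ph, ph + pi / 2 + jit)
  expect_equal(shifted$mean_diff, pi / 2, tolerance = 0.1)
  expect_lt(shifted$p, 0.01)

  # invariance to 2*pi shifts of any input
  shifted2 <- circular_phase_test(ph + 2 * pi, ph + pi / 2 + jit - 2 * pi)
  expect_equal(shifted2$mean_diff, shifted$mean_diff, tolerance = 1e-10)
  expect_equal(shifted2$p, shifted$p, tolerance = 1e-10)

  # antipodal differences: no mean direction
  expect_error(
    circular_phase_test(rep(0, 4), c(pi / 2, -pi / 2, pi / 2, -pi / 2)),
    "resultant")
})

test_that("watson-williams variant detects the same shift", {
  set.seed(12)
  ph <- rnorm(16, 1, 0.3)
  res <- circular_phase_test(ph, ph + pi / 3 + rnorm(16, sd = 0.2),
                             method = "watson_williams")
  expect_lt(res$p, 0.01)
})

test_that("phase differences convert to milliseconds at each frequency", {
  expect_equal(phase_diff_to_latency(pi / 2, 2), 125)
  expect_equal(phase_diff_to_latency(0, 7), 0)
  expect_equal(phase_diff_to_latency(pi, 3), 1000 / 6, tolerance = 1e-10)
  # wrapping first: 2*pi + pi/2 is the same angle
  expect_equal(phase_diff_to_latency(2 * pi + pi / 2, 2), 125)
})
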