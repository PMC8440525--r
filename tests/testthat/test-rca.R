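make_random_trials <- function(n_trials, n_sensors, n_feat = 8, sd = 1,
                               seed = 1) {
  set.seed(seed)
  structure(list(
    trials = lapply(seq_len(n_trials), function(i)
      matrix(rnorm(n_sensors * n_feat, sd = sd), n_sensors, n_feat)),
    subject = rep("S01", n_trials), freqs = seq_len(n_feat / 2),
    n_sensors = n_sensors), class = "ssvep_trials")
}

test_that("feature matrices stack (re, im) pairs and propagate masks", {
  co <- as_coeffs(array(complex(real = 1:24, imaginary = -(1:24)),
                        c(2, 3, 4)), freqs = c(2, 4, 6, 8))
  tr <- build_feature_trials(co)
  expect_length(tr$trials, 2)
  expect_equal(dim(tr$trials[[1]]), c(3, 8))      # 4 harmonics x (re, im)
  expect_equal(tr$trials[[1]][2, 3], Re(co$coeffs[1, 2, 2]))
  expect_equal(tr$trials[[1]][2, 4], Im(co$coeffs[1, 2, 2]))
  tr1 <- build_feature_trials(co, harmonics = 4)
  expect_equal(dim(tr1$trials[[1]]), c(3, 2))
  expect_error(build_feature_trials(co, harmonics = 5), "computed")

  co$coeffs[2, 1, ] <- NA
  tr2 <- build_feature_trials(co)
  expect_true(all(is.na(tr2$trials[[2]][1, ])))
  expect_false(anyNA(tr2$trials[[1]]))
})

test_that("eigenvalues and filters match a dense generalized solve", {
  for (seed in 1:5) {
    tr <- make_random_trials(40, 6, seed = seed)
    # plant a weakly reliable direction so the spectrum is non-trivial
    u <- rnorm(6)
    for (i in seq_along(tr$trials)) {
      tr$trials[[i]] <- tr$trials[[i]] + outer(u, rnorm(8, sd = 0.5))
    }
    model <- train_rca(tr, n_components = 3, rank_k = 6)
    cov <- ssveprca:::rca_covariances(tr)
    dense <- eigen(solve(cov$R_within, cov$R_across))
    vals <- Re(dense$values)
    ord <- order(vals, decreasing = TRUE)
    expect_equal(model$evals, vals[ord], tolerance = 1e-8)
    for (k in 1:3) {
      v <- Re(dense$vectors[, ord[k]])
      w <- model$W[, k]
      expect_equal(abs(sum(v * w)) / sqrt(sum(v^2) * sum(w^2)), 1,
                   tolerance = 1e-8)
    }
  }
})

test_that("a planted reliable direction is recovered", {
  set.seed(7)
  u <- rnorm(12); u <- u / sqrt(sum(u^2))
  f <- rnorm(8, sd = 2)
  tr <- make_random_trials(80, 12, sd = 0.4, seed = 8)
  for (i in seq_along(tr$trials)) tr$trials[[i]] <- tr$trials[[i]] + outer(u, f)
  model <- train_rca(tr, n_components = 2)
  expect_gt(abs(cor(model$A[, 1], u)), 0.99)
  expect_gt(model$evals[1] / abs(model$evals[2]), 5)
})

test_that("pure-noise eigenvalues sit inside the null band", {
  lam1 <- function(seed) {
    train_rca(make_random_trials(30, 6, seed = seed), n_components = 1)$evals[1]
  }
  observed <- lam1(1000)
  null <- vapply(1:99, lam1, 1)
  expect_gt(observed, quantile(null, 0.005))
  expect_lt(observed, quantile(null, 0.995))
})

test_that("forward models satisfy the activation-pattern identity", {
  tr <- make_random_trials(40, 8, seed = 3)
  model <- train_rca(tr, n_components = 3)
  G <- crossprod(model$W, model$R_within %*% model$W)
  expect_equal(model$A, model$R_within %*% model$W %*% solve(G),
               tolerance = 1e-8)
  # identity covariance + orthonormal filters: A equals W
  m2 <- model
  m2$W <- qr.Q(qr(matrix(rnorm(64), 8, 8)))[, 1:3]
  expect_equal(forward_model(m2, R_within = diag(8)), m2$W,
               tolerance = 1e-10)
  # scaling the data leaves the topography direction unchanged
  tr10 <- tr
  tr10$trials <- lapply(tr$trials, function(X) 10 * X)
  m10 <- train_rca(tr10, n_components = 3)
  expect_equal(abs(cor(m10$A[, 1], model$A[, 1])), 1, tolerance = 1e-8)
})

test_that("sign alignment is idempotent and undoes a flip", {
  tr <- make_random_trials(40, 8, seed = 4)
  u <- rnorm(8)
  for (i in seq_along(tr$trials)) {
    tr$trials[[i]] <- tr$trials[[i]] + outer(u, rnorm(8))
  }
  model <- align_signs(train_rca(tr, n_components = 2), tr)
  expect_identical(align_signs(model, tr)$W, model$W)
  flipped <- model
  flipped$W[, 1] <- -flipped$W[, 1]
  flipped$A[, 1] <- -flipped$A[, 1]
  expect_equal(align_signs(flipped, tr)$W, model$W, tolerance = 1e-12)
})

test_that("reliability fractions normalize over positive eigenvalues", {
  expect_equal(reliability_explained(c(3, 1)), c(75, 25))
  expect_equal(reliability_explained(1), 100)
  expect_equal(reliability_explained(c(2, 1, -0.5)),
               c(200 / 3, 100 / 3), tolerance = 1e-12)
  expect_error(reliability_explained(c(-1, -2)), "positive")
})

test_that("projection is the expected linear map", {
  co <- as_coeffs(array(complex(real = rnorm(24), imaginary = rnorm(24)),
                        c(2, 3, 4)), freqs = c(2, 4, 6, 8))
  tr <- build_feature_trials(co)
  model <- train_rca(make_random_trials(30, 3, seed = 6), n_components = 2)
  # indicator filter selects one sensor's coefficients
  model$W <- cbind(c(0, 1, 0), c(1, 0, 0))
  proj <- project(tr, model)
  expect_equal(proj[1, 1, ], co$coeffs[1, 2, ], tolerance = 1e-12)
  expect_equal(proj[2, 2, ], co$coeffs[2, 1, ], tolerance = 1e-12)
  # general filter: independent matrix-multiply oracle
  set.seed(9)
  model$W <- matrix(rnorm(6), 3, 2)
  proj <- project(tr, model)
  for (e in 1:2) {
    oracle <- t(model$W) %*% co$coeffs[e, , ]
    expect_equal(proj[e, , ], oracle, tolerance = 1e-12)
  }
})

test_that("topography correlations behave as Pearson r across sensors", {
  a <- rnorm(32)
  expect_equal(topography_correlation(a, a), 1)
  expect_equal(topography_correlation(a, -a), -1)
  expect_error(topography_correlation(a, rep(1, 32)), "zero-variance")
})

test_that("joint training pools conditions and demands aligned layouts", {
  tr <- make_random_trials(30, 6, seed = 12)
  u <- rnorm(6)
  for (i in seq_along(tr$trials)) {
    tr$trials[[i]] <- tr$trials[[i]] + outer(u, rnorm(8))
  }
  single <- train_rca(tr, n_components = 2)
  joint <- train_joint(list(a = tr, b = tr), n_components = 2)
  # a duplicated trial is perfectly reliable with its copy, which shifts
  # the pairwise across-trial covariance by R_within/(2n-1); eigenvectors
  # are unchanged and eigenvalues move by the exact affine law
  n <- length(tr$trials)
  expect_equal(joint$evals, (single$evals * (2 * n - 2) + 1) / (2 * n - 1),
               tolerance = 1e-8)
  expect_equal(abs(cor(joint$W[, 1], single$W[, 1])), 1, tolerance = 1e-8)
  expect_equal(abs(cor(joint$W[, 2], single$W[, 2])), 1, tolerance = 1e-8)
  bad <- make_random_trials(10, 5, seed = 13)
  expect_error(train_joint(list(tr, bad)), "incompatible")
  empty <- tr; empty$trials <- list()
  expect_error(train_joint(list(tr, empty)), "non-empty")
})
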