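#' Build per-trial feature matrices for RCA
#'
#' RCA operates on sensor x feature matrices, one per trial (here, per 1-s
#' epoch). The features are the real and imaginary Fourier coefficients of
#' the selected harmonics, stacked as (re, im) pairs. Sensors rejected in a
#' given epoch are carried as missing rows of that trial only.
#'
#' @param coeffs An `ssvep_coefficients` object (or a list of them, e.g.
#'   from several recordings; all must share sensor count and frequencies —
#'   frequency *labels* may differ across conditions as long as the layout
#'   has the same length).
#' @param harmonics Optional subset of frequencies to use (default: all).
#' @return A list of class `ssvep_trials`: `trials` (list of sensor x
#'   (2 * n_harmonics) matrices with `NA` rows for missing sensors),
#'   `subject` (character per trial), `freqs`, `n_sensors`.
#' @export
build_feature_trials <- function(coeffs, harmonics = NULL) {
  if (inherits(coeffs, "ssvep_coefficients")) coeffs <- list(coeffs)
  stopifnot(length(coeffs) >= 1,
            all(vapply(coeffs, inherits, TRUE, "ssvep_coefficients")))
  f0 <- coeffs[[1]]$freqs
  sel <- if (is.null(harmonics)) seq_along(f0) else match(harmonics, f0)
  if (anyNA(sel)) {
    stop("harmonic subset must be among the computed frequencies (",
         paste(f0, collapse = ", "), " Hz)")
  }
  trials <- list(); subject <- character(0)
  for (co in coeffs) {
    n_ep <- dim(co$coeffs)[1]
    for (e in seq_len(n_ep)) {
      M <- co$coeffs[e, , sel, drop = FALSE]
      dim(M) <- dim(M)[2:3]                  # sensor x harmonic, complex
      X <- matrix(NA_real_, nrow(M), 2L * ncol(M))
      X[, seq(1, ncol(X), 2)] <- Re(M)
      X[, seq(2, ncol(X), 2)] <- Im(M)
      trials[[length(trials) + 1L]] <- X
      subject <- c(subject, co$subject_id %||% "S?")
    }
  }
  if (!length(trials)) stop("empty trial set")
  structure(list(trials = trials, subject = subject,
                 freqs = f0[sel], n_sensors = nrow(trials[[1]])),
            class = "ssvep_trials")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# accumulate across/within covariance with pairwise-complete counts.
# sum identity: sum over ordered pairs i != j of X_i t(X_j)
#             = S t(S) - sum_i X_i t(X_i), with S = sum_i X_i.
rca_covariances <- function(trials) {
  n_sens <- nrow(trials$trials[[1]])
  n_feat <- ncol(trials$trials[[1]])
  S <- matrix(0, n_sens, n_feat)
  Wsum <- matrix(0, n_sens, n_sens)
  M <- numeric(n_sens)                      # per-sensor trial counts
  Cw <- matrix(0, n_sens, n_sens)           # pairwise within counts
  for (X in trials$trials) {
    m <- as.numeric(!is.na(X[, 1]))
    X0 <- X; X0[is.na(X0)] <- 0
    S <- S + X0
    Wsum <- Wsum + tcrossprod(X0)
    M <- M + m
    Cw <- Cw + tcrossprod(m)
  }
  Ca <- tcrossprod(M) - Cw                  # ordered cross-pair counts
  P <- tcrossprod(S) - Wsum
  if (any(Ca == 0) || any(Cw == 0)) {
    warning("some sensor pairs have no complete observations; ",
            "their covariance entries are set to zero")
  }
  n_feat_eff <- n_feat
  Ra <- P / pmax(Ca, 1) / n_feat_eff
  Ra <- (Ra + t(Ra)) / 2
  Rw <- Wsum / pmax(Cw, 1) / n_feat_eff
  Rw <- (Rw + t(Rw)) / 2
  list(R_across = Ra, R_within = Rw)
}

#' Train a Reliable Components Analysis model
#'
#' Solves the generalized eigenproblem maximizing across-trial covariance
#' relative to pooled within-trial covariance of the (re, im) coefficient
#' features: `R_across w = lambda R_within w`. The across-trial covariance
#' is the symmetrized mean cross-covariance over all ordered trial pairs
#' (computed by the sum identity, so cost is linear in trials); the within
#' covariance is the mean per-trial covariance, both with
#' pairwise-complete normalization over the missing-sensor masks. The
#' problem is solved inside the top-`rank_k` principal subspace of
#' `R_within` (whitening), which regularizes rank deficiency; components
#' are returned in sensor space, ordered by decreasing eigenvalue.
#'
#' @param trials An `ssvep_trials` object.
#' @param n_components Number of components to retain (default 3).
#' @param rank_k Dimensionality of the principal subspace; default keeps
#'   eigenvalues of `R_within` at or above `rank_tol` relative to the
#'   largest.
#' @param rank_tol Relative eigenvalue cutoff for the default rank choice.
#' @return An `ssvep_rca` model: `W` (sensor x component spatial filters),
#'   `A` (forward-model topographies), `evals` (all eigenvalues in the
#'   retained subspace, decreasing), `reliability` (percent of reliability
#'   explained per retained component), `rank_k`, `R_within`, `R_across`,
#'   `n_features`.
#' @export
train_rca <- function(trials, n_components = 3L, rank_k = NULL,
                      rank_tol = 1e-4) {
  stopifnot(inherits(trials, "ssvep_trials"))
  if (length(trials$trials) < 2) stop("at least 2 trials are required")
  cov <- rca_covariances(trials)
  Rw <- cov$R_within; Ra <- cov$R_across
  ew <- eigen(Rw, symmetric = TRUE)
  pos <- ew$values > rank_tol * ew$values[1]
  k_auto <- sum(pos)
  if (is.null(rank_k)) {
    rank_k <- k_auto
  } else if (rank_k > k_auto) {
    warning("R_within is rank deficient beyond rank_k = ", rank_k,
            "; reducing to ", k_auto)
    rank_k <- k_auto
  }
  if (n_components > rank_k) {
    stop("n_components (", n_components, ") exceeds usable rank (", rank_k,
         ")")
  }
  Y <- ew$vectors[, seq_len(rank_k), drop = FALSE] %*%
    diag(1 / sqrt(ew$values[seq_len(rank_k)]), rank_k)
  Mh <- crossprod(Y, Ra %*% Y)
  Mh <- (Mh + t(Mh)) / 2
  eh <- eigen(Mh, symmetric = TRUE)
  W <- Y %*% eh$vectors[, seq_len(n_components), drop = FALSE]
  evals <- eh$values
  pos_sum <- sum(evals[evals > 0])
  rel <- ifelse(evals > 0 & pos_sum > 0, 100 * evals / pos_sum, NA_real_)
  model <- structure(
    list(W = W, A = NULL, evals = evals,
         reliability = rel[seq_len(n_components)],
         rank_k = rank_k, n_components = n_components,
         R_within = Rw, R_across = Ra,
         n_features = ncol(trials$trials[[1]]),
         freqs = trials$freqs, sign_convention = rep(1, n_components)),
    class = "ssvep_rca")
  model$A <- forward_model(model)
  model
}

#' @export
print.ssvep_rca <- function(x, ...) {
  cat(sprintf("RCA model: %d components over %d sensors (rank %d)\n",
              x$n_components, nrow(x$W), x$rank_k))
  cat(sprintf("  reliability explained: %s\n",
              paste(sprintf("%.1f%%", x$reliability), collapse = ", ")))
  invisible(x)
}

#' Forward-model topographies of spatial filters
#'
#' Converts extraction filters W into activation patterns suitable for
#' scalp visualization: `A = R_within W (t(W) R_within W)^-1`. With
#' orthonormal filters and identity covariance, A equals W.
#'
#' @param model A trained `ssvep_rca` model.
#' @param R_within Optional covariance override (defaults to the model's).
#' @return Sensor x component matrix of topographies.
#' @export
forward_model <- function(model, R_within = NULL) {
  stopifnot(inherits(model, "ssvep_rca"))
  Rw <- R_within %||% model$R_within
  G <- crossprod(model$W, Rw %*% model$W)
  if (rcond(G) < 1e-12) stop("t(W) R_within W is singular")
  Rw %*% model$W %*% solve(G)
}

#' Resolve the sign ambiguity of eigenvector filters
#'
#' Eigenvectors carry arbitrary signs. Each component's sign is flipped so
#' that its projected feature course correlates positively with the raw
#' data at the sensor where its forward-model topography has maximal
#' absolute weight (the automated analogue of matching components to raw
#' sensor data by maximal correlation). Idempotent.
#'
#' @param model A trained `ssvep_rca` model.
#' @param trials The `ssvep_trials` used for training (or compatible data).
#' @return The model with aligned `W`, `A` and `sign_convention` updated.
#' @export
align_signs <- function(model, trials) {
  stopifnot(inherits(model, "ssvep_rca"), inherits(trials, "ssvep_trials"))
  for (cc in seq_len(model$n_components)) {
    ref <- which.max(abs(model$A[, cc]))
    xs <- c(); ys <- c()
    for (X in trials$trials) {
      if (is.na(X[ref, 1])) next
      ok <- !is.na(X[, 1])
      y <- as.numeric(crossprod(model$W[ok, cc, drop = FALSE],
                                X[ok, , drop = FALSE]))
      xs <- c(xs, X[ref, ]); ys <- c(ys, y)
    }
    if (!length(xs) || stats::sd(ys) == 0 || stats::sd(xs) == 0) {
      warning("component ", cc, ": zero-variance projection; sign unchanged")
      next
    }
    if (stats::cor(xs, ys) < 0) {
      model$W[, cc] <- -model$W[, cc]
      model$A[, cc] <- -model$A[, cc]
      model$sign_convention[cc] <- -model$sign_convention[cc]
    }
  }
  model
}

#' Percent reliability explained per component
#'
#' Each retained positive eigenvalue as a percentage of the sum of
#' positive eigenvalues; components with non-positive eigenvalues are
#' dropped from the output.
#'
#' @param evals Numeric eigenvalues, decreasing.
#' @return Percentages for the positive eigenvalues.
#' @export
reliability_explained <- function(evals) {
  stopifnot(is.numeric(evals), length(evals) >= 1)
  pos <- evals > 0
  if (!any(pos)) stop("no positive eigenvalues: nothing reliable to explain")
  100 * evals[pos] / sum(evals[pos])
}

#' Project trials through an RCA model
#'
#' Applies each spatial filter to the real and imaginary parts separately
#' and recombines them, giving one complex coefficient per trial,
#' component and harmonic. Missing sensors within a trial are excluded
#' from the inner product (zero-filled), matching the pairwise-complete
#' policy used in training.
#'
#' @param trials An `ssvep_trials` object.
#' @param model A trained `ssvep_rca` model.
#' @return An array trial x component x harmonic of complex values, with
#'   attribute `"subject"` carrying per-trial subject ids.
#' @export
project <- function(trials, model) {
  stopifnot(inherits(trials, "ssvep_trials"), inherits(model, "ssvep_rca"))
  if (trials$n_sensors != nrow(model$W)) {
    stop("sensor count mismatch between trials (", trials$n_sensors,
         ") and model (", nrow(model$W), ")")
  }
  n_h <- model$n_features / 2
  out <- array(NA_complex_,
               c(length(trials$trials), model$n_components, n_h))
  for (i in seq_along(trials$trials)) {
    X <- trials$trials[[i]]
    X[is.na(X)] <- 0
    Y <- crossprod(model$W, X)                 # comp x 2h
    out[i, , ] <- Y[, seq(1, 2 * n_h, 2), drop = FALSE] +
      1i * Y[, seq(2, 2 * n_h, 2), drop = FALSE]
  }
  attr(out, "subject") <- trials$subject
  attr(out, "freqs") <- trials$freqs
  out
}

#' Pearson correlation between two topographies
#'
#' @param a,b Sensor-value vectors on the same montage.
#' @return Pearson r across sensors.
#' @export
topography_correlation <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance topography: correlation undefined")
  }
  stats::cor(a, b)
}

#' Train RCA jointly over several conditions
#'
#' Pools all conditions' trials into one training set so that projections
#' of the individual conditions live in a shared component space and are
#' directly comparable. Feature layouts (sensor count and number of
#' harmonic slots) must align; the harmonic frequency labels may differ.
#'
#' @param trials_by_condition Named list of `ssvep_trials`.
#' @param ... Passed to [train_rca()].
#' @return An `ssvep_rca` model trained on the pooled trials.
#' @export
train_joint <- function(trials_by_condition, ...) {
  stopifnot(is.list(trials_by_condition), length(trials_by_condition) >= 1)
  for (tr in trials_by_condition) {
    if (!inherits(tr, "ssvep_trials") || !length(tr$trials)) {
      stop("every condition must supply a non-empty ssvep_trials object")
    }
  }
  ns <- vapply(trials_by_condition, function(t) t$n_sensors, 1)
  nf <- vapply(trials_by_condition, function(t) ncol(t$trials[[1]]), 1)
  if (length(unique(ns)) != 1 || length(unique(nf)) != 1) {
    stop("conditions have incompatible feature layouts (sensors: ",
         paste(ns, collapse = "/"), "; features: ",
         paste(nf, collapse = "/"), ")")
  }
  pooled <- structure(
    list(trials = do.call(c, lapply(trials_by_condition, `[[`, "trials")),
         subject = do.call(c, lapply(trials_by_condition, `[[`, "subject")),
         freqs = trials_by_condition[[1]]$freqs,
         n_sensors = ns[1]),
    class = "ssvep_trials")
  train_rca(pooled, ...)
}
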