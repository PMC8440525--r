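#' Per-subject mean component responses
#'
#' Averages projected complex coefficients across each subject's valid
#' epochs. Per-subject averaging precedes all group statistics: tests are
#' performed across the distribution of participants, not epochs.
#'
#' @param projected Array trial x component x harmonic of complex values
#'   from [project()], with a `"subject"` attribute.
#' @return An `ssvep_group` object: `means` (subject x component x
#'   harmonic complex array), `subjects`, `freqs`, `n_subjects`.
#' @export
group_component_response <- function(projected) {
  subj <- attr(projected, "subject")
  stopifnot(!is.null(subj), length(subj) == dim(projected)[1])
  ids <- unique(subj)
  means <- array(NA_complex_, c(length(ids), dim(projected)[2:3]))
  for (i in seq_along(ids)) {
    rows <- which(subj == ids[i])
    block <- projected[rows, , , drop = FALSE]
    means[i, , ] <- apply(block, c(2, 3), function(z) mean(z, na.rm = TRUE))
  }
  structure(list(means = means, subjects = ids,
                 freqs = attr(projected, "freqs"),
                 n_subjects = length(ids)),
            class = "ssvep_group")
}

#' Hotelling T-squared test of a complex mean against zero
#'
#' Treats each subject's complex coefficient as a bivariate (re, im)
#' observation and tests whether the population mean differs from the
#' origin (origin = no stimulus-locked response):
#' `T2 = n * t(m) solve(S) m`, referred to an F distribution with
#' (2, n - 2) degrees of freedom via `F = (n - 2) / (2 * (n - 1)) * T2`.
#' The statistic is invariant to a common phase rotation of all samples.
#'
#' @param samples Complex vector, one value per subject.
#' @return A list of class `ssvep_t2`: `statistic` (T2), `F`, `df`, `p`,
#'   `n`.
#' @export
hotelling_t2_zero <- function(samples) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 3) stop("at least 3 subjects are required")
  X <- cbind(Re(samples), Im(samples))
  m <- colMeans(X)
  S <- stats::cov(X)
  if (rcond(S) < 1e-14) {
    stop("singular sample covariance (collinear re/im values); T2 undefined")
  }
  T2 <- n * drop(t(m) %*% solve(S, m))
  Fstat <- (n - 2) / (2 * (n - 1)) * T2
  p <- stats::pf(Fstat, 2, n - 2, lower.tail = FALSE)
  structure(list(statistic = T2, F = Fstat, df = c(2, n - 2), p = p, n = n),
            class = "ssvep_t2")
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1. The
#' family size `m` may exceed the number of supplied p-values (tests
#' counted in the family but not computed).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Family size (default `length(p_values)`).
#' @return Adjusted p-values in the input order; significance at level
#'   alpha is `adjusted <= alpha`.
#' @export
fdr_adjust <- function(p_values, m = length(p_values)) {
  if (!length(p_values)) stop("empty p-value vector")
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
            m >= length(p_values))
  ord <- order(p_values)
  k <- length(p_values)
  raw <- p_values[ord] * m / seq_len(k)
  adj <- rev(cummin(rev(raw)))
  adj <- pmin(adj, 1)
  out <- numeric(k)
  out[ord] <- adj
  out
}

#' Standard-error ellipse of a complex sample mean
#'
#' Summarizes amplitude and phase uncertainty of a group mean in the
#' complex plane: semi-axes and orientation come from the eigenstructure
#' of the (re, im) covariance divided by n.
#'
#' @param samples Complex vector (n >= 3).
#' @return List of class `ssvep_ellipse`: `center` (complex mean), `axes`
#'   (semi-axis lengths, decreasing), `orientation` (radians of the major
#'   axis), `degenerate` (TRUE when the samples are collinear).
#' @export
error_ellipse <- function(samples) {
  samples <- samples[!is.na(samples)]
  n <- length(samples)
  if (n < 3) stop("at least 3 samples are required")
  X <- cbind(Re(samples), Im(samples))
  S <- stats::cov(X) / n
  e <- eigen(S, symmetric = TRUE)
  axes <- sqrt(pmax(e$values, 0))
  structure(list(center = mean(samples), axes = axes,
                 orientation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
                 degenerate = axes[2] < 1e-12 * max(axes[1], 1e-300)),
            class = "ssvep_ellipse")
}

#' Wrap angles to (-pi, pi]
#'
#' @param x Radians.
#' @return Wrapped values.
#' @export
wrap_pi <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

circ_mean <- function(x) Arg(mean(exp(1i * x)))
circ_resultant <- function(x) Mod(mean(exp(1i * x)))

# maximum-likelihood-ish concentration estimate (Fisher's A1 inverse)
kappa_est <- function(R, n) {
  k <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  if (n <= 15 && k < 2) k <- max(k - 2 / (n * k), 0)
  k
}

#' Paired circular comparison of two phase distributions
#'
#' Computes per-subject phase differences, their circular mean (wrapped to
#' (-pi, pi]) and a test of zero mean direction. The default paired test
#' uses the von Mises approximation for the circular mean direction: with
#' resultant length R and concentration kappa, the mean direction is
#' approximately normal with standard error `1 / sqrt(n * R * kappa)`. A
#' two-sample Watson-Williams variant (equal-concentration F test,
#' ignoring the pairing) is available for comparison.
#'
#' @param phases_rc1,phases_rc2 Per-subject phases in radians (paired).
#' @param method "paired" (default) or "watson_williams".
#' @return List of class `ssvep_circtest`: `mean_diff` (circular mean of
#'   rc2 - rc1, radians in (-pi, pi]), `p`, `method`, `n`, `resultant`.
#' @export
circular_phase_test <- function(phases_rc1, phases_rc2,
                                method = c("paired", "watson_williams")) {
  method <- match.arg(method)
  stopifnot(length(phases_rc1) == length(phases_rc2))
  ok <- !is.na(phases_rc1) & !is.na(phases_rc2)
  p1 <- phases_rc1[ok]; p2 <- phases_rc2[ok]
  n <- length(p1)
  if (n < 3) stop("at least 3 paired samples are required")
  d <- wrap_pi(p2 - p1)
  R <- circ_resultant(d)
  if (R < 1e-12) stop("zero resultant length: mean direction undefined")
  mu <- wrap_pi(circ_mean(d))
  if (R < 0.45) {
    warning("low resultant length (", signif(R, 2),
            "): the parametric mean-direction test may be unreliable")
  }
  if (method == "paired") {
    if (R > 1 - 1e-12) {
      p <- if (abs(mu) < 1e-12) 1 else 0
    } else {
      kap <- kappa_est(R, n)
      se <- 1 / sqrt(n * R * kap)
      p <- 2 * stats::pnorm(abs(mu) / se, lower.tail = FALSE)
    }
  } else {
    # Watson-Williams one-way test between the two groups of phases
    R1 <- circ_resultant(p1); R2 <- circ_resultant(p2)
    Rall <- circ_resultant(c(p1, p2))
    rw <- (n * R1 + n * R2) / (2 * n)
    kap <- kappa_est(rw, 2 * n)
    corr <- 1 + 3 / (8 * kap)
    num <- (2 * n - 2) * (n * R1 + n * R2 - 2 * n * Rall)
    den <- (2 * n - n * R1 - n * R2)
    Fstat <- corr * num / den
    p <- stats::pf(max(Fstat, 0), 1, 2 * n - 2, lower.tail = FALSE)
  }
  structure(list(mean_diff = mu, p = p, method = method, n = n,
                 resultant = R),
            class = "ssvep_circtest")
}

#' Convert a phase difference to a latency difference
#'
#' At frequency f, a phase shift of `delta_phi` radians corresponds to
#' `delta_phi / (2 * pi * f) * 1000` milliseconds; the input is wrapped to
#' (-pi, pi] first. Under the convention that delay lowers phase, pass
#' `phase_earlier - phase_later` to obtain a positive latency difference.
#'
#' @param delta_phi Phase difference in radians.
#' @param f Frequency in Hz (> 0).
#' @return Latency difference in milliseconds.
#' @examples
#' phase_diff_to_latency(pi / 2, 2)   # 125 ms
#' phase_diff_to_latency(pi, 3)       # 166.67 ms
#' @export
phase_diff_to_latency <- function(delta_phi, f) {
  stopifnot(f > 0)
  wrap_pi(delta_phi) / (2 * pi * f) * 1000
}
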