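#' Unwrap phases across harmonics assuming a fixed group delay
#'
#' A fixed processing delay makes phase decrease linearly with frequency,
#' but measured phases are only known modulo 2*pi. This routine adds an
#' integer multiple of 2*pi to each point (branch window `|k| <= max_k`,
#' first point pinned at k = 0 since a common offset does not change the
#' slope) to minimize the squared deviation from the best-fitting line
#' with non-positive slope. Among branch choices whose residuals tie
#' within `tie_tol`, the one implying the smallest physical delay |tau| is
#' chosen and the ambiguity is flagged.
#'
#' @param freqs Strictly increasing frequencies (Hz).
#' @param wrapped_phases Phases in (-pi, pi], one per frequency.
#' @param max_k Branch window half-width per point (default 4).
#' @param tie_tol Residual tie tolerance (default 1e-6).
#' @return Numeric vector of unwrapped phases; attribute `"ambiguous"` is
#'   TRUE when two branch windows tied.
#' @export
unwrap_phases <- function(freqs, wrapped_phases, max_k = 4L,
                          tie_tol = 1e-6) {
  stopifnot(length(freqs) == length(wrapped_phases),
            !is.unsorted(freqs, strictly = TRUE))
  m <- length(freqs)
  if (m <= 1) {
    out <- wrapped_phases
    attr(out, "ambiguous") <- FALSE
    return(out)
  }
  if (m > 6L) {
    # exhaustive enumeration is exponential; pre-unwrap sequentially and
    # only search a narrow window around that solution
    for (j in 2:m) {
      wrapped_phases[j] <- wrapped_phases[j - 1] +
        wrap_pi(wrapped_phases[j] - wrapped_phases[j - 1])
    }
    max_k <- 1L
  }
  ks <- -max_k:max_k
  # enumerate branch vectors (k_1 = 0); fit a line per candidate, keep the
  # non-positive-slope fit with minimal SSE
  grid <- as.matrix(expand.grid(rep(list(ks), m - 1L)))
  best <- NULL; best_sse <- Inf; best_tau <- Inf; ambiguous <- FALSE
  X <- cbind(1, freqs)
  XtXinv <- solve(crossprod(X))
  H <- XtXinv %*% t(X)
  for (r in seq_len(nrow(grid))) {
    ph <- wrapped_phases + 2 * pi * c(0, grid[r, ])
    beta <- H %*% ph
    slope <- beta[2]
    if (slope > 1e-12) {
      # refit with slope clamped to zero: residual around the mean
      slope <- 0
      res <- ph - mean(ph)
    } else {
      res <- ph - X %*% beta
    }
    sse <- sum(res^2)
    tau <- -slope / (2 * pi) * 1000
    if (sse < best_sse - tie_tol) {
      best <- ph; best_sse <- sse; best_tau <- tau; ambiguous <- FALSE
    } else if (sse < best_sse + tie_tol && abs(tau - best_tau) > 1e-9) {
      ambiguous <- TRUE
      if (abs(tau) < abs(best_tau)) {
        best <- ph; best_sse <- sse; best_tau <- tau
      }
    }
  }
  out <- as.numeric(best)
  attr(out, "ambiguous") <- ambiguous
  if (ambiguous) {
    message("phase unwrapping ambiguous; smallest-|tau| branch chosen ",
            "(tau = ", signif(best_tau, 4), " ms)")
  }
  out
}

#' Fit a line through phase versus frequency (group delay)
#'
#' Ordinary least squares of unwrapped phase on frequency,
#' `phi(f) = b + s * f`; the group delay is `tau = -s / (2 * pi) * 1000`
#' ms (delay lowers phase, so the slope of a physical delay is negative).
#' The slope's standard error is propagated to `se_ms` when three or more
#' points are available; with exactly two points the fit is exact and the
#' standard error is unavailable.
#'
#' @param freqs Frequencies (Hz), at least 2.
#' @param unwrapped_phases Unwrapped phases (radians).
#' @return An `ssvep_latency` object: `tau_ms`, `se_ms` (NA when
#'   unavailable), `intercept` (radians), `harmonics_used`,
#'   `fit_residual` (RMS radians), `estimable`.
#' @export
fit_phase_slope <- function(freqs, unwrapped_phases) {
  stopifnot(length(freqs) == length(unwrapped_phases))
  m <- length(freqs)
  if (m < 2) stop("at least 2 points are required to fit a phase slope")
  fit <- stats::lm(unwrapped_phases ~ freqs)
  s <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  tau_ms <- -s / (2 * pi) * 1000
  se_ms <- NA_real_
  if (m >= 3) {
    # zero-residual fits trip lm's "perfect fit" warning; SE 0 is correct
    se_s <- suppressWarnings(summary(fit)$coefficients[2, 2])
    se_ms <- se_s / (2 * pi) * 1000
  }
  structure(list(tau_ms = tau_ms, se_ms = se_ms, intercept = b,
                 harmonics_used = freqs,
                 fit_residual = sqrt(mean(stats::residuals(fit)^2)),
                 estimable = TRUE),
            class = "ssvep_latency")
}

#' @export
print.ssvep_latency <- function(x, ...) {
  if (!x$estimable) {
    cat("latency not estimable:", x$reason, "\n")
  } else {
    cat(sprintf("latency %.2f ms%s over harmonics %s Hz\n", x$tau_ms,
                if (is.na(x$se_ms)) " (SE unavailable)"
                else sprintf(" +/- %.2f", x$se_ms),
                paste(x$harmonics_used, collapse = ", ")))
  }
  invisible(x)
}

not_estimable <- function(reason) {
  structure(list(tau_ms = NA_real_, se_ms = NA_real_, intercept = NA_real_,
                 harmonics_used = numeric(0), fit_residual = NA_real_,
                 estimable = FALSE, reason = reason),
            class = "ssvep_latency")
}

#' Estimate a component's latency from significant harmonics
#'
#' Selects the harmonics with FDR-significant responses, takes the phase
#' of the group-mean complex coefficient (coherent average across
#' subjects) at each, unwraps assuming a fixed group delay, and fits the
#' phase slope. With fewer than two significant harmonics the latency is
#' reported as not estimable (no error), mirroring how conditions with a
#' single significant harmonic are reported.
#'
#' @param group An `ssvep_group` from [group_component_response()].
#' @param component Component index.
#' @param significant Logical vector over the group's harmonics (e.g.
#'   `p_fdr <= alpha` per harmonic for this component).
#' @return An `ssvep_latency` object (`estimable = FALSE` when fewer than
#'   two significant harmonics).
#' @export
estimate_component_latency <- function(group, component, significant) {
  stopifnot(inherits(group, "ssvep_group"),
            length(significant) == length(group$freqs))
  sel <- which(significant)
  if (length(sel) < 2) {
    return(not_estimable(sprintf(
      "only %d significant harmonic(s); at least 2 are needed",
      length(sel))))
  }
  zbar <- apply(group$means[, component, sel, drop = FALSE], 3,
                function(z) mean(z, na.rm = TRUE))
  ph <- wrap_pi(Arg(zbar))
  unw <- unwrap_phases(group$freqs[sel], ph)
  fit_phase_slope(group$freqs[sel], unw)
}
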