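#' Enumerate analysis harmonics for a base or deviant response
#'
#' Base analyses use the first `n_harmonics` multiples of the base rate.
#' Deviant analyses use multiples of the deviant rate; in alternation
#' designs (deviant = base/2) every even deviant harmonic coincides with a
#' base harmonic, so the deviant set is restricted to deviant multiples
#' that are not base multiples (the odd harmonics), with the skipped base
#' multiples reported.
#'
#' @param deviant_hz Frequency whose multiples are enumerated (pass the
#'   base rate itself for a base analysis).
#' @param base_hz Base rate (Hz); must be an integer multiple of
#'   `deviant_hz`.
#' @param n_harmonics Number of frequencies returned.
#' @param exclude_base If TRUE, drop deviant multiples that are also base
#'   multiples.
#' @return An object of class `ssvep_harmonics`: `role` ("base" or
#'   "deviant"), `frequencies`, `excluded`, `rule`.
#' @examples
#' enumerate_harmonics(2, 10, 4)$frequencies             # 2 4 6 8
#' enumerate_harmonics(3, 6, 4, exclude_base = TRUE)     # 3 9 15 21
#' enumerate_harmonics(10, 10, 4)$frequencies            # 10 20 30 40
#' @export
enumerate_harmonics <- function(deviant_hz, base_hz, n_harmonics = 4L,
                                exclude_base = FALSE) {
  stopifnot(deviant_hz > 0, base_hz > 0, n_harmonics >= 1)
  ratio <- base_hz / deviant_hz
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("base_hz (", base_hz, ") must be an integer multiple of ",
         "deviant_hz (", deviant_hz, ")")
  }
  role <- if (deviant_hz == base_hz) "base" else "deviant"
  is_base_multiple <- function(f) {
    m <- f / base_hz
    abs(m - round(m)) < 1e-9
  }
  if (!exclude_base) {
    freqs <- deviant_hz * seq_len(n_harmonics)
    excluded <- numeric(0)
    rule <- sprintf("first %d multiples of %g Hz", n_harmonics, deviant_hz)
  } else {
    if (role == "base") {
      stop("exclusion is meaningful only for a deviant analysis")
    }
    freqs <- numeric(0)
    k <- 0
    while (length(freqs) < n_harmonics) {
      k <- k + 1
      f <- deviant_hz * k
      if (!is_base_multiple(f)) freqs <- c(freqs, f)
    }
    excluded <- base_hz * seq_len(n_harmonics)
    rule <- sprintf(
      "first %d multiples of %g Hz that are not multiples of %g Hz",
      n_harmonics, deviant_hz, base_hz)
  }
  structure(list(role = role, frequencies = freqs, excluded = excluded,
                 rule = rule),
            class = "ssvep_harmonics")
}

#' @export
print.ssvep_harmonics <- function(x, ...) {
  cat(sprintf("%s harmonics: %s Hz%s\n", x$role,
              paste(x$frequencies, collapse = ", "),
              if (length(x$excluded))
                paste0(" (excluded: ", paste(x$excluded, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Complex Fourier coefficients at analysis frequencies
#'
#' Converts each valid (epoch, sensor) trace to one complex coefficient per
#' analysis frequency. Amplitude convention: a unit-amplitude cosine at a
#' bin frequency with zero phase gives the coefficient 1 + 0i, so
#' `Mod(coeff)` is the microvolt amplitude of the underlying sinusoid and
#' `Arg(coeff)` its phase, measured counterclockwise from the positive real
#' axis. With 1-s epochs the bin spacing is 1 Hz and every integer analysis
#' frequency sits exactly on a bin.
#'
#' The default method is the on-bin discrete Fourier coefficient (the
#' matched-filter inner product `2/N * sum(x * exp(-2i*pi*f*t))`), the
#' steady-state equivalent of a narrowband recursive least squares (RLS)
#' filter on whole epochs of exact integer cycles. `method = "rls"` runs an
#' exponentially weighted recursive estimator with forgetting factor
#' `rls_lambda` for fidelity studies; it converges to the DFT value on
#' stationary epochs.
#'
#' @param epochs An `ssvep_epochs` object.
#' @param freqs An `ssvep_harmonics` object or numeric vector (Hz). Each
#'   frequency must be an integer multiple of `1/epoch_s` (on-bin).
#' @param method "dft" (default) or "rls".
#' @param rls_lambda Forgetting factor in (0, 1) for `method = "rls"`.
#' @return An `ssvep_coefficients` object: `coeffs` (epoch x sensor x
#'   frequency complex array, `NA` where the epoch mask is invalid),
#'   `freqs`, `valid`, and the epochs' identifiers.
#' @export
spectral_coefficients <- function(epochs, freqs, method = c("dft", "rls"),
                                  rls_lambda = 0.995) {
  stopifnot(inherits(epochs, "ssvep_epochs"))
  method <- match.arg(method)
  fvec <- if (inherits(freqs, "ssvep_harmonics")) freqs$frequencies else freqs
  stopifnot(is.numeric(fvec), length(fvec) >= 1, all(fvec > 0))
  n <- dim(epochs$data)[3]
  epoch_s <- n / epochs$fs
  bins <- fvec * epoch_s
  if (any(abs(bins - round(bins)) > 1e-9)) {
    bad <- fvec[abs(bins - round(bins)) > 1e-9]
    stop("frequency(ies) ", paste(bad, collapse = ", "), " Hz are off-bin: ",
         "each analysis frequency must be an integer multiple of 1/epoch_s ",
         "= ", 1 / epoch_s, " Hz")
  }
  if (any(fvec >= epochs$fs / 2)) {
    stop("analysis frequency at or above Nyquist")
  }
  n_ep <- dim(epochs$data)[1]; n_sens <- dim(epochs$data)[2]
  tt <- (seq_len(n) - 1L) / epochs$fs
  X <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)  # time x (ep*sens)
  if (method == "dft") {
    B <- exp(-2i * pi * outer(tt, fvec))                 # time x freq
    C <- (2 / n) * crossprod(B, X)                       # freq x (ep*sens)
  } else {
    C <- matrix(0+0i, length(fvec), ncol(X))
    for (k in seq_along(fvec)) {
      e <- exp(-2i * pi * fvec[k] * tt)
      est <- rep(0+0i, ncol(X))
      lam <- rls_lambda
      # the demodulated recursive estimate ripples at 2f; averaging the
      # trailing full cycle of 2f removes it
      L <- max(1L, min(n, as.integer(round(epochs$fs / (2 * fvec[k])))))
      tail_sum <- rep(0+0i, ncol(X))
      for (t_i in seq_len(n)) {
        est <- lam * est + (1 - lam) * 2 * X[t_i, ] * e[t_i]
        if (t_i > n - L) tail_sum <- tail_sum + est / (1 - lam^t_i)
      }
      C[k, ] <- tail_sum / L
    }
  }
  coeffs <- array(t(C), c(n_ep, n_sens, length(fvec)))
  for (k in seq_along(fvec)) {
    ck <- coeffs[, , k]
    ck[!epochs$valid] <- NA_complex_
    coeffs[, , k] <- ck
  }
  structure(
    list(coeffs = coeffs, freqs = fvec, valid = epochs$valid,
         convention = "unit cosine at bin frequency, zero phase -> 1 + 0i",
         fs = epochs$fs, subject_id = epochs$subject_id,
         condition_id = epochs$condition_id),
    class = "ssvep_coefficients")
}
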