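## Time-averaged wavelet scattering transform (orders 0-2) used to featurize
## candidate pulse sources. Gabor (Gaussian-envelope, analytic) filters are
## built in the frequency domain; first order uses Q wavelets per octave over
## J octaves, second order one wavelet per octave, and coefficients are
## temporal averages of the modulus cascades, giving translation-tolerant
## descriptors of temporal and spectral structure.

.scatter_cache <- new.env(parent = emptyenv())

## frequency-domain filter bank for signal length n (normalized frequency)
scattering_filters <- function(n, J = 6L, Q = 8L, xi_max = 0.4) {
  key <- sprintf("n%d_J%d_Q%d", n, J, Q)
  if (!is.null(.scatter_cache[[key]])) return(.scatter_cache[[key]])
  f <- (seq_len(n) - 1L) / n                     # [0, 1)
  gauss <- function(xi, sigma) exp(-(f - xi)^2 / (2 * sigma^2))
  xi1 <- xi_max * 2^(-(seq_len(J * Q) - 1L) / Q)
  psi1 <- lapply(xi1, function(x) gauss(x, x * (2^(1 / Q) - 1)))
  xi2 <- xi_max * 2^(-(seq_len(J) - 1L))
  psi2 <- lapply(xi2, function(x) gauss(x, x * 0.6))
  out <- list(psi1 = psi1, xi1 = xi1, psi2 = psi2, xi2 = xi2)
  .scatter_cache[[key]] <- out
  out
}

#' Time-averaged scattering coefficients of a signal
#'
#' Computes order 0 (signal mean), order 1 (time-averaged modulus of each
#' first-order wavelet response) and order 2 (time-averaged modulus cascade
#' over all pairs with decreasing centre frequency). The coefficient layout
#' is fixed by `(J, Q)`, so vectors are comparable across signals of the
#' same length.
#'
#' @param x numeric vector, length at least `2^J`.
#' @param J number of octaves (default 6).
#' @param Q first-order wavelets per octave (default 8).
#' @return Named numeric vector of scattering coefficients.
#' @export
scattering_coeffs <- function(x, J = 6L, Q = 8L) {
  n <- length(x)
  if (n < 2^J)
    stop(sprintf("length error: need >= %d samples for J = %d octaves",
                 2^J, J), call. = FALSE)
  fl <- scattering_filters(n, J, Q)
  X <- stats::fft(x)
  n1 <- length(fl$psi1)
  s1 <- numeric(n1)
  u1 <- vector("list", n1)
  for (j in seq_len(n1)) {
    u <- Mod(stats::fft(X * fl$psi1[[j]], inverse = TRUE)) / n
    u1[[j]] <- u
    s1[j] <- mean(u)
  }
  s2 <- numeric(0); s2n <- character(0)
  for (j1 in seq_len(n1)) {
    lower <- which(fl$xi2 < fl$xi1[j1])
    if (length(lower) == 0L) next
    U <- stats::fft(u1[[j1]])
    for (j2 in lower) {
      s2 <- c(s2, mean(Mod(stats::fft(U * fl$psi2[[j2]], inverse = TRUE)) / n))
      s2n <- c(s2n, sprintf("s2_%d_%d", j1, j2))
    }
  }
  out <- c(mean(x), s1, s2)
  names(out) <- c("s0", sprintf("s1_%d", seq_len(n1)), s2n)
  out
}

#' Feature vector of a candidate source
#'
#' Scattering coefficients of the z-scored trace concatenated with those of
#' its biased autocorrelation function (lags `0..T/2`, normalized to 1 at
#' lag zero), capturing both waveform morphology and periodicity structure.
#'
#' @param trace numeric source time course.
#' @param fs sampling rate (Hz); recorded, not used in the transform.
#' @param J,Q scattering configuration (defaults 6 octaves, 8 wavelets per
#'   octave).
#' @return Named numeric feature vector (fixed length for fixed `J`, `Q`
#'   and trace length).
#' @export
featurize <- function(trace, fs, J = 6L, Q = 8L) {
  n <- length(trace)
  if (n < 2^J)
    stop(sprintf("length error: trace of %d samples is shorter than 2^J = %d",
                 n, 2^J), call. = FALSE)
  sdv <- stats::sd(trace)
  z <- if (sdv == 0) trace - mean(trace) else (trace - mean(trace)) / sdv
  nl <- floor(n / 2)
  ac <- vapply(0:nl, function(l) sum(z[1:(n - l)] * z[(1 + l):n]) / n,
               numeric(1))
  if (abs(ac[1L]) > 1e-12) ac <- ac / ac[1L]
  f1 <- scattering_coeffs(z, J, Q)
  f2 <- scattering_coeffs(ac, J, Q)
  names(f2) <- paste0("acf_", names(f2))
  names(f1) <- paste0("sig_", names(f1))
  c(f1, f2)
}
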