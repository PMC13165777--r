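## Trace-level artifact gating (modified z-scores and outlier ratio),
## spectral harmonic suppression with in-phase energy redistribution, and
## time-point outlier zeroing.

#' Ideal FFT-domain bandpass filter
#'
#' Zero-phase ideal bandpass: FFT bins with `low <= |f| <= high` are kept
#' with unit gain, everything else (including DC) is zeroed.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param low,high passband edges (Hz).
#' @return Filtered real vector.
#' @export
bandpass_fft <- function(x, fs, low = 0.8, high = 3.0) {
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- ifelse(f <= fs / 2, f, f - fs)
  X <- stats::fft(x)
  X[!(abs(f) >= low & abs(f) <= high)] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Modified z-scores via the median absolute deviation
#'
#' `z[i] = 0.6745 * (x[i] - median(x)) / MAD(x)` with the unscaled
#' `MAD(x) = median(|x - median(x)|)`. Samples with `|z| > threshold` are
#' flagged as outliers. A zero MAD (e.g. a constant signal) defines all
#' scores as 0 (no outliers).
#'
#' @param x numeric vector, length >= 3.
#' @param threshold outlier threshold on `|z|` (default 3).
#' @return list with `z`, `mask` (logical outliers), `n_outliers`.
#' @export
modified_zscore <- function(x, threshold = 3) {
  stopifnot(length(x) >= 3L)
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  z <- if (mad0 == 0) rep(0, length(x)) else 0.6745 * (x - med) / mad0
  mask <- abs(z) > threshold
  list(z = z, mask = mask, n_outliers = sum(mask))
}

#' Detect local-maximum peaks in a trace
#'
#' Local maxima with prominence at least `prominence_frac` of the trace's
#' standard deviation and minimum spacing `fs / max_rate_hz` samples
#' (defaults match the upper edge of the cardiac band). This is the peak
#' count entering the outlier-ratio denominator in [gate_traces].
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param prominence_frac prominence threshold as a fraction of `sd(x)`.
#' @param max_rate_hz maximum expected peak rate (Hz), default 3.
#' @return Integer vector of peak indices.
#' @export
detect_peaks <- function(x, fs, prominence_frac = 0.5, max_rate_hz = 3.0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                  x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  prom <- vapply(cand, function(i) {
    lmin <- x[i]; j <- i
    while (j > 1L && x[j] <= x[i]) { j <- j - 1L; lmin <- min(lmin, x[j]) }
    left <- if (x[j] > x[i]) lmin else min(x[seq_len(i)])
    rmin <- x[i]; j <- i
    while (j < n && x[j] <= x[i]) { j <- j + 1L; rmin <- min(rmin, x[j]) }
    right <- if (x[j] > x[i]) rmin else min(x[i:n])
    x[i] - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= prominence_frac * stats::sd(x)]
  if (length(keep) == 0L) return(integer(0))
  min_dist <- fs / max_rate_hz
  keep <- keep[order(-x[keep], keep)]
  sel <- integer(0)
  for (i in keep) if (all(abs(i - sel) >= min_dist)) sel <- c(sel, i)
  sort(sel)
}

#' Gate episode traces by outlier ratio
#'
#' For each trace, outliers are the samples with `|z_mod| > z_thresh`
#' ([modified_zscore]) and the outlier ratio is
#' `n_outliers / (n_outliers + n_peaks)` ([detect_peaks]); traces with ratio
#' strictly above `ratio_thresh` are discarded (order preserved). A ratio
#' with zero denominator is defined as 0.
#'
#' @param episode an `episode` (see [segment_episodes]).
#' @param z_thresh modified z-score threshold (default 3).
#' @param ratio_thresh discard threshold on the outlier ratio (default 0.4).
#' @return The episode with discarded traces removed; per-trace ratios in
#'   attribute `gating`.
#' @export
gate_traces <- function(episode, z_thresh = 3, ratio_thresh = 0.4) {
  stopifnot(inherits(episode, "episode"), nrow(episode$signals) >= 1L)
  M <- nrow(episode$signals)
  ratio <- numeric(M)
  for (i in seq_len(M)) {
    x <- episode$signals[i, ]
    n_out <- modified_zscore(x, threshold = z_thresh)$n_outliers
    n_pk <- length(detect_peaks(x, episode$fps))
    ratio[i] <- if (n_out + n_pk == 0L) 0 else n_out / (n_out + n_pk)
  }
  keep <- ratio <= ratio_thresh
  out <- episode
  out$signals <- episode$signals[keep, , drop = FALSE]
  if (!is.null(episode$triangle_ids))
    out$triangle_ids <- episode$triangle_ids[keep]
  attr(out, "gating") <- list(ratio = ratio, kept = keep)
  if (!any(keep))
    warning("all traces discarded by outlier gating; episode is empty")
  out
}

#' Detect the fundamental cardiac frequency of a spectrum
#'
#' Finds the in-band magnitude peak and checks whether it is a harmonic by
#' inspecting the neighbourhood of its half-frequency (within one FFT bin)
#' for significant energy (more than `half_energy_frac` of the peak
#' magnitude). If such a fundamental candidate exists in band, its bin is
#' returned; otherwise the peak itself.
#'
#' @param x numeric signal (or its complex FFT via `is_spectrum = TRUE`).
#' @param fs sampling rate (Hz).
#' @param band search band in Hz (default `c(0.8, 3)`).
#' @param half_energy_frac half-frequency significance threshold
#'   (default 0.4).
#' @param is_spectrum interpret `x` as FFT coefficients.
#' @return list with `f0` (Hz), `bin` (1-based FFT bin), `phi0` (phase of
#'   the fundamental bin), `df` (bin width, Hz), `harmonic_corrected`.
#' @export
detect_fundamental <- function(x, fs, band = c(0.8, 3.0),
                               half_energy_frac = 0.4, is_spectrum = FALSE) {
  X <- if (is_spectrum) x else stats::fft(x)
  n <- length(X)
  df <- fs / n
  freqs <- (seq_len(n) - 1L) * df
  in_band <- which(freqs >= band[1L] & freqs <= band[2L] & freqs <= fs / 2)
  if (length(in_band) == 0L)
    stop("spectral error: no FFT bins inside the search band", call. = FALSE)
  mag <- Mod(X)
  peak <- in_band[which.max(mag[in_band])]
  half_bin <- round((freqs[peak] / 2) / df) + 1L
  cand <- intersect(half_bin + (-1L:1L), in_band)
  bin <- peak
  corrected <- FALSE
  if (length(cand) > 0L && max(mag[cand]) > half_energy_frac * mag[peak]) {
    bin <- cand[which.max(mag[cand])]
    corrected <- TRUE
  }
  list(f0 = freqs[bin], bin = bin, phi0 = Arg(X[bin]), df = df,
       harmonic_corrected = corrected)
}

#' Gaussian notch response of the harmonic-suppression filter
#'
#' `H(f) = 1 - alpha * exp(-(f - 2 f0)^2 / (2 sigma^2))`; at the notch
#' centre `1 - H(2 f0)` equals the attenuation depth `alpha`.
#'
#' @param f frequency (Hz), vectorised.
#' @param f0 fundamental frequency (Hz).
#' @param sigma notch bandwidth (Hz), default 0.1.
#' @param alpha attenuation depth, default 0.7.
#' @return `H(f)`.
#' @export
harmonic_notch_response <- function(f, f0, sigma = 0.1, alpha = 0.7) {
  1 - alpha * exp(-(f - 2 * f0)^2 / (2 * sigma^2))
}

#' Suppress the first harmonic and redistribute its energy
#'
#' Applies the Gaussian notch [harmonic_notch_response] at `2 f0` (mirrored
#' onto negative frequencies so the output stays real). The total magnitude
#' removed from the positive-frequency bins is added back to the fundamental
#' bin in phase with it (`X(f0) <- X(f0) + dE * exp(i phi0)`), so the sum of
#' spectral magnitudes is conserved to machine precision.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param sigma,alpha notch bandwidth (Hz) and attenuation depth.
#' @param f0 fundamental frequency (Hz); detected with
#'   [detect_fundamental] when `NULL`.
#' @param band detection band for `f0`.
#' @return Filtered real signal; attributes `f0` and `delta_e` record the
#'   fundamental and the redistributed magnitude.
#' @export
harmonic_suppress <- function(x, fs, sigma = 0.1, alpha = 0.7, f0 = NULL,
                              band = c(0.8, 3.0)) {
  n <- length(x)
  X <- stats::fft(x)
  det <- detect_fundamental(X, fs, band = band, is_spectrum = TRUE)
  if (is.null(f0)) f0 <- det$f0
  if (2 * f0 > fs / 2) {
    message(sprintf("harmonic 2 f0 = %.2f Hz above Nyquist; suppression skipped",
                    2 * f0))
    out <- x
    attr(out, "f0") <- f0; attr(out, "delta_e") <- 0
    return(out)
  }
  freqs <- (seq_len(n) - 1L) / n * fs
  fsym <- ifelse(freqs <= fs / 2, freqs, fs - freqs)   # |f| for real signals
  H <- harmonic_notch_response(fsym, f0, sigma = sigma, alpha = alpha)
  Xn <- X * H
  pos <- which(freqs > 0 & freqs <= fs / 2)
  delta_e <- sum(Mod(X[pos]) - Mod(Xn[pos]))
  k0 <- det$bin
  phi0 <- Arg(Xn[k0])
  Xn[k0] <- Xn[k0] + delta_e * exp(1i * phi0)
  conj_bin <- n - k0 + 2L
  if (conj_bin != k0 && conj_bin <= n) Xn[conj_bin] <- Conj(Xn[k0])
  out <- Re(stats::fft(Xn, inverse = TRUE)) / n
  attr(out, "f0") <- f0
  attr(out, "delta_e") <- delta_e
  out
}

#' Zero time-point outliers and re-filter
#'
#' Samples departing from the mean by more than `tau` standard deviations
#' are replaced with zeros; the signal is then bandpass filtered again
#' (0.8-3 Hz by default) to remove the discontinuities this introduces.
#'
#' @param x numeric vector, length >= 3.
#' @param fs sampling rate (Hz); needed when `refilter = TRUE`.
#' @param tau outlier threshold in standard deviations (default 4).
#' @param band re-filtering passband (Hz).
#' @param refilter apply the bandpass after zeroing (default `TRUE`).
#' @return Cleaned signal; attribute `mask` flags the zeroed samples.
#' @export
zero_timepoint_outliers <- function(x, fs = NULL, tau = 4,
                                    band = c(0.8, 3.0), refilter = TRUE) {
  stopifnot(length(x) >= 3L)
  mu <- mean(x); sdev <- stats::sd(x)
  mask <- if (sdev == 0) rep(FALSE, length(x)) else abs(x - mu) > tau * sdev
  x[mask] <- 0
  if (refilter) {
    stopifnot(!is.null(fs))
    x <- bandpass_fft(x, fs, band[1L], band[2L])
  }
  attr(x, "mask") <- mask
  x
}
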