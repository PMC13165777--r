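## Final reconstruction and heart-rate estimation: back-project selected
## SOBI components to the original trace space, phase-align and average,
## link consecutive episodes over their shared 15 s, and read the heart rate
## off the spectral peak.

#' Back-project selected components to an earlier signal space
#'
#' Propagates the selected SOBI components (all others zeroed) back through
#' the SOBI mixing operator, the global-PCA loadings and, for
#' `to = "traces"`, the per-window PCA loadings (overlapping windows
#' averaged per trace), undoing the z-scorings applied at each stage.
#'
#' @param selection a `selection_result` with at least one selected
#'   component.
#' @param sobi_set the `sobi` component set (must carry its `parent`
#'   `global_pca` stage; the global stage in turn carries the `window_pca`
#'   stage when trace-space reconstruction is requested).
#' @param to `"presobi"` (the global-PCA input components) or `"traces"`
#'   (original per-triangle trace space).
#' @return Reconstructed signal matrix (rows = components or traces).
#' @export
back_project <- function(selection, sobi_set, to = c("traces", "presobi")) {
  to <- match.arg(to)
  if (inherits(selection, "selection_result")) {
    if (length(selection$indices) == 0L)
      stop("pipeline-state error: no components selected (null selection)",
           call. = FALSE)
    idx <- selection$indices
  } else idx <- as.integer(selection)
  stopifnot(identical(sobi_set$stage, "sobi"))
  S <- sobi_set$components
  keep <- matrix(0, nrow(S), ncol(S))
  keep[idx, ] <- S[idx, , drop = FALSE]
  G_hat <- sobi_set$mixing %*% keep + sobi_set$row_means

  gp <- sobi_set$parent
  if (is.null(gp))
    stop("pipeline-state error: missing global-PCA operator for back-projection",
         call. = FALSE)
  stopifnot(identical(gp$stage, "global_pca"))
  Z_hat <- gp$loadings %*% G_hat
  pre_sobi <- Z_hat * gp$in_scale + gp$in_center
  if (to == "presobi") return(pre_sobi)

  wp <- gp$parent
  if (is.null(wp) || !identical(wp$stage, "window_pca"))
    stop("pipeline-state error: missing window-PCA operator for trace-space back-projection",
         call. = FALSE)
  T_ <- ncol(pre_sobi)
  acc <- matrix(0, wp$M, T_)
  cnt <- numeric(wp$M)
  for (i in seq_len(nrow(pre_sobi))) {
    w <- wp$windows[[wp$meta[i, "window"]]]
    pc <- wp$meta[i, "pc"]
    contrib <- w$loadings[, pc] %o% pre_sobi[i, ]
    acc[w$trace_idx, ] <- acc[w$trace_idx, ] + contrib
    cnt[w$trace_idx] <- cnt[w$trace_idx] + 1
  }
  used <- cnt > 0
  acc[used, ] <- acc[used, ] / cnt[used]
  traces <- acc * wp$trace_scale + wp$trace_center
  traces[used, , drop = FALSE]
}

## circular shift by integer lag (positive lag delays the signal)
.circshift <- function(x, lag) {
  n <- length(x)
  lag <- ((lag %% n) + n) %% n
  if (lag == 0) x else c(x[(n - lag + 1L):n], x[1:(n - lag)])
}

#' Phase-align traces and average them
#'
#' Each trace is band-passed to the cardiac band, lag-aligned to the first
#' trace by maximizing cross-correlation over lags up to +/- `max_lag_s`
#' seconds, sign-corrected to positive correlation, and averaged; this
#' prevents inter-region pulse-transit delays from attenuating the averaged
#' oscillation.
#'
#' @param traces matrix (rows = traces) or vector.
#' @param fs sampling rate (Hz).
#' @param band cardiac band (Hz).
#' @param max_lag_s alignment search range in seconds (default 1).
#' @return The representative (averaged) trace.
#' @export
align_and_average <- function(traces, fs, band = c(0.8, 3.0), max_lag_s = 1) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1L)
  stopifnot(nrow(traces) >= 1L)
  B <- t(apply(traces, 1L, bandpass_fft, fs = fs, low = band[1L],
               high = band[2L]))
  if (nrow(traces) == 1L) return(as.numeric(B[1L, ]))
  ref <- B[1L, ]
  lags <- seq(-round(max_lag_s * fs), round(max_lag_s * fs))
  out <- B
  for (i in 2:nrow(B)) {
    cc <- vapply(lags, function(l)
      suppressWarnings(stats::cor(ref, .circshift(B[i, ], l))), numeric(1))
    cc[!is.finite(cc)] <- 0
    best <- which.max(abs(cc))
    shifted <- .circshift(B[i, ], lags[best])
    if (cc[best] < 0) shifted <- -shifted
    out[i, ] <- shifted
  }
  colMeans(out)
}

#' Link consecutive episodes over their shared 15 s
#'
#' Compares the final `link_s` seconds of the current episode's
#' representative trace with the same span of the previous episode's. When
#' both are valid the two tails are stacked, z-scored and reduced by PCA;
#' the first principal component (sign set by positive correlation with the
#' current tail) is the representative trace for rate estimation. If one is
#' null the other's tail is used directly; if both are null the result is
#' null.
#'
#' @param current,previous representative episode traces (numeric vectors
#'   or `NULL`).
#' @param fs sampling rate (Hz).
#' @param link_s linked-tail length in seconds (default 15).
#' @return The representative `link_s`-second trace, or `NULL`.
#' @export
link_segments <- function(current, previous, fs, link_s = 15) {
  n_tail <- round(link_s * fs)
  tail_of <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(x) < n_tail) return(NULL)
    x[(length(x) - n_tail + 1L):length(x)]
  }
  ct <- tail_of(current); pt <- tail_of(previous)
  if (is.null(ct) && is.null(pt)) return(NULL)
  if (is.null(pt)) return(ct)
  if (is.null(ct)) return(pt)
  Z <- rbind(ct, pt)
  ctr <- rowMeans(Z); sdv <- apply(Z, 1L, stats::sd)
  if (any(sdv == 0)) return(ct)
  Z <- (Z - ctr) / sdv
  p <- .row_pca(Z, 1L)
  pc1 <- as.numeric(p$components[1L, ])
  r <- suppressWarnings(stats::cor(pc1, ct))
  if (is.finite(r) && r < 0) pc1 <- -pc1
  pc1
}

#' Estimate heart rate from a representative trace
#'
#' Zero-pads the trace, takes the FFT, restricts to the cardiac band and
#' multiplies the peak frequency by 60. An all-zero (or null) trace yields a
#' null estimate.
#'
#' @param trace numeric vector (typically 15 s), or `NULL`.
#' @param fs sampling rate (Hz).
#' @param band cardiac band (Hz); the estimate is confined to
#'   `60 * band` bpm.
#' @param pad FFT length after zero-padding (default 8192, ~0.15 bpm grid
#'   at 20 Hz; `NULL` disables padding).
#' @return An `hr_estimate`: `hr_bpm` (or `NA`), `peak_hz`, `n`.
#' @export
estimate_hr <- function(trace, fs, band = c(0.8, 3.0), pad = 8192L) {
  null_est <- structure(list(hr_bpm = NA_real_, peak_hz = NA_real_,
                             n = length(trace)), class = "hr_estimate")
  if (is.null(trace) || length(trace) == 0L) return(null_est)
  x <- trace - mean(trace)
  if (all(abs(x) < 1e-12)) return(null_est)
  n <- length(x)
  nfft <- if (is.null(pad)) n else max(n, as.integer(pad))
  X <- stats::fft(c(x, numeric(nfft - n)))
  f <- (seq_len(nfft) - 1L) / nfft * fs
  sel <- which(f >= band[1L] & f <= band[2L] & f <= fs / 2)
  peak <- sel[which.max(Mod(X)[sel])]
  structure(list(hr_bpm = 60 * f[peak], peak_hz = f[peak], n = n),
            class = "hr_estimate")
}

#' @export
print.hr_estimate <- function(x, ...) {
  if (is.na(x$hr_bpm)) cat("hr_estimate: null\n")
  else cat(sprintf("hr_estimate: %.1f bpm (peak %.3f Hz)\n", x$hr_bpm,
                   x$peak_hz))
  invisible(x)
}
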