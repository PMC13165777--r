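test_that("modified z-scores follow the MAD formula with its degenerate rule", {
  ## x = 1..5: median 3, MAD 1, score at x = 4 is exactly the 0.6745 constant
  z <- modified_zscore(c(1, 2, 3, 4, 5))
  expect_equal(z$z[4], 0.6745)
  expect_equal(z$z, 0.6745 * (c(1:5) - 3) / 1)
  expect_equal(z$n_outliers, 0)

  ## constant signal: MAD 0 -> all scores 0, no outliers
  zc <- modified_zscore(rep(2.5, 10))
  expect_equal(zc$z, rep(0, 10))
  expect_equal(zc$n_outliers, 0)

  ## a gross spike is flagged and the mask equals brute-force re-evaluation
  set.seed(9)
  x <- rnorm(200); x[77] <- 50
  zs <- modified_zscore(x)
  expect_true(zs$mask[77])
  med <- median(x); mad0 <- median(abs(x - med))
  expect_identical(zs$mask, abs(0.6745 * (x - med) / mad0) > 3)
})

test_that("trace gating discards on outlier ratio with a strict threshold", {
  fs <- 20; t <- (0:(20 * fs - 1)) / fs
  mk_ep <- function(traces) structure(
    list(signals = traces, fps = fs, start_time = 0, duration = 20,
         triangle_ids = seq_len(nrow(traces)), truncated = FALSE),
    class = "episode")

  ## clean sinusoid: no outliers, many peaks, ratio 0 -> kept
  clean <- sin(2 * pi * 1.2 * t)
  g1 <- gate_traces(mk_ep(rbind(clean)))
  expect_equal(nrow(g1$signals), 1)
  expect_equal(attr(g1, "gating")$ratio, 0)

  ## constructed trace with verified counts: 3 outliers, 2 peaks -> 0.6 > 0.4
  x <- sin(2 * pi * 0.1 * t)           # two slow cycles -> 2 detected peaks
  x[c(100, 200, 300)] <- -30           # downward spikes: outliers, not peaks
  expect_equal(modified_zscore(x)$n_outliers, 3)
  expect_equal(length(detect_peaks(x, fs)), 2)
  g2 <- gate_traces(mk_ep(rbind(x, clean)))
  expect_equal(nrow(g2$signals), 1)
  expect_equal(attr(g2, "gating")$ratio[1], 0.6)

  ## exactly 0.4 is kept (strict inequality); order of survivors preserved
  y <- -cos(2 * pi * 0.15 * t)         # three interior maxima -> 3 peaks
  y[c(120, 260)] <- -30                # 2 outliers
  expect_equal(modified_zscore(y)$n_outliers, 2)
  expect_equal(length(detect_peaks(y, fs)), 3)
  g3 <- gate_traces(mk_ep(rbind(y, clean, x)))
  expect_equal(attr(g3, "gating")$ratio[1], 0.4)
  expect_equal(attr(g3, "gating")$kept, c(TRUE, TRUE, FALSE))
  expect_equal(g3$signals[1, ], y)

  ## gating is idempotent
  g4 <- gate_traces(g3)
  expect_equal(g4$signals, g3$signals)

  ## everything discarded: empty episode with a warning
  expect_warning(g5 <- gate_traces(mk_ep(rbind(x))), "all traces")
  expect_equal(nrow(g5$signals), 0)
})

test_that("fundamental detection resolves harmonics by the 40% half-frequency rule", {
  fs <- 20; n <- 600; t <- (0:(n - 1)) / fs
  ## pure in-band tone: the peak is the fundamental
  d1 <- detect_fundamental(sin(2 * pi * 1.2 * t), fs)
  expect_equal(d1$f0, 1.2, tolerance = 1e-9)
  expect_false(d1$harmonic_corrected)

  ## strong 2.4 Hz with half-frequency energy above 40%: f0 = 1.2
  d2 <- detect_fundamental(sin(2 * pi * 2.4 * t) + 0.5 * sin(2 * pi * 1.2 * t),
                           fs)
  expect_equal(d2$f0, 1.2, tolerance = 1e-9)
  expect_true(d2$harmonic_corrected)

  ## half-frequency energy below 40%: the peak stands
  d3 <- detect_fundamental(sin(2 * pi * 2.4 * t) + 0.3 * sin(2 * pi * 1.2 * t),
                           fs)
  expect_equal(d3$f0, 2.4, tolerance = 1e-9)

  ## empty search band (above Nyquist)
  expect_error(detect_fundamental(sin(t), fs, band = c(10.5, 12)), "spectral")
})

test_that("harmonic suppression notches 2f0 and conserves spectral magnitude", {
  ## the notch centre attenuation equals the configured depth
  expect_equal(1 - harmonic_notch_response(2.4, 1.2), 0.7)
  expect_equal(1 - harmonic_notch_response(2.4 + 0.1, 1.2),
               0.7 * exp(-0.5))

  fs <- 20; n <- 600; t <- (0:(n - 1)) / fs
  ## no energy near 2f0: output equals input
  x1 <- sin(2 * pi * 1.0 * t)
  expect_equal(as.numeric(harmonic_suppress(x1, fs)), x1, tolerance = 1e-12)

  ## two equal tones: post/pre magnitude at 2f0 is 0.3 and sum conserved
  x2 <- sin(2 * pi * 1.2 * t) + sin(2 * pi * 2.4 * t)
  y2 <- harmonic_suppress(x2, fs)
  X <- Mod(fft(x2)); Y <- Mod(fft(as.numeric(y2)))
  k2 <- which(abs((0:(n - 1)) / n * fs - 2.4) < 1e-9)
  expect_equal(Y[k2] / X[k2], 0.3, tolerance = 1e-9)
  expect_lt(abs(sum(Y) - sum(X)), 1e-9)
  ## the output is real and its argmax lands on the fundamental
  expect_true(is.numeric(y2))
  f <- (0:(n - 1)) / n * fs
  sel <- which(f >= 0.8 & f <= 3)
  expect_equal(f[sel[which.max(Y[sel])]], 1.2, tolerance = 1e-9)

  ## 2 f0 above Nyquist: a no-op with a notice
  t10 <- (0:599) / 10
  slow <- sin(2 * pi * 2.9 * t10)
  expect_message(y3 <- harmonic_suppress(slow, 10), "Nyquist")
  expect_equal(as.numeric(y3), slow)
})

test_that("time-point outlier zeroing matches the tau-sigma rule", {
  set.seed(10)
  x <- rnorm(300); x <- (x - mean(x)) / sd(x)
  x[123] <- 10
  y <- zero_timepoint_outliers(x, fs = 20, refilter = FALSE)
  expect_true(attr(y, "mask")[123])
  expect_equal(as.numeric(y)[123], 0)

  ## all samples within 4 sigma: unchanged before re-filtering
  z <- sin((1:100) / 5)
  expect_equal(as.numeric(zero_timepoint_outliers(z, refilter = FALSE)), z)

  ## mask equals brute-force evaluation on random signals
  for (s in 1:10) {
    set.seed(s)
    w <- rnorm(200) * runif(1, 0.5, 3) + rnorm(1)
    w[sample(200, 3)] <- w[sample(200, 3)] + 30
    m <- attr(zero_timepoint_outliers(w, refilter = FALSE), "mask")
    expect_identical(m, abs(w - mean(w)) > 4 * sd(w))
  }
})
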