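test_that("pyramid band preserves constants and matches an explicit blur oracle", {
  ## constant frame: level-3 luma stays at the constant's luma
  v <- flat_video(2, 32, 32, c(0.4, 0.4, 0.4))
  pb <- build_pyramid_band(v, 3)
  expect_equal(dim(pb$frames[[1]]), c(4, 4, 3))
  expect_equal(as.vector(pb$frames[[1]][, , 1]), rep(0.4, 16),
               tolerance = 1e-12)

  ## impulse response equals explicit convolution + decimation (1 level)
  img <- array(0, c(16, 16, 3)); img[8, 8, ] <- 1
  v1 <- frame_sequence(list(img, img), 20)
  pb1 <- build_pyramid_band(v1, 1)
  k <- c(1, 4, 6, 4, 1) / 16
  ref <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    di <- pmin(pmax(i + (-2:2), 1), 16); dj <- pmin(pmax(j + (-2:2), 1), 16)
    ref[i, j] <- sum(outer(k, k) * outer(di == 8, dj == 8))
  }
  dec <- ref[seq(1, 16, 2), seq(1, 16, 2)]
  expect_equal(pb1$frames[[1]][, , 1], dec * rgb_to_yiq(img)[8, 8, 1],
               tolerance = 1e-12)

  ## frames smaller than 2^level are rejected
  tiny <- flat_video(2, 4, 4, c(0.5, 0.5, 0.5))
  expect_error(build_pyramid_band(tiny, 3), "size error")
})

test_that("ideal temporal bandpass has unit passband gain and hard stopbands", {
  fps <- 20; n <- 200                     # 10 s: 1.5 Hz is bin-aligned
  t <- (0:(n - 1)) / fps
  mk_band <- function(ts) {
    frames <- lapply(ts, function(v) array(v, c(4, 4, 3)))
    structure(list(frames = frames, level = 3L, fps = fps, height = 4,
                   width = 4), class = "pyramid_band")
  }
  val <- function(fb) vapply(fb$frames, function(f) f[2, 2, 1], numeric(1))

  ## DC only -> zero
  expect_lt(max(abs(val(temporal_bandpass(mk_band(rep(0.7, n)))))), 1e-12)
  ## 1.5 Hz (bin-aligned), amplitude 0.3 -> amplitude preserved
  out <- val(temporal_bandpass(mk_band(0.3 * sin(2 * pi * 1.5 * t))))
  expect_equal(out, 0.3 * sin(2 * pi * 1.5 * t), tolerance = 1e-10)
  ## 5 Hz -> rejected
  out5 <- val(temporal_bandpass(mk_band(0.3 * sin(2 * pi * 5 * t))))
  expect_lt(max(abs(out5)), 1e-10)
  ## masked-out pixels are zero
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE
  fb <- temporal_bandpass(mk_band(0.3 * sin(2 * pi * 1.5 * t)), roi_mask = m)
  expect_equal(fb$frames[[10]][1, 1, 1], 0)
  expect_false(fb$frames[[10]][2, 2, 1] == 0)
  ## aliasing guard
  slow <- mk_band(rep(0, n)); slow$fps <- 5
  expect_error(temporal_bandpass(slow), "aliasing")
})

test_that("amplification is additive and linear in the band", {
  v <- flat_video(40, 16, 16, c(0.5, 0.4, 0.3))
  pb <- build_pyramid_band(v, 3)
  zero <- pb; zero$frames <- lapply(zero$frames, function(f) f * 0)
  ## zero band: magnified equals original exactly
  m0 <- amplify_and_reconstruct(v, zero, alpha = 50)
  expect_equal(m0$frames[[5]], v$frames[[5]], tolerance = 1e-12)
  ## alpha = 0: identity
  fb <- pb; fb$frames <- lapply(fb$frames, function(f) f * 0 + 0.001)
  ma <- amplify_and_reconstruct(v, fb, alpha = 0)
  expect_equal(ma$frames[[5]], v$frames[[5]], tolerance = 1e-12)
  ## doubling the band doubles the delta (linearity below saturation)
  m1 <- amplify_and_reconstruct(v, fb, alpha = 50)
  fb2 <- fb; fb2$frames <- lapply(fb2$frames, function(f) 2 * f)
  m2 <- amplify_and_reconstruct(v, fb2, alpha = 50)
  d1 <- m1$frames[[1]] - v$frames[[1]]
  d2 <- m2$frames[[1]] - v$frames[[1]]
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
})

test_that("saturation clamp applies the channel-wise bound and stays in range", {
  ## no delta: output equals the original (8-bit quantized)
  o <- array(runif(12 * 12 * 3), c(12, 12, 3))
  expect_equal(saturation_clamp(o, o), round(255 * o) / 255, tolerance = 1e-12)

  ## worked bound: I=(0.9,0.5,0.5), dI=(+0.2,+0.1,0) -> k=0.5, R hits 1.0
  o1 <- array(rep(c(0.9, 0.5, 0.5), each = 1), c(1, 1, 3))
  m1 <- array(rep(c(1.1, 0.6, 0.5), each = 1), c(1, 1, 3))
  out <- saturation_clamp(o1, m1)
  expect_equal(out[1, 1, 1], 1.0)
  expect_equal(out[1, 1, 2], round(255 * 0.55) / 255)
  expect_equal(out[1, 1, 3], round(255 * 0.5) / 255)

  ## sweep: output never leaves [0,1]; k = 1 where nothing would saturate
  set.seed(8)
  o2 <- array(runif(1e5 * 3), c(100, 1000, 3))
  m2 <- o2 + array(rnorm(3e5, 0, 0.5), c(100, 1000, 3))
  s <- saturation_clamp(o2, m2)
  expect_true(all(s >= 0 & s <= 1))
  ## where the magnified value itself stays in range, k = 1 and the
  ## amplification is fully retained
  msafe <- pmin(pmax(o2 + (m2 - o2) * 0.001, 0), 1)
  ssafe <- saturation_clamp(o2, msafe)
  expect_equal(ssafe, round(255 * msafe) / 255, tolerance = 1e-12)
})

test_that("trace extraction and episode segmentation follow the 30/15 grid", {
  ## constant green: trace equals the constant (on the 8-bit scale)
  pts <- rbind(c(1, 1), c(6, 1), c(1, 6))
  tris <- tessellate(pts, matrix(1:3, 1))
  tris$region <- "forehead"
  v <- flat_video(10, 10, 10, c(0.2, 0.6, 0.3))
  tr <- extract_traces(v, tris)
  expect_equal(as.vector(tr), rep(0.6 * 255, 10))

  ## 60 s at 2 Hz: episodes start at 0, 15 and 30 s
  traces <- matrix(rnorm(2 * 120), 2)
  eps <- segment_episodes(traces, fps = 2)
  expect_length(eps, 3)
  expect_equal(vapply(eps, `[[`, numeric(1), "start_time"), c(0, 15, 30))
  expect_true(all(vapply(eps, function(e) ncol(e$signals), 1) == 60))
  ## a short video yields one truncated, flagged episode
  expect_warning(short <- segment_episodes(traces[, 1:20], fps = 2),
                 "truncated")
  expect_true(short[[1]]$truncated)
})

test_that("magnified video keeps non-ROI pixels at the quantized original", {
  sc <- clean_scene()
  v <- frame_sequence(sc$video$frames[1:60], sc$video$fps)
  can <- as_canonical(sc$truth$canonical_landmarks)
  rois <- filter_anatomical(tessellate(can))
  mask <- hrvideo:::roi_mask_from_triangles(rois, v$height, v$width)
  mag <- magnify_video(v, roi_mask_full = mask)
  out <- !mask
  for (t in c(1, 30)) {
    for (c in 1:3)
      expect_identical(mag$frames[[t]][, , c][out],
                       (round(255 * v$frames[[t]][, , c]) / 255)[out])
  }
})

test_that("magnified traces peak at the injected cardiac frequency", {
  sc <- clean_scene()
  v <- sc$video
  can <- as_canonical(sc$truth$canonical_landmarks)
  rois <- order_triangles(filter_anatomical(tessellate(can)))
  mask <- hrvideo:::roi_mask_from_triangles(rois, v$height, v$width)
  mag <- magnify_video(v, roi_mask_full = mask)
  tr <- extract_traces(mag, rois)
  fps <- v$fps; n <- ncol(tr)
  f <- (0:(n - 1)) / n * fps
  sel <- which(f >= 0.8 & f <= 3)
  f0 <- sc$truth$f0_hz
  peak_ok <- apply(tr, 1, function(x) {
    pk <- f[sel[which.max(Mod(stats::fft(x - mean(x)))[sel])]]
    abs(pk - f0) <= fps / n + 1e-9
  })
  expect_gte(mean(peak_ok), 0.97)
})
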