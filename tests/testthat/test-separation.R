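test_that("window planning follows the adaptive width rule and covers all traces", {
  ## M = 9: width 5, windows at trace starts 1, 4 and the end-clamped 5
  p9 <- plan_windows(9)
  expect_equal(p9$width, 5L)
  expect_equal(p9$starts, c(1L, 4L, 5L))

  ## M = 30: width min(max(10, 5), 30) = 10
  expect_equal(plan_windows(30)$width, 10L)

  ## M = 4: clamped to a single full window
  p4 <- plan_windows(4)
  expect_equal(p4$width, 4L)
  expect_equal(p4$starts, 1L)

  ## properties: width within [min(5, M), M]; full coverage; increasing
  ## deduplicated starts
  for (M in c(1:8, 13, 21, 50, 101)) {
    p <- plan_windows(M)
    expect_gte(p$width, min(5L, M))
    expect_lte(p$width, M)
    covered <- sort(unique(unlist(lapply(p$starts, function(s)
      s:(s + p$width - 1)))))
    expect_equal(covered, 1:M)
    expect_false(any(duplicated(p$starts)))
    expect_true(all(diff(p$starts) > 0))
  }
})

test_that("window PCA recovers coherent modes with orthonormal loadings", {
  fs <- 20; t <- (0:(599)) / fs
  s1 <- sin(2 * pi * 1.1 * t)
  ## identical sinusoids: PC1 explains ~everything and matches the sinusoid
  X <- matrix(rep(s1, 6), 6, byrow = TRUE) * runif(6, 0.5, 2)
  w <- window_pca(X)
  expect_gt(w$evar[1], 0.999)
  expect_gt(abs(cor(w$components[1, ], s1)), 0.9999)

  ## two orthogonal sinusoids, duplicated: both recovered up to sign/order
  s2 <- cos(2 * pi * 1.7 * t)
  X2 <- rbind(s1, s1, s2, s2, s1)
  w2 <- window_pca(X2)
  C <- abs(cor(t(w2$components[1:2, ]), cbind(s1, s2)))
  expect_true(all(apply(C, 2, max) > 0.999))
  ## eigen-decomposition oracle on the z-scored window
  Z <- t(scale(t(X2)))
  ev <- eigen(Z %*% t(Z) / ncol(Z), symmetric = TRUE)
  expect_equal(sort(w2$evar[1:2], decreasing = TRUE),
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-8)

  ## loadings are orthonormal
  for (win in w2$windows) {
    G <- t(win$loadings) %*% win$loadings
    expect_equal(G, diag(ncol(win$loadings)), tolerance = 1e-8)
  }

  ## coherent pulse in noise: PC1 beats the average single trace
  set.seed(12)
  noise <- matrix(rnorm(10 * 600), 10)
  Xn <- matrix(rep(s1, 10), 10, byrow = TRUE) + noise     # 0 dB per trace
  wn <- window_pca(Xn)
  pc1 <- wn$components[1, ]
  r_pc <- abs(cor(pc1, s1))
  r_traces <- mean(abs(apply(Xn, 1, cor, y = s1)))
  expect_gt(r_pc, r_traces)

  ## zero-variance traces are excluded with a notice
  Xz <- rbind(s1, rep(1, 600), s1 * 2, s2, s2)
  expect_message(wz <- window_pca(Xz), "zero-variance")
})

test_that("correlation selection keeps the coherent cluster with a strict 0.5 cut", {
  fs <- 20; t <- (0:599) / fs
  pulse <- sin(2 * pi * 1.2 * t)
  ## all identical: everything retained
  same <- matrix(rep(pulse, 4), 4, byrow = TRUE)
  expect_equal(nrow(correlation_select(same)), 4)

  ## three pulse copies and one independent noise: noise dropped
  set.seed(13)
  X <- rbind(pulse, pulse + 0.05 * rnorm(600), -pulse, rnorm(600))
  sel <- correlation_select(X)
  expect_equal(nrow(sel), 3)
  expect_true(all(abs(cor(t(sel), pulse))[, 1] > 0.99))

  ## the 0.5 cut is strict: r just below is discarded, just above retained
  x <- rep(c(1, -1), 200)
  z <- rep(c(1, 1, -1, -1), 100)         # orthogonal to x
  mix_at <- function(r) r * x + sqrt(1 - r^2) * z
  below <- correlation_select(rbind(x, x, mix_at(0.5 - 1e-6)))
  above <- correlation_select(rbind(x, x, mix_at(0.5 + 1e-6)))
  expect_equal(nrow(below), 2)
  expect_equal(nrow(above), 3)

  ## single component returned unchanged
  one <- matrix(pulse, 1)
  expect_identical(correlation_select(one), one)
})

test_that("global PCA caps components and reconstructs low-rank inputs", {
  fs <- 20; t <- (0:599) / fs
  base <- rbind(sin(2 * pi * 1.1 * t), cos(2 * pi * 1.6 * t),
                sin(2 * pi * 2.2 * t))
  ## 4 inputs -> 4 PCs (no padding)
  X4 <- rbind(base, base[1, ] + base[2, ])
  expect_equal(nrow(global_pca(X4)$components), 4)

  ## 25 inputs -> exactly 10
  set.seed(14)
  X25 <- matrix(rnorm(25 * 600), 25)
  expect_equal(nrow(global_pca(X25)$components), 10)

  ## rank-3 input: reconstruction from all PCs is exact
  M <- matrix(rnorm(12 * 3), 12) %*% base
  gp <- global_pca(M)
  Z <- (M - rowMeans(M)) / apply(M, 1, sd)
  Zhat <- gp$loadings %*% gp$components
  expect_lt(max(abs(Z - Zhat)), 1e-8)
})

test_that("SOBI separates temporally structured sources with exact operator inverses", {
  fs <- 20; t <- (0:599) / fs
  S <- rbind(sin(2 * pi * 1.0 * t), sin(2 * pi * 1.7 * t))
  A <- matrix(c(0.8, 0.6, -0.6, 0.8), 2)
  so <- sobi(A %*% S, lags = 1:20)
  C <- abs(cor(t(so$sources), t(S)))
  expect_true(all(apply(C, 2, max) > 0.99))
  expect_lt(max(abs(so$unmixing %*% so$mixing - diag(2))), 1e-6)
  ## joint-diagonalization criterion never increases across sweeps
  expect_true(all(diff(so$off_criterion) <= 1e-10))
  ## unit-variance sources
  expect_equal(apply(so$sources, 1, function(x) mean((x - mean(x))^2)),
               c(1, 1), tolerance = 1e-8)

  ## already-uncorrelated input: unmixing is a signed permutation of identity
  so2 <- sobi(S, lags = 1:20)
  P <- so2$unmixing %*% diag(apply(S, 1, sd))
  P[abs(P) < 1e-3] <- 0
  expect_true(all(colSums(P != 0) == 1) && all(rowSums(P != 0) == 1))

  ## mixture recovery at moderate noise
  mix <- make_mixture(10, snr_db = 0, seed = 15)
  gp <- global_pca(mix$X)
  so3 <- sobi(gp, lags = 1:20)
  expect_gt(max(abs(cor(t(so3$sources), mix$pulse))), 0.95)
})

test_that("component cleanup removes harmonics and spikes without hurting clean tones", {
  fs <- 20; t <- (0:599) / fs
  clean <- sin(2 * pi * 1.3 * t)
  out <- cleanup_components(rbind(clean), fs)
  expect_gt(abs(cor(out[1, ], clean)), 0.999)

  ## strong first harmonic: post-cleanup argmax sits at f0
  x <- 0.8 * sin(2 * pi * 1.2 * t) + 1.0 * sin(2 * pi * 2.4 * t)
  y <- cleanup_components(rbind(x), fs)[1, ]
  f <- (0:599) / 600 * fs
  sel <- which(f >= 0.8 & f <= 3)
  expect_equal(f[sel[which.max(Mod(fft(y))[sel])]], 1.2, tolerance = 1e-9)

  ## a 6-sigma spike is zeroed and re-filtering leaves no energy above 3 Hz
  z <- sin(2 * pi * 1.0 * t); z[300] <- 6 * sd(z) + 10
  w <- cleanup_components(rbind(z), fs)[1, ]
  hi <- which(f > 3.05 & f < fs - 3.05)
  expect_lt(max(Mod(fft(w))[hi]) / max(Mod(fft(w))), 1e-9)
})
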