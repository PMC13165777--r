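test_that("4-DOF decompose/reconstruct is an exact round trip", {
  set.seed(3)
  for (i in 1:20) {
    p <- affine_params(tx = rnorm(1, 0, 10), ty = rnorm(1, 0, 10),
                       theta = runif(1, -pi, pi), s = runif(1, 0.5, 2))
    q <- decompose_affine(affine_matrix(p))
    expect_equal(q[c("tx", "ty", "theta", "s")], p[c("tx", "ty", "theta", "s")],
                 tolerance = 1e-12)
    ## inverse composes to the identity
    m <- affine_matrix(p); mi <- affine_matrix(invert_affine(p))
    expect_equal(mi[, 1:2] %*% m[, 1:2], diag(2), tolerance = 1e-12)
    expect_equal(as.vector(mi[, 1:2] %*% m[, 3] + mi[, 3]), c(0, 0),
                 tolerance = 1e-10)
  }
})

test_that("similarity estimation recovers known transforms", {
  Q <- face_mesh_template()$points * 100
  ## identity
  p0 <- estimate_similarity(Q, Q)
  expect_equal(c(p0$tx, p0$ty, p0$theta, p0$s), c(0, 0, 0, 1),
               tolerance = 1e-10, ignore_attr = TRUE)

  ## rotation of the landmarks by +0.1 rad about the centroid must be
  ## undone by theta = -0.1
  ctr <- colMeans(Q)
  R <- matrix(c(cos(0.1), -sin(0.1), sin(0.1), cos(0.1)), 2, byrow = TRUE)
  P <- sweep(sweep(Q, 2, ctr) %*% t(R), 2, ctr, `+`)
  pr <- estimate_similarity(P, Q)
  expect_equal(pr$theta, -0.1, tolerance = 1e-9)
  expect_equal(pr$s, 1, tolerance = 1e-9)
  expect_lt(pr$residual, 1e-9)

  ## scale x1.2 and shift (5, -3): the inverse map is recovered exactly
  P2 <- sweep(Q * 1.2, 2, c(5, -3), `+`)
  pe <- estimate_similarity(P2, Q)
  expect_equal(pe$s, 1 / 1.2, tolerance = 1e-9)
  expect_equal(transform_points(P2, pe), Q, tolerance = 1e-8,
               ignore_attr = TRUE)

  ## degenerate cloud
  expect_error(estimate_similarity(matrix(1, 478, 2), Q), "degenerate")
})

test_that("adaptive EMA smoothing follows the update rule and ramps on large rotations", {
  ## constant stream: fixed point
  const <- rep(list(affine_params(tx = 2, ty = -1, theta = 0.01, s = 1.1)), 10)
  sm <- smooth_params(const)
  expect_equal(sm$params[[10]]$tx, 2)
  expect_equal(sm$params[[10]]$s, 1.1)

  ## single EMA step at the slow factor: 0 -> 1 gives 0.05
  step_tx <- list(affine_params(tx = 0), affine_params(tx = 1))
  sm2 <- smooth_params(step_tx)
  expect_equal(sm2$params[[2]]$tx, 0.05)
  expect_equal(sm2$alpha[2], 0.05)

  ## a 0.2 rad rotation step engages the correction phase and settles
  ## within 1% of the target faster than a fixed slow smoother
  obs <- c(rep(0, 5), rep(0.2, 150))
  stream <- lapply(obs, function(th) affine_params(theta = th))
  ad <- smooth_params(stream)
  expect_true(any(ad$correction))
  expect_true(all(ad$alpha >= 0.05 & ad$alpha <= 0.8))
  fx <- smooth_params(stream, alpha_fast = 0.05, theta_threshold = Inf)
  settle <- function(sm) {
    th <- vapply(sm$params, `[[`, numeric(1), "theta")
    which(abs(th - 0.2) < 0.002)[1]
  }
  expect_lt(settle(ad), settle(fx))
  ## alpha returns to the baseline after the error subsides
  expect_equal(ad$alpha[length(obs)], 0.05)
})

test_that("warping follows the sampling convention and round-trips", {
  set.seed(4)
  img <- array(0, c(40, 50, 3))
  img[20, 30, ] <- 1                       # impulse at x=29, y=19 (0-based)
  ## identity is a no-op
  expect_equal(warp_affine(img, affine_params()), img, tolerance = 1e-12)
  ## tx = +3 moves content by -3 px in x
  w <- warp_affine(img, affine_params(tx = 3))
  expect_equal(w[20, 27, 2], 1)
  expect_equal(sum(w[, , 2]), 1, tolerance = 1e-9)

  ## warp then inverse warp of a smooth image is close to the original
  sm <- array(0, c(40, 50, 3))
  xs <- matrix(rep(0:49, each = 40), 40)
  ys <- matrix(rep(0:39, 50), 40)
  for (c in 1:3) sm[, , c] <- 0.5 + 0.3 * sin(xs / 6) * cos(ys / 5)
  p <- affine_params(tx = 1.3, ty = -0.7, theta = 0.03, s = 1.02)
  rt <- warp_affine(warp_affine(sm, p), invert_affine(p))
  interior <- rt[8:32, 8:42, ] - sm[8:32, 8:42, ]
  expect_lt(max(abs(interior)), 0.005)
})

test_that("optical-flow refinement removes horizontal shifts only", {
  set.seed(5)
  base <- array(0, c(60, 80, 3))
  xs <- matrix(rep(0:79, each = 60), 60)
  ys <- matrix(rep(0:59, 80), 60)
  tex <- 0.5 + 0.2 * sin(xs / 3.1) * cos(ys / 2.7) + 0.1 * sin((xs + ys) / 5)
  for (c in 1:3) base[, , c] <- tex
  pts <- matrix(c(25, 30, 55, 30), 2, byrow = TRUE)

  ## identical frames: no correction
  r0 <- translational_refine(base, base, pts, pts[, 1])
  expect_equal(r0$tx, 0, tolerance = 1e-3)

  ## +2 px global x shift is recovered within 0.25 px
  shifted <- warp_affine(base, affine_params(tx = -2))  # content moves +2
  r1 <- translational_refine(base, shifted, pts, pts[, 1])
  expect_equal(r1$tx, 2, tolerance = 0.25)
  expect_equal(r1$n_tracked, 2L)

  ## pure vertical shift: horizontal correction stays near zero
  vshift <- warp_affine(base, affine_params(ty = -2))
  r2 <- translational_refine(base, vshift, pts, pts[, 1])
  expect_lt(abs(r2$tx), 0.25)

  ## flow failure on both points falls back to the unchanged frame
  flat <- array(0.5, c(60, 80, 3))
  expect_warning(r3 <- translational_refine(flat, flat, pts, pts[, 1]),
                 "failed")
  expect_equal(r3$tx, 0)
  expect_identical(r3$frame, flat)
})

test_that("jitter metrics use population SDs over high-motion frames", {
  ## constant trajectory: zero jitter (whole-trajectory fallback engaged)
  j0 <- jitter_metrics(cbind(rep(3, 20), rep(4, 20)), rep(0.1, 20), 20)
  expect_equal(j0$positional, 0)
  expect_equal(j0$rotational, 0)
  expect_true(j0$fallback)

  ## x alternating +/-1 about fixed y: positional jitter exactly 1 px
  n <- 40
  traj <- cbind(rep(c(1, -1), n / 2), rep(0, n))
  j1 <- jitter_metrics(traj, rep(0, n), 20)
  expect_equal(j1$positional, 1.0)
  expect_equal(j1$rotational, 0)
})

test_that("stabilization reduces jitter on a moving synthetic scene", {
  sc <- study_scene()
  track <- detect_landmarks(sc$video, landmark_provider_synthetic(sc$truth))
  rep <- jitter_report(sc$video, track)
  expect_lte(rep$after$positional, rep$before$positional)
  expect_lte(rep$after$rotational, rep$before$rotational)
})
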