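## Ground-truthed synthetic data: face-like video scenes with a known
## pulsatile colour modulation, rigid head motion, a shadowed cheek, sensor
## noise and a paired 256 Hz reference PPG; plus signal-level mixtures for
## the source-separation stages. Everything is seed-deterministic.

#' Synthetic scene configuration
#'
#' Defines the study conditions the scene generator emulates: a skin-toned
#' elliptical face on a textured background carrying a weak pulsatile colour
#' modulation at a known cardiac frequency, smooth band-limited head motion
#' (drift plus wander; physical head motion is slow, so wander is built from
#' incommensurate low-frequency sinusoids scaled to the requested SD, with a
#' small iid landmark-noise floor on top), a shadowed right cheek with
#' reduced luminance and a cooler, desaturated cast, and Gaussian pixel
#' noise.
#'
#' @param duration_s scene length in seconds.
#' @param fps frame rate (Hz); must exceed twice the cardiac band top.
#' @param width,height frame size in pixels.
#' @param hr_bpm injected heart rate (48-180 bpm).
#' @param modulation fractional pulsatile modulation of skin intensity
#'   (green channel; red gets half, physiologically signed).
#' @param drift_amp slow translational drift amplitude (px, 0.03 Hz).
#' @param jitter_sd SD of the translational wander per axis (px).
#' @param rot_sd SD of the rotational wander (radians).
#' @param step_rot,step_time optional step rotation (radians) applied from
#'   `step_time` seconds onward (exercises the correction-phase smoother).
#' @param shadow add the shadowed-cheek region (default `TRUE`).
#' @param noise_sd pixel noise SD (intensity units in `[0, 1]`).
#' @param lm_noise_sd landmark observation noise SD (px).
#' @param seed RNG seed.
#' @return A validated `scene_config` list.
#' @export
scene_config <- function(duration_s = 60, fps = 20, width = 160, height = 120,
                         hr_bpm = 72, modulation = 0.01,
                         drift_amp = 2, jitter_sd = 1.5, rot_sd = 0.01,
                         step_rot = 0, step_time = NULL,
                         shadow = TRUE, noise_sd = 0.01, lm_noise_sd = 0.15,
                         seed = 1L) {
  cfg <- list(duration_s = duration_s, fps = fps, width = width,
              height = height, hr_bpm = hr_bpm, modulation = modulation,
              drift_amp = drift_amp, jitter_sd = jitter_sd, rot_sd = rot_sd,
              step_rot = step_rot, step_time = step_time, shadow = shadow,
              noise_sd = noise_sd, lm_noise_sd = lm_noise_sd,
              seed = as.integer(seed))
  if (!(hr_bpm / 60 > 0.8 && hr_bpm / 60 < 3.0))
    stop("validation error: hr_bpm must lie strictly inside 48-180 bpm",
         call. = FALSE)
  if (fps <= 6)
    stop("validation error: fps must exceed twice the 3 Hz cardiac band",
         call. = FALSE)
  if (modulation < 0 || noise_sd < 0 || duration_s <= 0)
    stop("validation error: invalid scene parameters", call. = FALSE)
  class(cfg) <- "scene_config"
  cfg
}

## band-limited wander: two incommensurate sinusoids, scaled to unit SD
.wander <- function(t, f1, f2) {
  w <- 0.7 * sin(2 * pi * f1 * t + stats::runif(1, 0, 2 * pi)) +
    0.5 * sin(2 * pi * f2 * t + stats::runif(1, 0, 2 * pi))
  s <- stats::sd(w)
  if (s == 0) w else w / s
}

.skin_rgb <- c(0.85, 0.55, 0.50)
.shadow_factors <- c(0.48, 0.72, 0.70)   # cool, desaturated fill light

#' Generate a ground-truthed synthetic face scene
#'
#' Renders the scene described by a [scene_config] and returns the video
#' together with complete ground truth: per-frame landmark observations and
#' exact positions, applied rigid transforms, the clean pulse waveform, the
#' shadowed-triangle id set (relative to the [face_mesh_template]
#' triangulation), and a paired 256 Hz reference PPG with matching beat
#' frequency.
#'
#' @param config a [scene_config].
#' @return list with `video` (a [frame_sequence]) and `truth` (class
#'   `scene_truth`).
#' @export
make_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  with_preserved_seed(config$seed, .make_scene_impl(config))
}

.make_scene_impl <- function(cfg) {
  W <- cfg$width; H <- cfg$height; fps <- cfg$fps
  n <- as.integer(round(cfg$duration_s * fps))
  tt <- (seq_len(n) - 1L) / fps
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  rx <- 0.30 * W; ry <- 0.42 * H

  ## canonical landmark layout in pixel coordinates
  lm0 <- place_template(c(cx, cy), rx, ry)

  ## background: smooth random texture with enough gradient for flow tracking
  bg <- matrix(stats::rnorm(H * W), H, W)
  for (i in 1:2) bg <- blur_binomial5(bg)
  bg <- 0.35 + 0.12 * (bg - mean(bg)) / stats::sd(bg)
  base <- array(0, c(H, W, 3L))
  for (c in 1:3) base[, , c] <- bg * c(1, 0.95, 0.9)[c]

  px <- matrix(rep(0:(W - 1L), each = H), H, W)
  py <- matrix(rep(0:(H - 1L), times = W), H, W)
  skin <- ((px - cx) / rx)^2 + ((py - cy) / ry)^2 <= 1
  for (c in 1:3) {
    ch <- base[, , c]
    ch[skin] <- .skin_rgb[c]
    base[, , c] <- ch
  }
  ## mild within-face shading so the face is not flat (keeps flow trackable)
  shade <- 1 - 0.08 * ((px - cx) / rx)^2
  shadow_rect <- c(x0 = cx + 0.12 * rx, x1 = cx + 0.85 * rx,
                   y0 = cy - 0.12 * ry, y1 = cy + 0.55 * ry)
  shadow_mask <- skin & px >= shadow_rect["x0"] & px <= shadow_rect["x1"] &
    py >= shadow_rect["y0"] & py <= shadow_rect["y1"]
  for (c in 1:3) {
    ch <- base[, , c]
    ch[skin] <- ch[skin] * shade[skin]
    if (cfg$shadow) ch[shadow_mask] <- ch[shadow_mask] * .shadow_factors[c]
    base[, , c] <- ch
  }

  ## pulse waveform (fundamental + second harmonic)
  f0 <- cfg$hr_bpm / 60
  pulse <- sin(2 * pi * f0 * tt) + 0.3 * sin(4 * pi * f0 * tt + 0.5)

  ## motion trajectories
  dx <- cfg$drift_amp * sin(2 * pi * 0.03 * tt + stats::runif(1, 0, 2 * pi)) +
    cfg$jitter_sd * .wander(tt, 0.09, 0.143)
  dy <- cfg$drift_amp * sin(2 * pi * 0.03 * tt + stats::runif(1, 0, 2 * pi)) +
    cfg$jitter_sd * .wander(tt, 0.076, 0.127)
  th <- cfg$rot_sd * .wander(tt, 0.055, 0.111)
  if (cfg$step_rot != 0 && !is.null(cfg$step_time))
    th <- th + cfg$step_rot * (tt >= cfg$step_time)

  frames <- vector("list", n)
  transforms <- vector("list", n)
  lms_exact <- vector("list", n)
  lms_obs <- vector("list", n)
  gmask <- skin
  for (t in seq_len(n)) {
    fr <- base
    mod_g <- cfg$modulation * pulse[t]
    fr[, , 2L][gmask] <- fr[, , 2L][gmask] - mod_g
    fr[, , 1L][gmask] <- fr[, , 1L][gmask] - 0.5 * mod_g
    ## rigid motion about the face centre: p' = R (p - c) + c + d
    ct <- cos(th[t]); st <- sin(th[t])
    M <- affine_params(
      tx = cx - (ct * cx - st * cy) + dx[t],
      ty = cy - (st * cx + ct * cy) + dy[t],
      theta = th[t], s = 1)
    transforms[[t]] <- M
    frames[[t]] <- warp_affine(fr, invert_affine(M))
    if (cfg$noise_sd > 0)
      frames[[t]] <- clamp01(frames[[t]] +
                               array(stats::rnorm(H * W * 3L, 0, cfg$noise_sd),
                                     c(H, W, 3L)))
    else frames[[t]] <- clamp01(frames[[t]])
    lm <- transform_points(lm0, M)
    lms_exact[[t]] <- lm
    lms_obs[[t]] <- lm + matrix(stats::rnorm(2L * nrow(lm), 0,
                                             cfg$lm_noise_sd), ncol = 2L)
  }

  ## shadowed triangles: centroid inside the shadow rectangle
  tpl <- face_mesh_template()
  tri <- tpl$triangles
  ccx <- (lm0[tri[, 1L], 1L] + lm0[tri[, 2L], 1L] + lm0[tri[, 3L], 1L]) / 3
  ccy <- (lm0[tri[, 1L], 2L] + lm0[tri[, 2L], 2L] + lm0[tri[, 3L], 2L]) / 3
  shadow_ids <- which(ccx >= shadow_rect["x0"] & ccx <= shadow_rect["x1"] &
                        ccy >= shadow_rect["y0"] & ccy <= shadow_rect["y1"])

  ppg <- make_reference_ppg(cfg$hr_bpm, cfg$duration_s, fs = 256,
                            seed = cfg$seed + 1L)

  truth <- structure(list(
    landmarks = lms_obs, landmarks_exact = lms_exact,
    canonical_landmarks = lm0, transforms = transforms,
    theta = th, translation = cbind(dx, dy),
    pulse = pulse, hr_bpm = cfg$hr_bpm, f0_hz = f0,
    shadow_triangle_ids = if (cfg$shadow) shadow_ids else integer(0),
    shadow_rect = shadow_rect, skin_mask = skin,
    ppg = ppg, config = cfg), class = "scene_truth")
  list(video = frame_sequence(frames, fps), truth = truth)
}

#' Synthetic reference PPG waveform
#'
#' Beat train with a two-bump (systolic/diastolic) morphology: each beat is
#' the sum of two Gaussians (systolic at 15% of the period, width 7%;
#' diastolic at 45%, width 12%, amplitude 0.45), plus baseline drift and
#' noise.
#'
#' @param hr_bpm heart rate (scalar, or vector over the sample grid for a
#'   trajectory).
#' @param duration_s length in seconds.
#' @param fs sampling rate (Hz), default 256.
#' @param noise_sd additive noise SD.
#' @param drift_amp baseline drift amplitude (0.1 Hz sinusoid).
#' @param seed RNG seed.
#' @return list with `x` (waveform), `fs`, `beat_times` (s), `hr_bpm`.
#' @export
make_reference_ppg <- function(hr_bpm, duration_s, fs = 256, noise_sd = 0.02,
                               drift_amp = 0.1, seed = 1L) {
  with_preserved_seed(seed, {
    nn <- as.integer(round(duration_s * fs))
    tt <- (seq_len(nn) - 1L) / fs
    f <- rep_len(hr_bpm, nn) / 60
    if (any(f < 0.8 | f > 3.0))
      stop("validation error: reference HR outside the cardiac band",
           call. = FALSE)
    phase <- cumsum(f) / fs
    beat_idx <- which(diff(floor(c(0, phase))) > 0)
    beat_times <- tt[beat_idx]
    x <- numeric(nn)
    for (tb in beat_times) {
      Tb <- 1 / f[max(1L, round(tb * fs))]
      x <- x + exp(-(tt - tb - 0.15 * Tb)^2 / (2 * (0.07 * Tb)^2)) +
        0.45 * exp(-(tt - tb - 0.45 * Tb)^2 / (2 * (0.12 * Tb)^2))
    }
    x <- x + drift_amp * sin(2 * pi * 0.1 * tt) +
      stats::rnorm(nn, 0, noise_sd)
    list(x = x, fs = fs, beat_times = beat_times, hr_bpm = hr_bpm)
  })
}

#' Write a synthetic reference PPG as CSV
#'
#' @param ppg output of [make_reference_ppg] (or `truth$ppg`).
#' @param path CSV path (`time,value`).
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(ppg, path) {
  utils::write.csv(data.frame(time = (seq_along(ppg$x) - 1L) / ppg$fs,
                              value = ppg$x),
                   path, row.names = FALSE)
  invisible(path)
}

#' Synthetic multichannel mixtures for the separation stages
#'
#' Mixes a quasi-periodic pulse source (fundamental plus a 0.3-amplitude
#' second harmonic with slow frequency wander) with noise sources (one
#' AR(1), the rest white) through a random full-rank mixing matrix whose
#' pulse column is scaled to the requested per-channel SNR.
#'
#' @param n_channels number of observed channels (>= 2).
#' @param snr_db per-channel pulse-to-noise ratio in dB.
#' @param seed RNG seed.
#' @param duration_s,fs signal length and rate.
#' @param f0_hz pulse fundamental (Hz).
#' @param n_noise number of noise sources (default 2).
#' @param mixing optional fixed mixing matrix
#'   (`n_channels x (1 + n_noise)`); overrides the random, SNR-scaled one.
#' @return list with `X` (`n_channels x T`), `sources`, `mixing`, `pulse`,
#'   `fs`.
#' @export
make_mixture <- function(n_channels = 10L, snr_db = 0, seed = 1L,
                         duration_s = 30, fs = 20, f0_hz = 1.2,
                         n_noise = 2L, mixing = NULL) {
  stopifnot(n_channels >= 2L, n_noise >= 1L)
  with_preserved_seed(seed, {
    nn <- as.integer(round(duration_s * fs))
    tt <- (seq_len(nn) - 1L) / fs
    f <- f0_hz * (1 + 0.03 * sin(2 * pi * 0.05 * tt +
                                   stats::runif(1, 0, 2 * pi)))
    ph <- 2 * pi * cumsum(f) / fs
    pulse <- sin(ph) + 0.3 * sin(2 * ph)
    noise <- matrix(0, n_noise, nn)
    ar <- stats::rnorm(nn)
    for (t in 2:nn) ar[t] <- 0.95 * ar[t - 1L] + ar[t]
    noise[1L, ] <- ar
    if (n_noise > 1L)
      for (j in 2:n_noise) noise[j, ] <- stats::rnorm(nn)
    S <- rbind(pulse, noise)
    S <- S / apply(S, 1L, stats::sd)
    dimnames(S) <- NULL
    if (is.null(mixing)) {
      A <- matrix(stats::rnorm(n_channels * (n_noise + 1L)), n_channels)
      snr <- 10^(snr_db / 10)
      for (i in seq_len(n_channels)) {
        nv <- sum(A[i, -1L]^2)
        A[i, 1L] <- sign(A[i, 1L]) * sqrt(snr * nv)
      }
    } else {
      A <- as.matrix(mixing)
      stopifnot(nrow(A) == n_channels, ncol(A) == n_noise + 1L)
    }
    list(X = A %*% S, sources = S, mixing = A, pulse = S[1L, ], fs = fs)
  })
}
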