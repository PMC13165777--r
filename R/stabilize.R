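## Two-stage geometric stabilization: temporally smoothed similarity
## correction into a canonical face coordinate system, followed by
## optical-flow translational refinement, plus residual-jitter metrics.

#' 4-DOF affine (similarity) parameters
#'
#' Translation `(tx, ty)` in pixels, in-plane rotation `theta` in radians and
#' isotropic scale `s`. [affine_matrix] and [decompose_affine] are exact
#' inverses for this 4-DOF family.
#'
#' @param tx,ty translation (pixels).
#' @param theta rotation (radians).
#' @param s isotropic scale (`> 0`).
#' @return An `affine_params` object.
#' @export
affine_params <- function(tx = 0, ty = 0, theta = 0, s = 1) {
  stopifnot(is.finite(tx), is.finite(ty), is.finite(theta), is.finite(s), s > 0)
  structure(list(tx = tx, ty = ty, theta = theta, s = s),
            class = "affine_params")
}

#' @rdname affine_params
#' @param params an `affine_params` object.
#' @return For `affine_matrix`, the `2 x 3` matrix `[A | t]` with
#'   `A = s R(theta)`.
#' @export
affine_matrix <- function(params) {
  a <- params$s * cos(params$theta)
  b <- params$s * sin(params$theta)
  matrix(c(a, -b, params$tx,
           b,  a, params$ty), nrow = 2L, byrow = TRUE)
}

#' @rdname affine_params
#' @param m a `2 x 3` similarity matrix.
#' @export
decompose_affine <- function(m) {
  s <- sqrt(m[1L, 1L]^2 + m[2L, 1L]^2)
  affine_params(tx = m[1L, 3L], ty = m[2L, 3L],
                theta = atan2(m[2L, 1L], m[1L, 1L]), s = s)
}

#' @rdname affine_params
#' @export
invert_affine <- function(params) {
  s <- 1 / params$s
  th <- -params$theta
  ## inverse of p' = A p + t is p = A^-1 p' - A^-1 t
  a <- s * cos(th); b <- s * sin(th)
  affine_params(tx = -(a * params$tx - b * params$ty),
                ty = -(b * params$tx + a * params$ty),
                theta = th, s = s)
}

#' Apply an affine transform to points
#'
#' @param points `n x 2` matrix of (x, y) coordinates.
#' @param params an [affine_params].
#' @return Transformed `n x 2` matrix.
#' @export
transform_points <- function(points, params) {
  m <- affine_matrix(params)
  cbind(m[1L, 1L] * points[, 1L] + m[1L, 2L] * points[, 2L] + m[1L, 3L],
        m[2L, 1L] * points[, 1L] + m[2L, 2L] * points[, 2L] + m[2L, 3L])
}

#' Least-squares similarity transform between two landmark sets
#'
#' Estimates the 4-DOF transform (rotation, isotropic scale, translation)
#' mapping `landmarks` onto `canonical` in the least-squares (Procrustes)
#' sense.
#'
#' @param landmarks `n x 2` matrix of current landmark positions (pixels).
#' @param canonical `n x 2` matrix of canonical positions, or a
#'   `canonical_reference`.
#' @return An [affine_params] with an extra `residual` element (RMS point
#'   distance after alignment).
#' @export
estimate_similarity <- function(landmarks, canonical) {
  if (inherits(canonical, "canonical_reference")) canonical <- canonical$points
  P <- as.matrix(landmarks); Q <- as.matrix(canonical)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 2L, ncol(Q) == 2L,
            all(is.finite(P)), all(is.finite(Q)))
  pm <- colMeans(P); qm <- colMeans(Q)
  Pc <- sweep(P, 2L, pm); Qc <- sweep(Q, 2L, qm)
  np <- sum(Pc^2)
  if (np < 1e-12)
    stop("estimation error: degenerate point cloud (all points coincident)",
         call. = FALSE)
  cc <- sum(Pc * Qc)
  dd <- sum(Pc[, 1L] * Qc[, 2L] - Pc[, 2L] * Qc[, 1L])
  s <- sqrt(cc^2 + dd^2) / np
  theta <- atan2(dd, cc)
  a <- s * cos(theta); b <- s * sin(theta)
  t <- c(qm[1L] - (a * pm[1L] - b * pm[2L]),
         qm[2L] - (b * pm[1L] + a * pm[2L]))
  out <- affine_params(tx = t[1L], ty = t[2L], theta = theta, s = s)
  fit <- transform_points(P, out)
  out$residual <- sqrt(mean(rowSums((Q - fit)^2)))
  out
}

#' Adaptive exponential smoothing of transform parameters
#'
#' Each of `tx, ty, theta, s` is smoothed independently by an exponential
#' moving average `p_hat[t] = (1 - alpha) p_hat[t-1] + alpha p[t]`. A low
#' baseline `alpha_slow` filters detection jitter; when the rotation
#' observation departs from the smoothed rotation by more than
#' `theta_threshold` radians a correction phase starts, ramping `alpha`
#' towards `alpha_fast` by `ramp` per frame until the rotational error
#' subsides, after which `alpha` resets to `alpha_slow`.
#'
#' @param params list of [affine_params] (one per frame; the first observation
#'   initialises the smoother).
#' @param alpha_slow,alpha_fast EMA baseline and correction-phase ceilings.
#' @param theta_threshold rotation-error threshold (radians) that triggers a
#'   correction phase.
#' @param ramp per-frame increment of `alpha` during a correction phase.
#' @return A list with `params` (list of smoothed [affine_params]), `alpha`
#'   (numeric vector of the alpha used at each frame) and `correction`
#'   (logical vector).
#' @export
smooth_params <- function(params, alpha_slow = 0.05, alpha_fast = 0.8,
                          theta_threshold = 0.05, ramp = 0.15) {
  n <- length(params)
  stopifnot(n >= 1L)
  out <- vector("list", n)
  alpha_trace <- numeric(n)
  correction <- logical(n)
  hat <- unlist(params[[1L]][c("tx", "ty", "theta", "s")])
  out[[1L]] <- params[[1L]]
  alpha <- alpha_slow
  alpha_trace[1L] <- alpha
  if (n > 1L) for (t in 2:n) {
    p <- unlist(params[[t]][c("tx", "ty", "theta", "s")])
    err <- abs(p[["theta"]] - hat[["theta"]])
    if (err > theta_threshold) {
      alpha <- min(alpha_fast, alpha + ramp)
      correction[t] <- TRUE
    } else {
      alpha <- alpha_slow
    }
    hat <- (1 - alpha) * hat + alpha * p
    alpha_trace[t] <- alpha
    out[[t]] <- affine_params(hat[["tx"]], hat[["ty"]], hat[["theta"]],
                              hat[["s"]])
  }
  list(params = out, alpha = alpha_trace, correction = correction)
}

## bilinear gather with replicate borders; xs/ys in 0-based pixel coords
bilinear_sample <- function(ch, xs, ys) {
  H <- nrow(ch); W <- ncol(ch)
  xs <- pmin(pmax(xs, 0), W - 1)
  ys <- pmin(pmax(ys, 0), H - 1)
  x0 <- pmin(floor(xs), W - 2); y0 <- pmin(floor(ys), H - 2)
  fx <- xs - x0; fy <- ys - y0
  i0 <- as.integer(y0) + 1L; j0 <- as.integer(x0) + 1L
  idx00 <- i0 + (j0 - 1L) * H
  idx01 <- idx00 + H          # x + 1
  idx10 <- idx00 + 1L         # y + 1
  idx11 <- idx01 + 1L
  (1 - fy) * ((1 - fx) * ch[idx00] + fx * ch[idx01]) +
    fy * ((1 - fx) * ch[idx10] + fx * ch[idx11])
}

#' Warp a frame under a similarity transform
#'
#' Resamples a frame with bilinear interpolation and replicate borders. The
#' parameters define the sampling map from output to input coordinates:
#' `out(q) = frame(A q + t)` (so a pure translation `tx = +3` moves image
#' content by `-3` px). [warp_to_canonical] is the stabilization use: given
#' the smoothed current-to-canonical transform it samples through its
#' inverse, placing the face at the canonical pose.
#'
#' @param frame `H x W x 3` array (or `H x W` matrix).
#' @param params an [affine_params]; for `warp_affine` the sampling map
#'   itself, for `warp_to_canonical` the current-to-canonical transform.
#' @return Warped frame, same size.
#' @export
warp_affine <- function(frame, params) {
  m <- affine_matrix(params)
  d <- dim(frame)
  H <- d[1L]; W <- d[2L]
  X <- rep(0:(W - 1L), each = H)
  Y <- rep(0:(H - 1L), times = W)
  xs <- m[1L, 1L] * X + m[1L, 2L] * Y + m[1L, 3L]
  ys <- m[2L, 1L] * X + m[2L, 2L] * Y + m[2L, 3L]
  if (length(d) == 2L) {
    return(matrix(bilinear_sample(frame, xs, ys), H, W))
  }
  out <- array(0, d)
  for (c in seq_len(d[3L]))
    out[, , c] <- bilinear_sample(frame[, , c], xs, ys)
  out
}

#' @rdname warp_affine
#' @export
warp_to_canonical <- function(frame, params) {
  warp_affine(frame, invert_affine(params))
}

## Lucas-Kanade tracking of one point from prev to cur (grayscale matrices).
## Returns the displacement c(dx, dy) or NULL on failure.
lk_track_point <- function(prev, cur, x, y, radius = 7L, max_iter = 10L) {
  H <- nrow(prev); W <- ncol(prev)
  gx <- rep(seq(-radius, radius), times = 2L * radius + 1L)
  gy <- rep(seq(-radius, radius), each = 2L * radius + 1L)
  px <- x + gx; py <- y + gy
  if (min(px) < 1 || max(px) > W - 2 || min(py) < 1 || max(py) > H - 2)
    return(NULL)
  i0 <- bilinear_sample(prev, px, py)
  ix <- (bilinear_sample(prev, px + 1, py) -
           bilinear_sample(prev, px - 1, py)) / 2
  iy <- (bilinear_sample(prev, px, py + 1) -
           bilinear_sample(prev, px, py - 1)) / 2
  g11 <- sum(ix * ix); g12 <- sum(ix * iy); g22 <- sum(iy * iy)
  det <- g11 * g22 - g12^2
  if (!is.finite(det) || det < 1e-8) return(NULL)
  d <- c(0, 0)
  for (it in seq_len(max_iter)) {
    i1 <- bilinear_sample(cur, px + d[1L], py + d[2L])
    e <- i0 - i1
    b1 <- sum(ix * e); b2 <- sum(iy * e)
    dd <- c(g22 * b1 - g12 * b2, g11 * b2 - g12 * b1) / det
    d <- d + dd
    if (!all(is.finite(d)) || max(abs(d)) > 4 * radius) return(NULL)
    if (max(abs(dd)) < 1e-3) break
  }
  d
}

#' Optical-flow translational refinement of a stabilized frame
#'
#' Tracks the two face-boundary landmarks from the previous stabilized frame
#' into the current one with Lucas-Kanade optical flow, computes their mean
#' horizontal displacement relative to the canonical reference x positions,
#' and removes it with a pure horizontal translation. If flow fails on both
#' points the frame is returned unchanged with a warning.
#'
#' @param prev_frame,cur_frame consecutive stabilized frames
#'   (`H x W x 3` arrays).
#' @param boundary_points `2 x 2` matrix: positions of the two tracked points
#'   in `prev_frame` (pixel coordinates).
#' @param canonical_x length-2 canonical x positions of the same points.
#' @return list with `frame` (corrected), `tx` (applied horizontal
#'   correction, px), `n_tracked`.
#' @export
translational_refine <- function(prev_frame, cur_frame, boundary_points,
                                 canonical_x) {
  gp <- (prev_frame[, , 1L] + prev_frame[, , 2L] + prev_frame[, , 3L]) / 3
  gc <- (cur_frame[, , 1L] + cur_frame[, , 2L] + cur_frame[, , 3L]) / 3
  dxs <- numeric(0)
  for (k in 1:2) {
    d <- lk_track_point(gp, gc, boundary_points[k, 1L], boundary_points[k, 2L])
    if (!is.null(d))
      dxs <- c(dxs, boundary_points[k, 1L] + d[1L] - canonical_x[k])
  }
  if (length(dxs) == 0L) {
    warning("optical-flow refinement failed on both boundary points; ",
            "skipping correction")
    return(list(frame = cur_frame, tx = 0, n_tracked = 0L))
  }
  tx <- mean(dxs)
  list(frame = warp_affine(cur_frame, affine_params(tx = tx)),
       tx = tx, n_tracked = length(dxs))
}

#' Residual-jitter metrics for a landmark trajectory
#'
#' Positional jitter is the spatial standard deviation
#' `sqrt(var_x + var_y)` (population variances) of a designated cheek
#' landmark over high-motion frames, i.e. frames whose inter-frame landmark
#' speed exceeds the mean speed plus one standard deviation. Rotational
#' jitter is the standard deviation of the rotation angle over the same
#' frames. With no high-motion frames, whole-trajectory values are reported
#' and flagged.
#'
#' @param trajectory `n x 2` matrix of the tracked landmark (pixels).
#' @param theta numeric vector of rotation angles (radians), length `n`.
#' @param fps frame rate (Hz); kept for reporting.
#' @return list with `positional`, `rotational`, `n_high_motion`, `fallback`.
#' @export
jitter_metrics <- function(trajectory, theta, fps = NULL) {
  trajectory <- as.matrix(trajectory)
  n <- nrow(trajectory)
  stopifnot(n >= 3L, length(theta) == n)
  v <- sqrt(diff(trajectory[, 1L])^2 + diff(trajectory[, 2L])^2)
  thr <- mean(v) + stats::sd(v)
  high <- which(v > thr) + 1L
  fallback <- length(high) == 0L
  sel <- if (fallback) seq_len(n) else high
  varp <- function(x) mean((x - mean(x))^2)
  list(
    positional = sqrt(varp(trajectory[sel, 1L]) + varp(trajectory[sel, 2L])),
    rotational = sqrt(varp(theta[sel])),
    n_high_motion = length(high),
    fallback = fallback
  )
}

#' Stabilize a video into the canonical face coordinate system
#'
#' Runs the full two-stage stabilization: per-frame similarity estimation
#' against the canonical reference, adaptive EMA smoothing of the transform
#' parameters, warping into canonical coordinates, and (optionally)
#' optical-flow translational refinement using the left/right face-boundary
#' landmarks. Frames without a detection reuse the previous frame's smoothed
#' transform.
#'
#' @param video a [frame_sequence].
#' @param track a [landmark_track] for `video`.
#' @param canonical optional `canonical_reference` (built from `track` with
#'   `n_reference` frames when omitted).
#' @param alpha_slow,alpha_fast,theta_threshold,ramp see [smooth_params].
#' @param refine run the optical-flow refinement stage (default `TRUE`).
#' @param boundary_indices indices of the two tracked boundary landmarks
#'   (defaults to the template's leftmost/rightmost points).
#' @param n_reference frames averaged for the canonical reference.
#' @return list with `video` (stabilized [frame_sequence]), `canonical`,
#'   `params_raw` and `params_smoothed` (lists of [affine_params]), `alpha`,
#'   `tx_refine` (stage-2 corrections), and `landmarks` (stabilized
#'   [landmark_track], i.e. the raw landmarks carried through the applied
#'   warps).
#' @export
stabilize_video <- function(video, track, canonical = NULL,
                            alpha_slow = 0.05, alpha_fast = 0.8,
                            theta_threshold = 0.05, ramp = 0.15,
                            refine = TRUE, boundary_indices = NULL,
                            n_reference = 15L) {
  stopifnot(inherits(video, "frame_sequence"), inherits(track, "landmark_track"))
  if (is.null(canonical))
    canonical <- build_canonical_reference(track, n = n_reference)
  if (is.null(boundary_indices))
    boundary_indices <- face_mesh_template()$boundary_indices
  n <- video$frame_count

  raw <- vector("list", n)
  prev <- affine_params()
  for (t in seq_len(n)) {
    if (track$detected[t]) {
      prev <- estimate_similarity(track$points[[t]], canonical$points)
    }
    raw[[t]] <- prev
  }
  sm <- smooth_params(raw, alpha_slow = alpha_slow, alpha_fast = alpha_fast,
                      theta_threshold = theta_threshold, ramp = ramp)

  canon_bpts <- canonical$points[boundary_indices, , drop = FALSE]
  frames <- vector("list", n)
  lms <- vector("list", n)
  tx_refine <- numeric(n)
  for (t in seq_len(n)) {
    fr <- warp_to_canonical(video$frames[[t]], sm$params[[t]])
    lm <- if (track$detected[t])
      transform_points(track$points[[t]], sm$params[[t]]) else NULL
    if (refine && t > 1L) {
      rf <- translational_refine(frames[[t - 1L]], fr, canon_bpts,
                                 canon_bpts[, 1L])
      fr <- rf$frame
      tx_refine[t] <- rf$tx
      if (!is.null(lm)) lm[, 1L] <- lm[, 1L] - rf$tx
    }
    frames[[t]] <- fr
    lms[[t]] <- lm
  }
  list(video = frame_sequence(frames, video$fps),
       canonical = canonical,
       params_raw = raw, params_smoothed = sm$params,
       alpha = sm$alpha, tx_refine = tx_refine,
       landmarks = landmark_track(lms))
}

#' Before/after jitter report for a stabilized scene
#'
#' Compares residual jitter ([jitter_metrics]) of the designated cheek
#' landmark and of the rotation angle before stabilization (observed
#' landmark trajectory and raw similarity estimates) and after (landmarks
#' carried through the applied warps, with the residual rotation
#' re-estimated against the canonical reference).
#'
#' @param video a [frame_sequence].
#' @param track the matching [landmark_track].
#' @param cheek_index landmark used for positional jitter (default from the
#'   template).
#' @param ... passed to [stabilize_video].
#' @return list with `before`, `after` ([jitter_metrics] lists) and the
#'   `stabilization` result.
#' @export
jitter_report <- function(video, track, cheek_index = NULL, ...) {
  if (is.null(cheek_index)) cheek_index <- face_mesh_template()$cheek_index
  st <- stabilize_video(video, track, ...)
  ok_b <- track$detected
  traj_b <- t(vapply(track$points[ok_b], function(p) p[cheek_index, ],
                     numeric(2)))
  th_b <- vapply(st$params_raw[ok_b], function(p) p$theta, numeric(1))
  ok_a <- !vapply(st$landmarks$points, is.null, TRUE)
  traj_a <- t(vapply(st$landmarks$points[ok_a], function(p) p[cheek_index, ],
                     numeric(2)))
  th_a <- vapply(which(ok_a), function(i)
    estimate_similarity(st$landmarks$points[[i]], st$canonical)$theta,
    numeric(1))
  list(before = jitter_metrics(traj_b, th_b, video$fps),
       after = jitter_metrics(traj_a, th_a, video$fps),
       stabilization = st)
}
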