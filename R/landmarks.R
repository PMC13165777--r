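## Dense face-mesh template, landmark providers and the canonical reference.
##
## The pipeline consumes 478-point face meshes. External detectors are plugged
## in through a provider interface; the package itself ships (i) a synthetic
## provider bound to the scene generator's ground truth and (ii) a CSV replay
## provider for landmarks exported by any external 478-point detector.

N_LANDMARKS <- 478L

#' Canonical 478-point face-mesh template
#'
#' A fixed, deterministic landmark layout in unit face coordinates
#' (`[0, 1] x [0, 1]`, origin top-left, y downward), together with its
#' triangulation and the anatomical region polygons used for ROI selection.
#' The layout is a regular grid clipped to an elliptical face outline; the
#' triangulation connects grid neighbours, so triangle indices are a fixed
#' data asset reproducible from code alone.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{points}{`478 x 2` matrix of (x, y) unit coordinates.}
#'     \item{triangles}{`K x 3` integer matrix of landmark indices (1-based).}
#'     \item{polygons}{named list (`forehead`, `left_cheek`, `right_cheek`) of
#'       landmark-index loops outlining each anatomical region.}
#'     \item{boundary_indices}{left and right face-boundary landmark indices
#'       used by the translational refinement stage.}
#'     \item{cheek_index}{cheek landmark used for jitter metrics.}
#'   }
#' @export
face_mesh_template <- function() {
  if (!is.null(.template_cache$tpl)) return(.template_cache$tpl)
  nx <- 26L; ny <- 24L
  gx <- (rep(seq_len(nx), times = ny) - 0.5) / nx
  gy <- (rep(seq_len(ny), each = nx) - 0.5) / ny
  r <- sqrt(((gx - 0.5) / 0.48)^2 + ((gy - 0.5) / 0.48)^2)
  keep_rank <- order(r, seq_along(r))[seq_len(N_LANDMARKS)]
  keep <- logical(nx * ny); keep[keep_rank] <- TRUE
  ## landmark index of each kept grid node, row-major
  lm_of_grid <- integer(nx * ny)
  lm_of_grid[keep] <- seq_len(sum(keep))
  pts <- cbind(x = gx[keep], y = gy[keep])

  tris <- list()
  for (i in seq_len(ny - 1L)) {
    for (j in seq_len(nx - 1L)) {
      tl <- (i - 1L) * nx + j; tr <- tl + 1L
      bl <- i * nx + j;        br <- bl + 1L
      k <- c(tl, tr, bl, br)[keep[c(tl, tr, bl, br)]]
      if (length(k) == 4L) {
        tris[[length(tris) + 1L]] <- lm_of_grid[c(tl, tr, bl)]
        tris[[length(tris) + 1L]] <- lm_of_grid[c(tr, br, bl)]
      } else if (length(k) == 3L) {
        tris[[length(tris) + 1L]] <- lm_of_grid[k]
      }
    }
  }
  triangles <- do.call(rbind, tris)

  nearest <- function(xy) {
    d <- (pts[, 1L] - xy[1L])^2 + (pts[, 2L] - xy[2L])^2
    which.min(d)
  }
  quad <- function(x0, x1, y0, y1) {
    vapply(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)), nearest, 1L)
  }
  polygons <- list(
    forehead    = quad(0.30, 0.70, 0.10, 0.30),
    left_cheek  = quad(0.16, 0.40, 0.46, 0.72),
    right_cheek = quad(0.60, 0.84, 0.46, 0.72)
  )

  tpl <- list(
    points = pts,
    triangles = triangles,
    polygons = polygons,
    boundary_indices = c(left = which.min(pts[, 1L] + 1e-6 * pts[, 2L]),
                         right = which.max(pts[, 1L] - 1e-6 * pts[, 2L])),
    cheek_index = nearest(c(0.27, 0.58))
  )
  .template_cache$tpl <- tpl
  tpl
}

.template_cache <- new.env(parent = emptyenv())

#' Per-frame facial landmark track
#'
#' @param points list (one entry per frame) of `478 x 2` matrices, or `NULL`
#'   for frames where detection failed.
#' @param detected logical vector, one entry per frame.
#' @return A `landmark_track` object.
#' @export
landmark_track <- function(points, detected = !vapply(points, is.null, TRUE)) {
  stopifnot(length(points) == length(detected))
  structure(list(points = points, detected = detected,
                 n = length(points)),
            class = "landmark_track")
}

#' @export
print.landmark_track <- function(x, ...) {
  cat(sprintf("landmark_track: %d frames, %d detected\n", x$n, sum(x$detected)))
  invisible(x)
}

#' Detect facial landmarks on every frame of a video
#'
#' Runs a pluggable landmark provider frame by frame. A provider is a function
#' `f(frame, index)` returning a `478 x 2` matrix of (x, y) pixel coordinates
#' (origin top-left, 0-based pixel centres) or `NULL` when no face is found.
#' Frames where the provider fails are flagged `detected = FALSE`; a provider
#' returning the wrong number of points is a topology error.
#'
#' @param video a [frame_sequence].
#' @param provider provider function (see Details), e.g.
#'   [landmark_provider_synthetic] or [landmark_provider_csv].
#' @return A [landmark_track].
#' @export
detect_landmarks <- function(video, provider) {
  stopifnot(inherits(video, "frame_sequence"), is.function(provider))
  points <- vector("list", video$frame_count)
  for (i in seq_len(video$frame_count)) {
    p <- provider(video$frames[[i]], i)
    if (is.null(p)) next
    p <- as.matrix(p)
    if (nrow(p) != N_LANDMARKS || ncol(p) != 2L)
      stop(sprintf(
        "topology error: provider returned %d x %d points at frame %d (expected %d x 2)",
        nrow(p), ncol(p), i, N_LANDMARKS), call. = FALSE)
    if (!all(is.finite(p)))
      stop(sprintf("topology error: non-finite landmark at frame %d", i),
           call. = FALSE)
    points[[i]] <- p
  }
  landmark_track(points)
}

#' Landmark provider backed by synthetic scene ground truth
#'
#' @param truth a `scene_truth` object from [make_scene] (or any list with a
#'   `landmarks` list of per-frame `478 x 2` matrices).
#' @return A provider function for [detect_landmarks].
#' @export
landmark_provider_synthetic <- function(truth) {
  lms <- truth$landmarks
  function(frame, index) lms[[index]]
}

#' Landmark provider replaying an exported CSV
#'
#' Reads a `frame,index,x,y` CSV (1-based frame numbers, 1-based landmark
#' indices) as written by an external face-mesh detector, and serves it as a
#' provider. Frames absent from the file are reported undetected.
#'
#' @param path CSV file path.
#' @return A provider function for [detect_landmarks].
#' @export
landmark_provider_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame", "index", "x", "y") %in% names(df)))
  split_frames <- split(df[, c("index", "x", "y")], df$frame)
  function(frame, index) {
    key <- as.character(index)
    if (is.null(split_frames[[key]])) return(NULL)
    d <- split_frames[[key]]
    m <- matrix(NA_real_, max(d$index), 2L)
    m[d$index, ] <- cbind(d$x, d$y)
    m
  }
}

#' Export a landmark track to CSV
#'
#' @param track a [landmark_track].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(track, path) {
  rows <- lapply(which(track$detected), function(i) {
    p <- track$points[[i]]
    data.frame(frame = i, index = seq_len(nrow(p)), x = p[, 1L], y = p[, 2L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Build the subject-specific canonical reference face
#'
#' Averages the 2D coordinates of each landmark over the first `n` frames in
#' which a face was reliably detected (scanning forward from the first frame
#' and skipping undetected frames).
#'
#' @param track a [landmark_track].
#' @param n number of detected frames to average (default 15).
#' @return A `canonical_reference`: list with `points` (`478 x 2` mean
#'   layout) and `n_frames_used`.
#' @export
build_canonical_reference <- function(track, n = 15L) {
  stopifnot(inherits(track, "landmark_track"))
  idx <- which(track$detected)
  if (length(idx) < n)
    stop(sprintf(
      "insufficient detections: need %d detected frames, have %d", n,
      length(idx)), call. = FALSE)
  idx <- idx[seq_len(n)]
  acc <- Reduce(`+`, track$points[idx])
  structure(list(points = acc / n, n_frames_used = as.integer(n)),
            class = "canonical_reference")
}

#' @export
print.canonical_reference <- function(x, ...) {
  cat(sprintf("canonical_reference: %d landmarks averaged over %d frames\n",
              nrow(x$points), x$n_frames_used))
  invisible(x)
}

#' Place the face-mesh template at a given pose in a frame
#'
#' Maps the unit-coordinate template onto an ellipse of semi-axes
#' `(rx, ry)` centred at `centre` (pixels). Used by the synthetic scene
#' generator and handy for visual checks.
#'
#' @param centre `(x, y)` pixel centre of the face.
#' @param rx,ry face semi-axes in pixels.
#' @return `478 x 2` matrix of pixel coordinates.
#' @export
place_template <- function(centre, rx, ry) {
  tpl <- face_mesh_template()
  ## template ellipse has radius 0.48 in unit coordinates
  cbind(centre[1L] + (tpl$points[, 1L] - 0.5) * rx / 0.48,
        centre[2L] + (tpl$points[, 2L] - 0.5) * ry / 0.48)
}
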