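#' Ordered colour frames with a frame rate
#'
#' A `frame_sequence` is the container used for the raw, stabilized and
#' magnified videos alike: a list of `H x W x 3` arrays with channel values in
#' `[0, 1]`, plus the frame rate in Hz.
#'
#' @param frames list of `H x W x 3` numeric arrays, values in `[0, 1]`.
#' @param fps frames per second (Hz), `> 0`.
#' @return An object of class `frame_sequence` with elements `frames`, `fps`,
#'   `frame_count`, `height`, `width`.
#' @export
frame_sequence <- function(frames, fps) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("empty input: a frame_sequence needs at least one frame", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number", call. = FALSE)
  d <- dim(frames[[1L]])
  if (is.null(d) || length(d) != 3L || d[3L] != 3L)
    stop("frames must be H x W x 3 arrays", call. = FALSE)
  for (f in frames) {
    df <- dim(f)
    if (is.null(df) || !identical(df, d))
      stop("all frames must share the same dimensions", call. = FALSE)
  }
  structure(
    list(frames = frames, fps = fps, frame_count = length(frames),
         height = d[1L], width = d[2L]),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("frame_sequence: %d frames, %d x %d px, %.3g fps (%.1f s)\n",
              x$frame_count, x$width, x$height, x$fps,
              x$frame_count / x$fps))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) x$frame_count

#' Read a video as a frame sequence
#'
#' Reads a directory of per-frame PNG images (lexicographic frame order, all
#' the same size) into a [frame_sequence]. Frames are resized to
#' `target_size` with bilinear interpolation and scaled to `[0, 1]`. The frame
#' rate is taken from `fps` or, if present, from an `fps.txt` file in the
#' directory.
#'
#' @param path directory containing `*.png` frames.
#' @param target_size `c(width, height)` in pixels; default `c(320, 240)`.
#' @param fps frame rate override (Hz); default looks for `fps.txt`.
#' @return A [frame_sequence].
#' @export
read_video <- function(path, target_size = c(320L, 240L), fps = NULL) {
  if (!dir.exists(path))
    stop(sprintf("cannot read video: '%s' is not a readable directory", path),
         call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("empty input: no PNG frames found under '%s'", path),
         call. = FALSE)
  if (is.null(fps)) {
    fps_file <- file.path(path, "fps.txt")
    if (file.exists(fps_file)) {
      fps <- as.numeric(readLines(fps_file, n = 1L, warn = FALSE))
    } else {
      fps <- 20
    }
  }
  frames <- lapply(files, function(f) {
    img <- tryCatch(png::readPNG(f), error = function(e)
      stop(sprintf("I/O error decoding frame '%s': %s", f, conditionMessage(e)),
           call. = FALSE))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
    resize_bilinear(img, width = target_size[1L], height = target_size[2L])
  })
  frame_sequence(frames, fps)
}

#' Write a frame sequence as PNG frames
#'
#' Inverse of [read_video]: writes `frame_%05d.png` plus `fps.txt` under
#' `path`.
#'
#' @param video a [frame_sequence].
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "frame_sequence"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(video$frame_count)) {
    png::writePNG(clamp01(video$frames[[i]]),
                  file.path(path, sprintf("frame_%05d.png", i)))
  }
  writeLines(format(video$fps), file.path(path, "fps.txt"))
  invisible(path)
}

## bilinear resize of an H x W x C array to height x width
resize_bilinear <- function(img, width, height) {
  d <- dim(img)
  if (d[1L] == height && d[2L] == width) return(img)
  ## sample positions in source pixel-centre coordinates (0-based)
  sy <- (seq_len(height) - 0.5) * d[1L] / height - 0.5
  sx <- (seq_len(width)  - 0.5) * d[2L] / width  - 0.5
  sy <- pmin(pmax(sy, 0), d[1L] - 1)
  sx <- pmin(pmax(sx, 0), d[2L] - 1)
  y0 <- pmin(floor(sy), d[1L] - 2L); x0 <- pmin(floor(sx), d[2L] - 2L)
  wy <- sy - y0; wx <- sx - x0
  i0 <- as.integer(y0) + 1L; j0 <- as.integer(x0) + 1L
  out <- array(0, c(height, width, d[3L]))
  WY <- matrix(wy, height, width); WX <- matrix(wx, height, width, byrow = TRUE)
  for (c in seq_len(d[3L])) {
    ch <- img[, , c]
    a <- ch[i0, j0, drop = FALSE];      b <- ch[i0, j0 + 1L, drop = FALSE]
    d2 <- ch[i0 + 1L, j0, drop = FALSE]; e <- ch[i0 + 1L, j0 + 1L, drop = FALSE]
    out[, , c] <- (1 - WY) * ((1 - WX) * a + WX * b) +
      WY * ((1 - WX) * d2 + WX * e)
  }
  out
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

## --- colour conversions ----------------------------------------------------

.yiq_mat <- matrix(c(0.299,     0.587,     0.114,
                     0.595716, -0.274453, -0.321263,
                     0.211456, -0.522591,  0.311135),
                   nrow = 3L, byrow = TRUE)
.yiq_inv <- solve(.yiq_mat)

#' Convert between RGB and YIQ (NTSC) colour spaces
#'
#' Linear channel transforms used by the magnification stage. Inputs are
#' `H x W x 3` arrays (any real values; the transform is linear).
#'
#' @param img `H x W x 3` array.
#' @return `H x W x 3` array in the target space.
#' @export
rgb_to_yiq <- function(img) .apply_colmat(img, .yiq_mat)

#' @rdname rgb_to_yiq
#' @export
yiq_to_rgb <- function(img) .apply_colmat(img, .yiq_inv)

.apply_colmat <- function(img, m) {
  d <- dim(img)
  x <- matrix(img, ncol = 3L) %*% t(m)
  array(x, d)
}

#' RGB to zero-centred YUV chrominance (BT.601 full range)
#'
#' Used by the chrominance ROI filter. Inputs are mean RGB values on the
#' `[0, 255]` scale; returns `Y`, and zero-centred `U = 0.492 (B - Y)`,
#' `V = 0.877 (R - Y)`.
#'
#' @param rgb numeric matrix with columns R, G, B on `[0, 255]`.
#' @return matrix with columns `Y`, `U`, `V`.
#' @export
rgb_to_yuv <- function(rgb) {
  rgb <- matrix(rgb, ncol = 3L)
  y <- 0.299 * rgb[, 1L] + 0.587 * rgb[, 2L] + 0.114 * rgb[, 3L]
  u <- 0.492 * (rgb[, 3L] - y)
  v <- 0.877 * (rgb[, 1L] - y)
  cbind(Y = y, U = u, V = v)
}
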