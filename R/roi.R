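## Dense triangular ROI selection: tessellate the canonical face, keep
## triangles inside the forehead/cheek polygons, then keep only well-lit
## triangles via K-means clustering in chrominance (UV) space.

#' Tessellate the canonical face into triangular ROIs
#'
#' Builds one triangle ROI per row of the topology (a fixed triangle-index
#' asset, by default the [face_mesh_template] triangulation), with the
#' centroid computed in canonical reference space.
#'
#' @param canonical a `canonical_reference` (or `478 x 2` point matrix).
#' @param topology `K x 3` integer matrix of landmark indices (1-based);
#'   default from [face_mesh_template].
#' @return A data frame (class `triangle_rois`) with columns `id`, `v1`,
#'   `v2`, `v3`, `cx`, `cy`, `region` (NA until [filter_anatomical]),
#'   `retained`; the canonical points are attached as attribute `points`.
#' @export
tessellate <- function(canonical, topology = NULL) {
  if (inherits(canonical, "canonical_reference")) canonical <- canonical$points
  pts <- as.matrix(canonical)
  if (is.null(topology)) topology <- face_mesh_template()$triangles
  topology <- as.matrix(topology)
  stopifnot(ncol(topology) == 3L)
  if (any(topology < 1L) || any(topology > nrow(pts)))
    stop("topology error: triangle index out of range", call. = FALSE)
  if (any(topology[, 1L] == topology[, 2L] |
            topology[, 2L] == topology[, 3L] |
            topology[, 1L] == topology[, 3L]))
    stop("topology error: duplicate vertex indices in a triangle", call. = FALSE)
  cx <- (pts[topology[, 1L], 1L] + pts[topology[, 2L], 1L] +
           pts[topology[, 3L], 1L]) / 3
  cy <- (pts[topology[, 1L], 2L] + pts[topology[, 2L], 2L] +
           pts[topology[, 3L], 2L]) / 3
  out <- data.frame(id = seq_len(nrow(topology)),
                    v1 = topology[, 1L], v2 = topology[, 2L],
                    v3 = topology[, 3L],
                    cx = cx, cy = cy,
                    region = NA_character_, retained = TRUE)
  attr(out, "points") <- pts
  class(out) <- c("triangle_rois", class(out))
  out
}

## distance from point to segment; used for boundary-inclusive containment
.point_seg_dist <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) 0 else pmin(pmax(((px - x1) * vx + (py - y1) * vy) / L2, 0), 1)
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

#' Even-odd point-in-polygon test (boundary counts as inside)
#'
#' @param px,py point coordinates (vectors).
#' @param poly `n x 2` polygon vertex matrix (closed implicitly).
#' @param eps boundary tolerance.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  nxt <- c(2:n, 1L)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  for (k in seq_len(n)) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xs[nxt[k]]; y2 <- ys[nxt[k]]
    on_edge <- on_edge | (.point_seg_dist(px, py, x1, y1, x2, y2) <= eps)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

## proper-intersection check of two segments (shared endpoints allowed)
.segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1L] - p[1L]) * (r[2L] - p[2L]) -
    (q[2L] - p[2L]) * (r[1L] - p[1L])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

validate_polygon <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3L) stop("validation error: polygon needs >= 3 vertices", call. = FALSE)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i + 1L || (i == 1L && j == n)) next
    if (.segments_cross(poly[i, ], poly[nxt[i], ], poly[j, ], poly[nxt[j], ]))
      stop("validation error: self-intersecting polygon", call. = FALSE)
  }
  invisible(poly)
}

#' Keep triangles whose centroid lies in an anatomical region polygon
#'
#' Applies an even-odd, boundary-inclusive point-in-polygon test of each
#' triangle centroid (in canonical space) against the forehead and cheek
#' polygons; surviving triangles are tagged with their region.
#'
#' @param triangles a `triangle_rois` data frame from [tessellate].
#' @param polygons named list of polygons, each either an `n x 2` coordinate
#'   matrix or a vector of landmark indices into the canonical points;
#'   default from [face_mesh_template].
#' @return The candidate subset of `triangles` with `region` filled in.
#' @export
filter_anatomical <- function(triangles, polygons = NULL) {
  pts <- attr(triangles, "points")
  if (is.null(polygons)) polygons <- face_mesh_template()$polygons
  region <- rep(NA_character_, nrow(triangles))
  for (nm in names(polygons)) {
    poly <- polygons[[nm]]
    if (is.null(dim(poly))) poly <- pts[poly, , drop = FALSE]
    validate_polygon(poly)
    hit <- point_in_polygon(triangles$cx, triangles$cy, poly)
    region[is.na(region) & hit] <- nm
  }
  out <- triangles[!is.na(region), , drop = FALSE]
  out$region <- region[!is.na(region)]
  attr(out, "points") <- pts
  class(out) <- class(triangles)
  out
}

#' Rasterize a triangle onto the pixel grid
#'
#' Returns the pixels whose centres lie inside the triangle, edges inclusive.
#' Pixel centres sit at integer coordinates `(x, y) = (col-1, row-1)`
#' (origin top-left). Off-frame pixels are clipped; degenerate (zero-area)
#' triangles give an empty set.
#'
#' @param vertices `3 x 2` matrix of (x, y) vertex coordinates in pixels.
#' @param height,width frame size.
#' @return Integer vector of linear (column-major) indices into an
#'   `height x width` matrix.
#' @export
rasterize_triangle <- function(vertices, height, width) {
  v <- as.matrix(vertices)
  stopifnot(nrow(v) == 3L, ncol(v) == 2L, all(is.finite(v)))
  area2 <- (v[2L, 1L] - v[1L, 1L]) * (v[3L, 2L] - v[1L, 2L]) -
    (v[2L, 2L] - v[1L, 2L]) * (v[3L, 1L] - v[1L, 1L])
  if (abs(area2) < 1e-12) return(integer(0))
  x0 <- max(0L, as.integer(ceiling(min(v[, 1L]) - 1e-9)))
  x1 <- min(width - 1L, as.integer(floor(max(v[, 1L]) + 1e-9)))
  y0 <- max(0L, as.integer(ceiling(min(v[, 2L]) - 1e-9)))
  y1 <- min(height - 1L, as.integer(floor(max(v[, 2L]) + 1e-9)))
  if (x0 > x1 || y0 > y1) return(integer(0))
  px <- rep(x0:x1, each = y1 - y0 + 1L)
  py <- rep(y0:y1, times = x1 - x0 + 1L)
  s <- sign(area2)
  edge <- function(a, b) s * ((v[b, 1L] - v[a, 1L]) * (py - v[a, 2L]) -
                                (v[b, 2L] - v[a, 2L]) * (px - v[a, 1L]))
  tol <- 1e-9
  inside <- edge(1L, 2L) >= -tol & edge(2L, 3L) >= -tol & edge(3L, 1L) >= -tol
  (py[inside] + 1L) + (px[inside]) * height
}

## rasterize every triangle of a set at given landmark positions
rasterize_rois <- function(triangles, points, height, width) {
  lapply(seq_len(nrow(triangles)), function(k) {
    v <- points[c(triangles$v1[k], triangles$v2[k], triangles$v3[k]), ,
                drop = FALSE]
    rasterize_triangle(v, height, width)
  })
}

## run expr under a fixed RNG seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Keep well-lit triangles by chrominance clustering
#'
#' Computes each candidate triangle's temporal-mean RGB over the original
#' (non-magnified) video, converts it to zero-centred YUV chrominance
#' (BT.601, `[0, 255]` scale), clusters the (U, V) pairs with 2-means, and
#' retains the cluster whose centroid is Euclidean-nearest to the reference
#' chrominance of well-lit skin. With fewer than two candidates, or when the
#' two centroids are equidistant from the reference (tie), all candidates are
#' retained.
#'
#' @param candidates a `triangle_rois` data frame (from [filter_anatomical]).
#' @param video the original (stabilized, non-magnified) [frame_sequence];
#'   triangles are rasterized at the canonical landmark positions.
#' @param reference_uv reference chrominance of well-lit skin, default
#'   `c(30, 45)`.
#' @param seed RNG seed for the K-means initialisation (restored afterwards).
#' @param nstart K-means restarts.
#' @return `candidates` with `retained` updated and columns `mean_r/g/b`,
#'   `u`, `v` added; clustering details in attribute `chrominance`.
#' @export
chrominance_filter <- function(candidates, video, reference_uv = c(30, 45),
                               seed = 1L, nstart = 10L) {
  stopifnot(inherits(video, "frame_sequence"))
  pts <- attr(candidates, "points")
  pix <- rasterize_rois(candidates, pts, video$height, video$width)
  npx <- lengths(pix)
  if (any(npx == 0L))
    stop("empty rasterization: a candidate triangle covers no pixel",
         call. = FALSE)
  allidx <- unlist(pix)
  grp <- rep.int(seq_along(pix), npx)
  acc <- matrix(0, nrow(candidates), 3L)
  for (fr in video$frames) {
    for (c in 1:3)
      acc[, c] <- acc[, c] + rowsum(fr[, , c][allidx], grp)[, 1L]
  }
  mean_rgb <- acc / (npx * video$frame_count) * 255
  yuv <- rgb_to_yuv(mean_rgb)
  uv <- yuv[, c("U", "V"), drop = FALSE]

  candidates$mean_r <- mean_rgb[, 1L]
  candidates$mean_g <- mean_rgb[, 2L]
  candidates$mean_b <- mean_rgb[, 3L]
  candidates$u <- uv[, 1L]
  candidates$v <- uv[, 2L]

  if (nrow(candidates) < 2L) {
    warning("fewer than 2 candidate triangles; skipping chrominance clustering")
    candidates$retained <- TRUE
    return(candidates)
  }
  km <- tryCatch(
    with_preserved_seed(seed, stats::kmeans(uv, centers = 2L, nstart = nstart)),
    error = function(e) NULL
  )
  if (is.null(km)) {           # degenerate input (all UV identical)
    candidates$retained <- TRUE
    attr(candidates, "chrominance") <- list(degenerate = TRUE)
    return(candidates)
  }
  d <- sqrt(rowSums(sweep(km$centers, 2L, reference_uv)^2))
  if (abs(d[1L] - d[2L]) < 1e-9) {
    candidates$retained <- TRUE                    # tie: fail open
  } else {
    candidates$retained <- km$cluster == which.min(d)
  }
  attr(candidates, "chrominance") <- list(
    centers = km$centers, cluster = km$cluster, dist_to_reference = d,
    reference_uv = reference_uv, degenerate = FALSE)
  attr(candidates, "points") <- pts
  candidates
}

#' Spatial ordering of retained triangles for trace extraction
#'
#' Orders triangles forehead first, then left cheek, then right cheek;
#' within a region, by canonical-space rows top to bottom and left to right.
#' This defines the spatial adjacency that the sliding-window PCA exploits.
#'
#' @param triangles a `triangle_rois` data frame with `region` filled.
#' @return `triangles`, reordered.
#' @export
order_triangles <- function(triangles) {
  rank <- match(triangles$region, c("forehead", "left_cheek", "right_cheek"))
  ord <- order(rank, round(triangles$cy, 3L), triangles$cx)
  out <- triangles[ord, , drop = FALSE]
  attr(out, "points") <- attr(triangles, "points")
  class(out) <- class(triangles)
  out
}
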