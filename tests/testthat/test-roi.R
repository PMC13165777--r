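test_that("tessellation computes centroids and validates the topology", {
  pts <- rbind(c(0, 0), c(2, 0), c(0, 2))
  t1 <- tessellate(pts, matrix(c(1, 2, 3), 1))
  expect_equal(c(t1$cx, t1$cy), c(2 / 3, 2 / 3))

  tpl <- face_mesh_template()
  full <- tessellate(as_canonical(tpl$points), tpl$triangles)
  for (k in c(1, 100, nrow(full))) {
    vx <- tpl$points[unlist(full[k, c("v1", "v2", "v3")]), 1]
    vy <- tpl$points[unlist(full[k, c("v1", "v2", "v3")]), 2]
    expect_gte(full$cx[k], min(vx)); expect_lte(full$cx[k], max(vx))
    expect_gte(full$cy[k], min(vy)); expect_lte(full$cy[k], max(vy))
  }

  expect_error(tessellate(pts, matrix(c(1, 2, 4), 1)), "out of range")
  expect_error(tessellate(pts, matrix(c(1, 1, 2), 1)), "duplicate")
})

test_that("point-in-polygon is even-odd with inclusive boundaries", {
  sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  expect_true(point_in_polygon(2, 2, sq))
  expect_false(point_in_polygon(5, 2, sq))
  ## boundary counts as inside; cross-check against half-plane containment
  edge_pts <- rbind(c(4, 2), c(2, 0), c(0, 0), c(4, 4))
  for (i in seq_len(nrow(edge_pts))) {
    p <- edge_pts[i, ]
    halfplane <- all(p >= 0) && all(p <= 4)
    expect_identical(point_in_polygon(p[1], p[2], sq), halfplane)
  }
  ## self-intersecting polygons are rejected
  bow <- rbind(c(0, 0), c(4, 4), c(4, 0), c(0, 4))
  tri <- tessellate(rbind(c(1, 1), c(2, 1), c(1, 2)), matrix(1:3, 1))
  expect_error(filter_anatomical(tri, list(bad = bow)), "self-intersecting")
})

test_that("anatomical filtering keeps only forehead/cheek centroids", {
  tpl <- face_mesh_template()
  tris <- tessellate(as_canonical(tpl$points))
  cand <- filter_anatomical(tris)
  expect_true(all(cand$region %in% c("forehead", "left_cheek", "right_cheek")))
  expect_true(all(cand$id %in% tris$id))
  ## every candidate centroid really lies in its tagged polygon
  for (nm in unique(cand$region)) {
    poly <- tpl$points[tpl$polygons[[nm]], ]
    sub <- cand[cand$region == nm, ]
    expect_true(all(point_in_polygon(sub$cx, sub$cy, poly)))
  }
  ## and discarded centroids lie in none
  out <- tris[!tris$id %in% cand$id, ]
  hit <- rep(FALSE, nrow(out))
  for (nm in names(tpl$polygons))
    hit <- hit | point_in_polygon(out$cx, out$cy, tpl$points[tpl$polygons[[nm]], ])
  expect_false(any(hit))
})

test_that("triangle rasterization matches a brute-force scan and clips", {
  brute <- function(v, H, W) {
    hits <- integer(0)
    for (x in 0:(W - 1)) for (y in 0:(H - 1)) {
      ## half-plane containment with inclusive edges
      s <- function(a, b) (v[b, 1] - v[a, 1]) * (y - v[a, 2]) -
        (v[b, 2] - v[a, 2]) * (x - v[a, 1])
      d1 <- s(1, 2); d2 <- s(2, 3); d3 <- s(3, 1)
      if ((d1 >= -1e-9 && d2 >= -1e-9 && d3 >= -1e-9) ||
            (d1 <= 1e-9 && d2 <= 1e-9 && d3 <= 1e-9))
        hits <- c(hits, (y + 1) + x * H)
    }
    sort(hits)
  }
  v <- rbind(c(0, 0), c(4, 0), c(0, 4))
  expect_identical(sort(rasterize_triangle(v, 8, 8)), brute(v, 8, 8))

  set.seed(7)
  for (i in 1:10) {
    v <- matrix(runif(6, 0, 10), 3)
    expect_identical(sort(rasterize_triangle(v, 12, 12)), brute(v, 12, 12))
  }

  ## zero-area triangle
  expect_length(rasterize_triangle(rbind(c(1, 1), c(3, 3), c(2, 2)), 8, 8), 0)

  ## off-frame part is clipped
  v2 <- rbind(c(-5, -5), c(3, 0), c(0, 3))
  idx <- rasterize_triangle(v2, 8, 8)
  expect_true(all(idx >= 1 & idx <= 64))
  expect_identical(sort(idx), brute(v2, 8, 8))
})

## six disjoint triangles painted with two colours -> exact 2-means oracle
make_colour_rois <- function(cols) {
  pts <- NULL; topo <- NULL
  for (k in seq_along(cols)) {
    x0 <- 2 + (k - 1) * 6
    pts <- rbind(pts, c(x0, 2), c(x0 + 4, 2), c(x0, 6))
    topo <- rbind(topo, (k - 1) * 3 + 1:3)
  }
  tris <- tessellate(pts, topo)
  tris$region <- "forehead"
  fr <- array(0, c(10, 40, 3))
  for (k in seq_along(cols)) {
    idx <- rasterize_triangle(pts[(k - 1) * 3 + 1:3, ], 10, 40)
    for (c in 1:3) {
      ch <- fr[, , c]; ch[idx] <- cols[[k]][c]; fr[, , c] <- ch
    }
  }
  list(tris = tris, video = frame_sequence(list(fr, fr), 20))
}

exhaustive_2means <- function(uv) {
  n <- nrow(uv); best <- NULL; best_ss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    if (length(unique(grp)) < 2) next
    ss <- 0
    for (g in 0:1) {
      m <- colMeans(uv[grp == g, , drop = FALSE])
      ss <- ss + sum(sweep(uv[grp == g, , drop = FALSE], 2, m)^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- grp }
  }
  best
}

test_that("chrominance filter equals the exhaustive 2-means oracle", {
  ## colours: four light-skin-like, two dark bluish
  lit <- list(c(0.85, 0.55, 0.50), c(0.83, 0.56, 0.49),
              c(0.86, 0.54, 0.52), c(0.84, 0.57, 0.50))
  dark <- list(c(0.25, 0.28, 0.38), c(0.22, 0.30, 0.40))
  mk <- make_colour_rois(c(lit, dark))
  out <- chrominance_filter(mk$tris, mk$video, seed = 1)
  uv <- cbind(out$u, out$v)
  oracle <- exhaustive_2means(uv)
  ## oracle partition, relabelled so the retained group is the one whose
  ## centroid is nearer the reference chrominance
  d0 <- sqrt(sum((colMeans(uv[oracle == 0, , drop = FALSE]) - c(30, 45))^2))
  d1 <- sqrt(sum((colMeans(uv[oracle == 1, , drop = FALSE]) - c(30, 45))^2))
  keep_oracle <- oracle == (if (d1 < d0) 1 else 0)
  expect_identical(out$retained, keep_oracle)
  expect_identical(which(out$retained), 1:4)

  ## determinism under a fixed seed
  out2 <- chrominance_filter(mk$tris, mk$video, seed = 1)
  expect_identical(out$retained, out2$retained)

  ## identical chrominance everywhere: degenerate clustering retains all
  same <- make_colour_rois(rep(list(c(0.8, 0.5, 0.45)), 4))
  all_same <- chrominance_filter(same$tris, same$video)
  expect_true(all(all_same$retained))

  ## fewer than two candidates: retain with a warning
  single <- make_colour_rois(list(c(0.8, 0.5, 0.45)))
  expect_warning(one <- chrominance_filter(single$tris, single$video),
                 "fewer than 2")
  expect_true(all(one$retained))
})

test_that("shadowed-cheek triangles are discarded on the synthetic scene", {
  sc <- study_scene()
  track <- detect_landmarks(sc$video, landmark_provider_synthetic(sc$truth))
  st <- stabilize_video(sc$video, track)
  cand <- filter_anatomical(tessellate(st$canonical))
  out <- chrominance_filter(cand, st$video)
  shadowed <- out$id %in% sc$truth$shadow_triangle_ids
  ## retained set is a subset of the candidates and excludes the shadow
  expect_true(all(out$id %in% cand$id))
  expect_equal(sum(out$retained & shadowed), 0)
  ## the vast majority of lit triangles survive
  expect_gte(mean(out$retained[!shadowed]), 0.9)
})

test_that("triangle ordering is by region then canonical row", {
  tpl <- face_mesh_template()
  cand <- filter_anatomical(tessellate(as_canonical(tpl$points)))
  ord <- order_triangles(cand)
  reg <- match(ord$region, c("forehead", "left_cheek", "right_cheek"))
  expect_true(all(diff(reg) >= 0))
  within <- split(seq_len(nrow(ord)), reg)
  for (idx in within) {
    ro <- round(ord$cy[idx], 3)
    expect_true(all(diff(ro) >= 0))
  }
})
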