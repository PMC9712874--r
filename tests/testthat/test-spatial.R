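axial_geom <- function(spacing = c(1, 1), position = c(0, 0, 0),
                       system = "PATIENT") {
  plane_geometry(position, row_direction = c(0, 1, 0),
                 col_direction = c(1, 0, 0), pixel_spacing = spacing,
                 coordinate_system = system)
}

rotated_geom <- function(theta, spacing = c(0.5, 0.25),
                         position = c(10, -5, 3)) {
  plane_geometry(position,
                 row_direction = c(-sin(theta), cos(theta), 0),
                 col_direction = c(cos(theta), sin(theta), 0),
                 pixel_spacing = spacing)
}

test_that("the affine maps indices to mm per the plane equation", {
  g <- axial_geom()
  m <- build_affine(g)
  expect_equal(as.numeric(m %*% c(0, 0, 0, 1))[1:3], c(0, 0, 0))
  expect_equal(as.numeric(m %*% c(3, 4, 0, 1))[1:3], c(3, 4, 0))
  # rotated geometry vs an explicit matrix-product oracle
  th <- pi / 2
  g2 <- rotated_geom(th)
  m2 <- build_affine(g2)
  set.seed(5)
  for (i in 1:20) {
    idx <- stats::runif(2, 0, 50)
    oracle <- g2$position + idx[1] * g2$pixel_spacing[2] * g2$col_direction +
      idx[2] * g2$pixel_spacing[1] * g2$row_direction
    expect_equal(as.numeric(m2 %*% c(idx, 0, 1))[1:3], oracle, tolerance = 1e-12)
  }
  expect_error(plane_geometry(c(0, 0, 0), c(0, 2, 0), c(1, 0, 0), c(1, 1)),
               "unit")
  expect_error(plane_geometry(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1)),
               "orthogonal")
})

test_that("pixel<->reference round-trip is exact within 1e-6 mm", {
  set.seed(7)
  geoms <- list(axial_geom(), axial_geom(c(0.25, 0.5), c(-3, 2, 7)),
                rotated_geom(0.3), rotated_geom(pi / 2),
                axial_geom(c(0.001, 0.001), system = "SLIDE"))
  for (g in geoms) {
    idx <- cbind(stats::runif(100, 0, 512), stats::runif(100, 0, 512))
    back <- reference_to_pixel(pixel_to_reference(idx, g), g)
    expect_lt(max(abs(back - idx)), 1e-6)
  }
})

test_that("out-of-plane points are rejected with the reported distance", {
  g <- axial_geom()
  p <- pixel_to_reference(c(5, 5), g) + c(0, 0, 5)  # 5 mm along the normal
  expect_error(reference_to_pixel(p, g, tolerance_mm = 1), "5.*mm")
  projected <- reference_to_pixel(p, g, tolerance_mm = 10)
  expect_equal(as.numeric(projected), c(5, 5), tolerance = 1e-9)
})

test_that("polygon area matches closed forms and the fan-triangulation oracle", {
  g <- axial_geom()
  square <- pixel_to_reference(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0)), g)
  expect_equal(polygon_area_mm2(square), 1.0, tolerance = 1e-12)
  clockwise <- square[c(1, 4, 3, 2, 1), ]
  expect_equal(polygon_area_mm2(clockwise), polygon_area_mm2(square))
  # random convex hexagons vs fan triangulation
  set.seed(21)
  for (i in 1:10) {
    ang <- sort(stats::runif(6, 0, 2 * pi))
    r <- stats::runif(1, 1, 20)
    ring2d <- cbind(r * cos(ang), r * sin(ang))
    ring <- pixel_to_reference(ring2d, g)
    ring <- rbind(ring, ring[1, ])
    v0 <- ring[1, ]
    fan <- 0
    for (k in 2:(nrow(ring) - 2)) {
      a <- ring[k, ] - v0; b <- ring[k + 1, ] - v0
      cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
              a[1] * b[2] - a[2] * b[1])
      fan <- fan + sqrt(sum(cr^2)) / 2
    }
    expect_lt(abs(polygon_area_mm2(ring) - fan), 1e-9)
  }
  expect_error(polygon_area_mm2(square[1:4, ]), "closed")
  expect_error(polygon_area_mm2(rbind(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0))),
               "degenerate")
  bent <- square; bent[2, 3] <- 2
  expect_error(polygon_area_mm2(bent), "closed|non-planar")
})

test_that("area is invariant under in-plane rigid motions", {
  set.seed(3)
  base <- rbind(c(0, 0), c(4, 0), c(4, 2), c(1, 3), c(0, 0))
  g0 <- axial_geom()
  a0 <- polygon_area_mm2(pixel_to_reference(base, g0))
  for (i in 1:8) {
    th <- stats::runif(1, 0, 2 * pi)
    shift <- stats::runif(2, -10, 10)
    rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    moved <- sweep(base %*% rot, 2, -shift)
    expect_equal(polygon_area_mm2(pixel_to_reference(moved, g0)), a0,
                 tolerance = 1e-9)
  }
})

test_that("conversion agrees across rotated encodings of the same plane", {
  # the same physical pixel grid described with a 90-degree-rotated basis:
  # index (c, r) in g0 corresponds to index (r, -c) in g90
  g0 <- axial_geom(c(0.5, 0.5), position = c(0, 0, 0))
  g90 <- plane_geometry(c(0, 0, 0),
                        row_direction = c(-1, 0, 0),
                        col_direction = c(0, 1, 0),
                        pixel_spacing = c(0.5, 0.5))
  set.seed(13)
  for (i in 1:20) {
    idx <- stats::runif(2, -20, 20)
    p0 <- pixel_to_reference(idx, g0)
    p90 <- pixel_to_reference(c(idx[2], -idx[1]), g90)
    expect_equal(as.numeric(p0), as.numeric(p90), tolerance = 1e-9)
  }
})

test_that("bounding boxes are tight, planar, closed and idempotent", {
  g <- axial_geom(c(0.5, 0.5))
  pts_px <- rbind(c(2, 3), c(10, 4), c(6, 12), c(3, 3))
  pts <- pixel_to_reference(pts_px, g)
  box <- bounding_box_3d(pts, g)
  expect_identical(dim(box), c(5L, 3L))
  expect_equal(box[1, ], box[5, ])
  idx <- reference_to_pixel(box, g)
  expect_equal(min(idx[, 1]), 2)
  expect_equal(max(idx[, 1]), 10)
  expect_equal(min(idx[, 2]), 3)
  expect_equal(max(idx[, 2]), 12)
  # idempotence: box of a box is itself
  box2 <- bounding_box_3d(box, g)
  expect_equal(sort(box2[1:4, 1]), sort(box[1:4, 1]), tolerance = 1e-9)
  expect_equal(sort(box2[1:4, 2]), sort(box[1:4, 2]), tolerance = 1e-9)
  # degenerate single point expands to one pixel's extent
  single <- bounding_box_3d(pixel_to_reference(c(4, 4), g), g)
  idx1 <- reference_to_pixel(single, g)
  expect_equal(max(idx1[, 1]) - min(idx1[, 1]), 1)
  expect_equal(max(idx1[, 2]) - min(idx1[, 2]), 1)
  expect_error(bounding_box_3d(matrix(numeric(0), ncol = 3), g), "at least one")
})
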