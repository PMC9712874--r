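#' Plane geometry: the affine link between pixels and the frame of reference
#'
#' Describes one image plane in the 3D frame of reference (patient-based in
#' radiology, slide-based in pathology): the mm position of the *center of
#' the top-left pixel*, unit direction cosines along increasing rows and
#' columns, and the pixel spacing. Pixel indices are `(column, row)`,
#' 0-based, at pixel centers, throughout the package.
#'
#' @param position numeric 3-vector, mm coordinates of the top-left pixel
#'   center.
#' @param row_direction,col_direction unit 3-vectors: direction of
#'   increasing row index / column index.
#' @param pixel_spacing numeric 2-vector `(between-rows mm, between-columns
#'   mm)`, both positive.
#' @param coordinate_system `"PATIENT"` or `"SLIDE"`.
#' @return an object of class `plane_geometry`.
#' @export
plane_geometry <- function(position, row_direction, col_direction,
                           pixel_spacing, coordinate_system = c("PATIENT", "SLIDE")) {
  coordinate_system <- match.arg(coordinate_system)
  position <- as.numeric(position)
  row_direction <- as.numeric(row_direction)
  col_direction <- as.numeric(col_direction)
  pixel_spacing <- as.numeric(pixel_spacing)
  stopifnot(length(position) == 3, length(row_direction) == 3,
            length(col_direction) == 3, length(pixel_spacing) == 2)
  if (any(pixel_spacing <= 0)) stop("pixel spacings must be positive", call. = FALSE)
  if (abs(sqrt(sum(row_direction^2)) - 1) > 1e-6 ||
      abs(sqrt(sum(col_direction^2)) - 1) > 1e-6) {
    stop("direction cosines must be unit vectors", call. = FALSE)
  }
  if (abs(sum(row_direction * col_direction)) > 1e-6) {
    stop("row and column directions must be orthogonal", call. = FALSE)
  }
  structure(list(position = position, row_direction = row_direction,
                 col_direction = col_direction, pixel_spacing = pixel_spacing,
                 coordinate_system = coordinate_system),
            class = "plane_geometry")
}

plane_normal <- function(geometry) {
  r <- geometry$row_direction; c <- geometry$col_direction
  # cross product col x row gives the plane normal
  c(c[2] * r[3] - c[3] * r[2],
    c[3] * r[1] - c[1] * r[3],
    c[1] * r[2] - c[2] * r[1])
}

#' Build the 4x4 affine matrix of a plane geometry
#'
#' Maps homogeneous pixel indices `(column, row, 0, 1)` to frame-of-reference
#' coordinates `(x, y, z, 1)` in mm; index `(0, 0)` maps to the geometry's
#' position.
#'
#' @param geometry a [plane_geometry()].
#' @return a 4x4 numeric matrix.
#' @export
build_affine <- function(geometry) {
  stopifnot(inherits(geometry, "plane_geometry"))
  dr <- geometry$pixel_spacing[1]; dc <- geometry$pixel_spacing[2]
  m <- cbind(geometry$col_direction * dc,
             geometry$row_direction * dr,
             plane_normal(geometry),
             geometry$position)
  rbind(m, c(0, 0, 0, 1))
}

as_index_matrix <- function(indices) {
  if (is.null(dim(indices))) indices <- matrix(indices, ncol = 2, byrow = TRUE)
  stopifnot(ncol(indices) == 2, all(is.finite(indices)))
  indices
}

as_coord_matrix <- function(coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)))
  coords
}

#' Convert pixel indices to frame-of-reference coordinates
#'
#' @param indices N x 2 matrix of `(column, row)` indices (0-based, pixel
#'   centers; fractional values allowed).
#' @inheritParams build_affine
#' @return N x 3 matrix of mm coordinates.
#' @export
pixel_to_reference <- function(indices, geometry) {
  indices <- as_index_matrix(indices)
  m <- build_affine(geometry)
  h <- cbind(indices[, 1], indices[, 2], 0, 1)
  out <- h %*% t(m)
  out[, 1:3, drop = FALSE]
}

#' Convert frame-of-reference coordinates to pixel indices
#'
#' Points are orthogonally projected onto the image plane; a point whose
#' distance from the plane exceeds `tolerance_mm` is rejected. Returned
#' indices are fractional; rounding is the caller's concern.
#'
#' @param coords N x 3 matrix of mm coordinates.
#' @inheritParams build_affine
#' @param tolerance_mm maximum tolerated out-of-plane distance; default half
#'   the smaller pixel spacing.
#' @return N x 2 matrix of `(column, row)` indices.
#' @export
reference_to_pixel <- function(coords, geometry,
                               tolerance_mm = min(geometry$pixel_spacing) / 2) {
  coords <- as_coord_matrix(coords)
  stopifnot(inherits(geometry, "plane_geometry"))
  d <- sweep(coords, 2, geometry$position)
  dist <- as.numeric(d %*% plane_normal(geometry))
  if (any(abs(dist) > tolerance_mm)) {
    bad <- which.max(abs(dist))
    stop(sprintf("point %d lies %.6g mm off the image plane (tolerance %.6g mm)",
                 bad, abs(dist[bad]), tolerance_mm), call. = FALSE)
  }
  col_idx <- as.numeric(d %*% geometry$col_direction) / geometry$pixel_spacing[2]
  row_idx <- as.numeric(d %*% geometry$row_direction) / geometry$pixel_spacing[1]
  cbind(col_idx, row_idx, deparse.level = 0)
}

#' Area of a closed planar polygon, in mm^2
#'
#' Computes the area of a closed planar ring in 3D via the magnitude of the
#' summed cross products (Newell's method), equivalent to the shoelace
#' formula evaluated in the plane's 2D basis. Orientation-independent.
#'
#' @param ring N x 3 matrix of mm coordinates; first vertex equal to last
#'   (closed), all vertices coplanar.
#' @param planarity_tol_mm maximum tolerated deviation from the best-fit
#'   plane.
#' @return area in mm^2.
#' @export
polygon_area_mm2 <- function(ring, planarity_tol_mm = 1e-6) {
  ring <- as_coord_matrix(ring)
  if (nrow(ring) < 2 || any(ring[1, ] != ring[nrow(ring), ])) {
    stop("ring must be closed (first vertex repeated last)", call. = FALSE)
  }
  v <- ring[-nrow(ring), , drop = FALSE]
  if (nrow(unique(v)) < 3) stop("polygon is degenerate (<3 distinct vertices)",
                                call. = FALSE)
  n_vec <- c(0, 0, 0)
  n <- nrow(v)
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[i %% n + 1, ]
    n_vec <- n_vec + c(a[2] * b[3] - a[3] * b[2],
                       a[3] * b[1] - a[1] * b[3],
                       a[1] * b[2] - a[2] * b[1])
  }
  norm <- sqrt(sum(n_vec^2))
  # planarity: distance of vertices to the best-fit plane through centroid
  if (norm > 0) {
    unit_n <- n_vec / norm
    centroid <- colMeans(v)
    dev <- abs(sweep(v, 2, centroid) %*% unit_n)
    if (max(dev) > planarity_tol_mm) {
      stop(sprintf("ring is non-planar: max deviation %.3g mm", max(dev)),
           call. = FALSE)
    }
  }
  norm / 2
}

#' Axis-aligned bounding box of in-plane points, as a closed 3D ring
#'
#' The box is axis-aligned in the plane's pixel basis: points are converted
#' to pixel indices, the index-space min/max rectangle is taken, and its
#' corners are mapped back to mm. A single point (or collinear points)
#' yields a degenerate box expanded to one pixel's extent. The first vertex
#' is repeated last, giving a 5-point POLYGON ring.
#'
#' @param points N x 3 matrix of mm coordinates, all in-plane for `geometry`.
#' @inheritParams reference_to_pixel
#' @return 5 x 3 matrix: closed rectangle ring in mm.
#' @export
bounding_box_3d <- function(points, geometry,
                            tolerance_mm = min(geometry$pixel_spacing) / 2) {
  points <- as_coord_matrix(points)
  if (nrow(points) == 0) stop("at least one point required", call. = FALSE)
  idx <- reference_to_pixel(points, geometry, tolerance_mm = tolerance_mm)
  c0 <- min(idx[, 1]); c1 <- max(idx[, 1])
  r0 <- min(idx[, 2]); r1 <- max(idx[, 2])
  if (c1 - c0 < 1e-9) c1 <- c0 + 1
  if (r1 - r0 < 1e-9) r1 <- r0 + 1
  corners <- rbind(c(c0, r0), c(c1, r0), c(c1, r1), c(c0, r1), c(c0, r0))
  pixel_to_reference(corners, geometry)
}

#' Plane geometry of a source image dataset
#'
#' Reads the plane position/orientation/spacing of a patient-based image
#' (Image Position/Orientation Patient) or a tiled slide image (total pixel
#' matrix origin and slide orientation) into a [plane_geometry()].
#'
#' @param ds a source image `dcm_dataset`.
#' @return a `plane_geometry`.
#' @export
geometry_from_dataset <- function(ds) {
  if (ds_has(ds, "ImageOrientationPatient")) {
    iop <- ds_get(ds, "ImageOrientationPatient")
    spacing <- ds_get(ds, "PixelSpacing")
    plane_geometry(position = ds_get(ds, "ImagePositionPatient"),
                   row_direction = iop[4:6], col_direction = iop[1:3],
                   pixel_spacing = spacing, coordinate_system = "PATIENT")
  } else if (ds_has(ds, "ImageOrientationSlide")) {
    ios <- ds_get(ds, "ImageOrientationSlide")
    shared <- ds_get(ds, "SharedFunctionalGroupsSequence")
    spacing <- ds_get(ds_get(shared[[1]], "PixelMeasuresSequence")[[1]],
                      "PixelSpacing")
    origin <- ds_get(ds, "TotalPixelMatrixOriginSequence")[[1]]
    pos <- c(ds_get(origin, "XOffsetInSlideCoordinateSystem"),
             ds_get(origin, "YOffsetInSlideCoordinateSystem"),
             ds_get(origin, "ZOffsetInSlideCoordinateSystem", 0))
    plane_geometry(position = pos,
                   row_direction = ios[4:6], col_direction = ios[1:3],
                   pixel_spacing = spacing, coordinate_system = "SLIDE")
  } else {
    stop("dataset carries no plane orientation", call. = FALSE)
  }
}
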