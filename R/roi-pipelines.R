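# ROI post-processing pipelines: probability maps -> fractional
# Segmentation; thresholded masks -> connected components -> border
# following -> bounding boxes -> Comprehensive 3D SR.

#' A detected region of interest
#'
#' @param contour closed pixel-index ring, N x 2 `(column, row)`, first
#'   point repeated last.
#' @param bounding_box numeric vector `c(col0, row0, col1, row1)` (tight,
#'   inclusive pixel indices); must contain the contour.
#' @param class_label optional [coded_concept()].
#' @param score optional detection score in `[0, 1]`.
#' @param n_pixels component size in pixels.
#' @return object of class `detected_roi`.
#' @export
detected_roi <- function(contour, bounding_box, class_label = NULL,
                         score = NULL, n_pixels = NA_integer_) {
  contour <- as_index_matrix(contour)
  stopifnot(length(bounding_box) == 4)
  if (any(contour[, 1] < bounding_box[1] - 1e-9) ||
      any(contour[, 1] > bounding_box[3] + 1e-9) ||
      any(contour[, 2] < bounding_box[2] - 1e-9) ||
      any(contour[, 2] > bounding_box[4] + 1e-9)) {
    stop("bounding box does not contain the contour", call. = FALSE)
  }
  if (!is.null(score)) stopifnot(is.finite(score), score >= 0, score <= 1)
  if (!is.null(class_label)) stopifnot(inherits(class_label, "coded_concept"))
  structure(list(contour = contour, bounding_box = as.numeric(bounding_box),
                 class_label = class_label, score = score,
                 n_pixels = n_pixels),
            class = "detected_roi")
}

# connected-component labeling, 4- or 8-connectivity, BFS
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    off <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    off <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))
  }
  current <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (k in seq_len(nrow(off))) {
        rr <- r + off[k, 1]; cc <- c + off[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] && labels[q] == 0L) {
            labels[q] <- current
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

# Moore-neighbor border following with Jacob's stopping criterion.
# Returns the outer contour as a closed (col, row) 0-based pixel ring,
# traced counter-clockwise from the top-most then left-most border pixel.
trace_contour <- function(component, connectivity = 8) {
  nr <- nrow(component); nc <- ncol(component)
  fg <- which(component, arr.ind = TRUE)
  start <- fg[order(fg[, 1], fg[, 2]), , drop = FALSE][1, ]
  # scan order around a pixel, counter-clockwise, starting west:
  dirs <- rbind(c(0, -1), c(1, -1), c(1, 0), c(1, 1),
                c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && component[r, c]
  p <- start
  backtrack_dir <- 1L  # direction from p to the backtrack pixel (west)
  ring <- list(p)
  first_move <- NA_integer_
  for (iter in seq_len(8 * length(fg) + 8)) {
    found <- FALSE
    for (step in 0:7) {
      d <- (backtrack_dir - 1L + step) %% 8L + 1L
      rr <- p[1] + dirs[d, 1]; cc <- p[2] + dirs[d, 2]
      if (inside(rr, cc)) {
        if (is.na(first_move)) first_move <- d
        else if (all(c(rr, cc) == start) && length(ring) > 1) {
          # entering the start again: Jacob's criterion
          nxt <- c(rr, cc)
          if (d == first_move) {
            found <- FALSE
          } else {
            ring[[length(ring) + 1]] <- nxt
            p <- nxt
            backtrack_dir <- (d - 1L + 6L) %% 8L + 1L
            found <- TRUE
          }
          break
        }
        ring[[length(ring) + 1]] <- c(rr, cc)
        p <- c(rr, cc)
        # new backtrack: the last background pixel examined, i.e. d - 1
        backtrack_dir <- (d - 1L + 6L) %% 8L + 1L
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  # drop trailing duplicate start entries, then close the ring
  coords <- do.call(rbind, ring)
  while (nrow(coords) > 1 && all(coords[nrow(coords), ] == coords[1, ])) {
    coords <- coords[-nrow(coords), , drop = FALSE]
  }
  coords <- rbind(coords, coords[1, ])
  # (row, col) 1-based -> (col, row) 0-based
  cbind(coords[, 2] - 1, coords[, 1] - 1, deparse.level = 0)
}

#' Extract ROIs from a binary mask
#'
#' Performs connected-component analysis and border following: one ROI per
#' component, with the component's outer border as a closed
#' counter-clockwise pixel ring (holes are ignored) and a tight bounding
#' box. ROIs are sorted by box top-left (row, then column).
#'
#' @param binary_mask logical or 0/1 matrix `(rows, cols)`.
#' @param connectivity pixel connectivity for components, 4 or 8
#'   (default 8, with the complementary convention for background).
#' @return list of [detected_roi()]s (empty for an empty mask).
#' @export
extract_rois <- function(binary_mask, connectivity = 8) {
  stopifnot(is.matrix(binary_mask))
  labels <- label_components(binary_mask, connectivity)
  n <- max(labels)
  if (n == 0) return(list())
  rois <- lapply(seq_len(n), function(k) {
    comp <- labels == k
    px <- which(comp, arr.ind = TRUE)
    box <- c(min(px[, 2]) - 1, min(px[, 1]) - 1,
             max(px[, 2]) - 1, max(px[, 1]) - 1)  # col0,row0,col1,row1 0-based
    detected_roi(contour = trace_contour(comp, connectivity),
                 bounding_box = box, n_pixels = nrow(px))
  })
  ord <- order(vapply(rois, function(r) r$bounding_box[2], numeric(1)),
               vapply(rois, function(r) r$bounding_box[1], numeric(1)))
  rois[ord]
}

#' Threshold a probability map into a binary mask
#'
#' @param prob_map numeric matrix/array of probabilities in `[0, 1]`.
#' @param threshold inclusion threshold; pixels with `p >= threshold` are
#'   foreground. Default 0.5.
#' @return logical object of the same shape.
#' @export
threshold_probabilities <- function(prob_map, threshold = 0.5) {
  stopifnot(is.numeric(prob_map), threshold >= 0, threshold <= 1)
  prob_map >= threshold
}

#' Encode per-class probability maps as a FRACTIONAL/PROBABILITY Segmentation
#'
#' One segment per class concept; values are quantized to
#' `0..max_fractional_value` by [encode_segmentation()].
#'
#' @param prob_maps list (one per class) of `(frames, rows, cols)` arrays
#'   of probabilities in `[0, 1]`, or a single `(frames, rows, cols,
#'   classes)` array.
#' @param source_images source image datasets (see
#'   [encode_segmentation()]).
#' @param class_concepts list of [coded_concept()]s, one per class.
#' @param property_category coded category shared by all segments.
#' @param max_fractional_value quantization ceiling (default 255).
#' @param omit_empty_frames drop all-background frames.
#' @param algorithm_name name recorded as the generating algorithm.
#' @return a Segmentation `dcm_dataset`.
#' @export
probabilities_to_seg <- function(prob_maps, source_images, class_concepts,
                                 property_category = registry_lookup("SCT", "BodyStructure"),
                                 max_fractional_value = 255L,
                                 omit_empty_frames = TRUE,
                                 algorithm_name = "classifier") {
  if (is.list(prob_maps)) {
    stopifnot(length(prob_maps) == length(class_concepts))
    d <- dim(prob_maps[[1]])
    if (length(d) == 2) d <- c(1, d)
    arr <- array(0, c(d, length(prob_maps)))
    for (k in seq_along(prob_maps)) {
      m <- prob_maps[[k]]
      if (length(dim(m)) == 2) m <- array(m, c(1, dim(m)))
      arr[, , , k] <- m
    }
  } else {
    arr <- prob_maps
    if (length(dim(arr)) == 3) arr <- array(arr, c(dim(arr), 1))
    stopifnot(dim(arr)[4] == length(class_concepts))
  }
  storage.mode(arr) <- "double"
  descriptions <- lapply(seq_along(class_concepts), function(k) {
    segment_description(
      segment_number = k, label = class_concepts[[k]]$meaning,
      property_category = property_category,
      property_type = class_concepts[[k]],
      algorithm_type = "AUTOMATIC",
      algorithm_identification = list(name = algorithm_name))
  })
  params <- segmentation_params("FRACTIONAL", fractional_type = "PROBABILITY",
                                max_fractional_value = max_fractional_value,
                                omit_empty_frames = omit_empty_frames)
  encode_segmentation(arr, source_images, descriptions, params)
}

#' Encode detected ROIs as a Comprehensive 3D SR document
#'
#' One measurement group per ROI: the bounding box as an SCOORD3D POLYGON
#' (pixel corners mapped to frame-of-reference mm through `geometry`), the
#' class label as the finding type, and the detection score as a NUM
#' measurement of the region.
#'
#' @param rois list of [detected_roi()]s with `class_label` and `score`
#'   set.
#' @param geometry [plane_geometry()] of the plane the ROI pixel indices
#'   live in.
#' @param context harvested [harvest_context()] metadata.
#' @param evidence evidence references from [build_evidence()].
#' @param frame_of_reference_uid UID of the target frame of reference.
#' @param procedure procedure-reported concept.
#' @param observer optional [observation_context()].
#' @return a Comprehensive 3D SR `dcm_dataset`.
#' @export
rois_to_sr <- function(rois, geometry, context, evidence,
                       frame_of_reference_uid = context$frame_of_reference_uid,
                       procedure = registry_lookup("SCT", "Imaging"),
                       observer = observation_context(device_uid = generate_uid())) {
  stopifnot(all(vapply(rois, inherits, logical(1), "detected_roi")))
  score_name <- registry_lookup("SCT", "Score")
  no_units <- registry_lookup("UCUM", "NoUnits")
  groups <- lapply(seq_along(rois), function(i) {
    roi <- rois[[i]]
    bb <- roi$bounding_box
    corners_px <- rbind(c(bb[1], bb[2]), c(bb[3], bb[2]),
                        c(bb[3], bb[4]), c(bb[1], bb[4]), c(bb[1], bb[2]))
    corners_mm <- pixel_to_reference(corners_px, geometry)
    region <- item_scoord3d(registry_lookup("DCM", "ImageRegion"),
                            "POLYGON", corners_mm, frame_of_reference_uid)
    measurements <- list()
    if (!is.null(roi$score)) {
      measurements <- list(measurement(score_name, roi$score, no_units))
    }
    measurement_group(
      tracking_id = sprintf("ROI-%d", i), tracking_uid = generate_uid(),
      finding_type = roi$class_label, region = region,
      measurements = measurements, kind = "planar")
  })
  tree <- build_measurement_report(observer, procedure, groups)
  create_sr_document(tree, evidence, context, kind = "comprehensive_3d")
}
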