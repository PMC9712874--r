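# Synthetic source images and pipeline scenarios. Pixel content is smooth
# noise plus planted blob intensities: enough structure for nontrivial
# masks, no attempt at photorealism. Given a seed, generation is
# deterministic down to the byte (UIDs included).

#' Specify a synthetic axial CT series
#'
#' @param n_slices number of single-frame slices (>= 1).
#' @param rows,cols slice dimensions.
#' @param pixel_spacing `(between-rows, between-columns)` mm.
#' @param slice_spacing distance between consecutive slices along the slice
#'   normal, mm.
#' @param orientation `"axial"` (identity direction cosines) or
#'   `"rotated"` (90 degrees about the slice normal).
#' @param patient_id,patient_name,study_id identifiers written into the
#'   patient/study modules.
#' @param seed RNG seed controlling pixel noise and UIDs.
#' @return object of class `ct_series_spec`.
#' @export
ct_series_spec <- function(n_slices = 3L, rows = 32L, cols = 32L,
                           pixel_spacing = c(0.7, 0.7), slice_spacing = 2.5,
                           orientation = c("axial", "rotated"),
                           patient_id = "PAT-001", patient_name = "Doe^Jane",
                           study_id = "STU-001", seed = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(n_slices >= 1, rows >= 1, cols >= 1, all(pixel_spacing > 0),
            slice_spacing > 0)
  structure(list(n_slices = as.integer(n_slices), rows = as.integer(rows),
                 cols = as.integer(cols), pixel_spacing = pixel_spacing,
                 slice_spacing = slice_spacing, orientation = orientation,
                 patient_id = patient_id, patient_name = patient_name,
                 study_id = study_id, seed = as.integer(seed)),
            class = "ct_series_spec")
}

orientation_cosines <- function(preset) {
  switch(preset,
         axial = c(1, 0, 0, 0, 1, 0),          # col dir +x, row dir +y
         rotated = c(0, 1, 0, -1, 0, 0),       # 90 deg about +z
         stop("unknown orientation preset: ", preset, call. = FALSE))
}

smooth_noise <- function(rows, cols, levels = 64) {
  base <- matrix(stats::runif(rows * cols), rows, cols)
  k <- stats::filter(base, rep(1 / 3, 3), circular = TRUE)
  m <- t(apply(matrix(k, rows, cols), 1, function(x)
    stats::filter(x, rep(1 / 3, 3), circular = TRUE)))
  m <- matrix(m, rows, cols)
  floor((m - min(m)) / (max(m) - min(m) + 1e-12) * (levels - 1))
}

#' Generate a synthetic axial CT series
#'
#' One single-frame dataset per slice with shared study, series and
#' frame-of-reference UIDs; slice positions are spaced by `slice_spacing`
#' along the slice normal. Byte-identical output for identical specs.
#'
#' @param spec a [ct_series_spec()].
#' @return list of `dcm_dataset`s, one per slice.
#' @export
generate_ct_series <- function(spec) {
  stopifnot(inherits(spec, "ct_series_spec"))
  withr::with_seed(spec$seed, {
    study_uid <- generate_uid()
    series_uid <- generate_uid()
    for_uid <- generate_uid()
    iop <- orientation_cosines(spec$orientation)
    lapply(seq_len(spec$n_slices), function(k) {
      px <- smooth_noise(spec$rows, spec$cols, levels = 1000)
      ds <- dcm_dataset(
        SpecificCharacterSet = "ISO_IR 192",
        SOPClassUID = DCM_UID$ct_image,
        SOPInstanceUID = generate_uid(),
        StudyInstanceUID = study_uid,
        SeriesInstanceUID = series_uid,
        FrameOfReferenceUID = for_uid,
        PositionReferenceIndicator = "",
        Modality = "CT",
        ImageType = c("ORIGINAL", "PRIMARY", "AXIAL"),
        Manufacturer = "dcmannot project",
        PatientID = spec$patient_id,
        PatientName = spec$patient_name,
        PatientBirthDate = "19700101",
        PatientSex = "O",
        StudyID = spec$study_id,
        StudyDate = "20260101",
        StudyTime = "120000",
        AccessionNumber = "ACC-1",
        ReferringPhysicianName = "Ref^Doc",
        SeriesNumber = 1L,
        InstanceNumber = k,
        Rows = spec$rows, Columns = spec$cols,
        PixelSpacing = spec$pixel_spacing,
        SliceThickness = spec$slice_spacing,
        ImageOrientationPatient = iop,
        ImagePositionPatient = c(0, 0, (k - 1) * spec$slice_spacing),
        SamplesPerPixel = 1L,
        PhotometricInterpretation = "MONOCHROME2",
        BitsAllocated = 16L, BitsStored = 16L, HighBit = 15L,
        PixelRepresentation = 0L,
        RescaleIntercept = -1024, RescaleSlope = 1
      )
      raw_px <- writeBin(as.integer(t(px)), raw(), size = 2, endian = "little")
      ds_set(ds, "PixelData", raw_px, vr = "OW")
    })
  })
}

#' Specify a synthetic tiled slide-microscopy image
#'
#' @param matrix_rows,matrix_cols total pixel matrix dimensions.
#' @param tile_rows,tile_cols per-frame tile dimensions; the last tile row
#'   and column are padded when the matrix is not an exact multiple.
#' @param pixel_spacing `(between-rows, between-columns)` mm (microscopy
#'   resolution, e.g. 0.001 mm = 1 micrometer).
#' @param container_id,specimen_id specimen-module identifiers.
#' @param patient_id subject of the slide.
#' @param seed RNG seed.
#' @return object of class `sm_image_spec`.
#' @export
sm_image_spec <- function(matrix_rows = 64L, matrix_cols = 64L,
                          tile_rows = 16L, tile_cols = 16L,
                          pixel_spacing = c(0.001, 0.001),
                          container_id = "SLIDE-001", specimen_id = "SPC-001",
                          patient_id = "PAT-001", seed = 1L) {
  stopifnot(matrix_rows >= 1, matrix_cols >= 1, all(pixel_spacing > 0))
  if (tile_rows > matrix_rows || tile_cols > matrix_cols) {
    stop("tile dimensions exceed the total pixel matrix", call. = FALSE)
  }
  structure(list(matrix_rows = as.integer(matrix_rows),
                 matrix_cols = as.integer(matrix_cols),
                 tile_rows = as.integer(tile_rows),
                 tile_cols = as.integer(tile_cols),
                 pixel_spacing = pixel_spacing, container_id = container_id,
                 specimen_id = specimen_id, patient_id = patient_id,
                 seed = as.integer(seed)),
            class = "sm_image_spec")
}

#' Generate a synthetic tiled slide-microscopy image
#'
#' One multi-frame dataset whose frames are tiles in row-major
#' total-pixel-matrix order, with slide frame-of-reference metadata and
#' specimen attributes.
#'
#' @param spec an [sm_image_spec()].
#' @return a `dcm_dataset`.
#' @export
generate_sm_image <- function(spec) {
  stopifnot(inherits(spec, "sm_image_spec"))
  withr::with_seed(spec$seed, {
    n_tile_rows <- ceiling(spec$matrix_rows / spec$tile_rows)
    n_tile_cols <- ceiling(spec$matrix_cols / spec$tile_cols)
    n_frames <- n_tile_rows * n_tile_cols
    full <- smooth_noise(n_tile_rows * spec$tile_rows,
                         n_tile_cols * spec$tile_cols, levels = 256)
    ds <- dcm_dataset(
      SpecificCharacterSet = "ISO_IR 192",
      SOPClassUID = DCM_UID$sm_image,
      SOPInstanceUID = generate_uid(),
      StudyInstanceUID = generate_uid(),
      SeriesInstanceUID = generate_uid(),
      FrameOfReferenceUID = generate_uid(),
      PositionReferenceIndicator = "SLIDE_CORNER",
      Modality = "SM",
      ImageType = c("ORIGINAL", "PRIMARY", "VOLUME", "NONE"),
      Manufacturer = "dcmannot project",
      PatientID = spec$patient_id,
      PatientName = "Doe^Jane",
      PatientBirthDate = "19700101",
      PatientSex = "O",
      StudyID = "STU-001",
      StudyDate = "20260101",
      StudyTime = "120000",
      AccessionNumber = "ACC-1",
      ReferringPhysicianName = "Ref^Doc",
      SeriesNumber = 1L,
      InstanceNumber = 1L,
      Rows = spec$tile_rows, Columns = spec$tile_cols,
      NumberOfFrames = n_frames,
      TotalPixelMatrixRows = spec$matrix_rows,
      TotalPixelMatrixColumns = spec$matrix_cols,
      TotalPixelMatrixOriginSequence = list(dcm_dataset(
        XOffsetInSlideCoordinateSystem = 0,
        YOffsetInSlideCoordinateSystem = 0)),
      ImageOrientationSlide = c(1, 0, 0, 0, 1, 0),
      DimensionOrganizationType = "TILED_FULL",
      ContainerIdentifier = spec$container_id,
      SpecimenDescriptionSequence = list(dcm_dataset(
        SpecimenIdentifier = spec$specimen_id,
        SpecimenUID = generate_uid())),
      SamplesPerPixel = 1L,
      PhotometricInterpretation = "MONOCHROME2",
      BitsAllocated = 8L, BitsStored = 8L, HighBit = 7L,
      PixelRepresentation = 0L,
      SharedFunctionalGroupsSequence = list(dcm_dataset(
        PixelMeasuresSequence = list(dcm_dataset(
          PixelSpacing = spec$pixel_spacing))))
    )
    per_frame <- list()
    tiles <- raw(0)
    f <- 0L
    for (tr in seq_len(n_tile_rows)) {
      for (tc in seq_len(n_tile_cols)) {
        f <- f + 1L
        r0 <- (tr - 1L) * spec$tile_rows
        c0 <- (tc - 1L) * spec$tile_cols
        tile <- full[r0 + seq_len(spec$tile_rows), c0 + seq_len(spec$tile_cols)]
        tiles <- c(tiles, as.raw(as.integer(t(tile))))
        per_frame[[f]] <- dcm_dataset(
          FrameContentSequence = list(dcm_dataset(DimensionIndexValues = c(tr, tc))),
          PlanePositionSlideSequence = list(dcm_dataset(
            RowPositionInTotalImagePixelMatrix = r0 + 1L,
            ColumnPositionInTotalImagePixelMatrix = c0 + 1L,
            XOffsetInSlideCoordinateSystem = c0 * spec$pixel_spacing[2],
            YOffsetInSlideCoordinateSystem = r0 * spec$pixel_spacing[1],
            ZOffsetInSlideCoordinateSystem = 0)))
      }
    }
    ds <- ds_set(ds, "PerFrameFunctionalGroupsSequence", per_frame)
    if (length(tiles) %% 2 == 1) tiles <- c(tiles, as.raw(0L))
    ds_set(ds, "PixelData", tiles, vr = "OB")
  })
}

#' Specify a detection scenario with planted blobs
#'
#' @param image_spec a [ct_series_spec()] or [sm_image_spec()].
#' @param classes list of [coded_concept()]s, one per class.
#' @param blobs list of blobs, each
#'   `list(frame =, center = c(row, col), size = c(h, w), class =, prob =)`
#'   (`frame`, `center` 1-based; `class` an index into `classes`; `prob`
#'   the probability level painted inside the blob).
#' @param background_prob upper bound of the background probability noise.
#' @param seed RNG seed.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(image_spec, classes, blobs,
                          background_prob = 0.1, seed = 1L) {
  stopifnot(inherits(image_spec, "ct_series_spec") ||
              inherits(image_spec, "sm_image_spec"),
            length(classes) >= 1, length(blobs) >= 1)
  dims <- if (inherits(image_spec, "ct_series_spec")) {
    c(image_spec$n_slices, image_spec$rows, image_spec$cols)
  } else {
    c(1L, image_spec$matrix_rows, image_spec$matrix_cols)
  }
  for (b in blobs) {
    stopifnot(b$class >= 1, b$class <= length(classes),
              b$prob >= 0, b$prob <= 1, b$frame >= 1, b$frame <= dims[1])
    r <- b$center[1] + c(-1, 1) * floor(b$size[1] / 2)
    c_ <- b$center[2] + c(-1, 1) * floor(b$size[2] / 2)
    if (r[1] < 1 || r[2] > dims[2] || c_[1] < 1 || c_[2] > dims[3]) {
      stop("blob exceeds image bounds", call. = FALSE)
    }
  }
  structure(list(image_spec = image_spec, classes = classes, blobs = blobs,
                 background_prob = background_prob, seed = as.integer(seed)),
            class = "scenario_spec")
}

merge_overlapping_boxes <- function(boxes) {
  # boxes: list of c(col0,row0,col1,row1); merge transitively overlapping
  merged_any <- TRUE
  warned <- FALSE
  while (merged_any && length(boxes) > 1) {
    merged_any <- FALSE
    for (i in seq_along(boxes)) {
      for (j in seq_along(boxes)) {
        if (j <= i) next
        a <- boxes[[i]]; b <- boxes[[j]]
        if (a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]) {
          boxes[[i]] <- c(min(a[1], b[1]), min(a[2], b[2]),
                          max(a[3], b[3]), max(a[4], b[4]))
          boxes[[j]] <- NULL
          merged_any <- TRUE
          if (!warned) {
            warning("overlapping blobs of one class merged in ground truth",
                    call. = FALSE)
            warned <- TRUE
          }
          break
        }
      }
      if (merged_any) break
    }
  }
  boxes
}

#' Generate a full detection scenario
#'
#' Builds the source image(s), per-class probability maps (background noise
#' plus planted blob probability levels), ground-truth binary masks at the
#' 0.5 threshold, and tight ground-truth bounding boxes (overlapping blobs
#' of one class are merged, with a warning). Boxes use 0-based
#' `(col0, row0, col1, row1)` pixel indices, matching [extract_rois()].
#'
#' @param spec a [scenario_spec()].
#' @param threshold threshold defining the ground-truth masks (default 0.5).
#' @return list with `images` (list of source datasets), `prob_maps` (per
#'   class, `(frames, rows, cols)` arrays), `truth_masks` (per class,
#'   logical arrays) and `truth_boxes` (data.frame: class, frame, col0,
#'   row0, col1, row1).
#' @export
generate_scenario <- function(spec, threshold = 0.5) {
  stopifnot(inherits(spec, "scenario_spec"))
  images <- if (inherits(spec$image_spec, "ct_series_spec")) {
    generate_ct_series(spec$image_spec)
  } else {
    list(generate_sm_image(spec$image_spec))
  }
  dims <- if (inherits(spec$image_spec, "ct_series_spec")) {
    c(spec$image_spec$n_slices, spec$image_spec$rows, spec$image_spec$cols)
  } else {
    c(1L, spec$image_spec$matrix_rows, spec$image_spec$matrix_cols)
  }
  n_class <- length(spec$classes)
  prob_maps <- withr::with_seed(spec$seed + 1L, {
    lapply(seq_len(n_class), function(k) {
      array(stats::runif(prod(dims), 0, spec$background_prob), dims)
    })
  })
  boxes_by_key <- list()
  for (b in spec$blobs) {
    r0 <- b$center[1] - floor(b$size[1] / 2)
    r1 <- b$center[1] + floor(b$size[1] / 2)
    c0 <- b$center[2] - floor(b$size[2] / 2)
    c1 <- b$center[2] + floor(b$size[2] / 2)
    prob_maps[[b$class]][b$frame, r0:r1, c0:c1] <- b$prob
    if (b$prob >= threshold) {
      key <- sprintf("%d|%d", b$class, b$frame)
      boxes_by_key[[key]] <- c(boxes_by_key[[key]],
                               list(c(c0 - 1, r0 - 1, c1 - 1, r1 - 1)))
    }
  }
  truth_masks <- lapply(prob_maps, function(m) m >= threshold)
  rows_out <- list()
  for (key in names(boxes_by_key)) {
    parts <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    for (box in merge_overlapping_boxes(boxes_by_key[[key]])) {
      rows_out[[length(rows_out) + 1]] <- data.frame(
        class = parts[1], frame = parts[2], col0 = box[1], row0 = box[2],
        col1 = box[3], row1 = box[4])
    }
  }
  truth_boxes <- do.call(rbind, rows_out)
  truth_boxes <- truth_boxes[order(truth_boxes$class, truth_boxes$frame,
                                   truth_boxes$row0, truth_boxes$col0), ]
  rownames(truth_boxes) <- NULL
  list(images = images, prob_maps = prob_maps, truth_masks = truth_masks,
       truth_boxes = truth_boxes)
}
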