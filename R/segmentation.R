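#' Describe one segment of a Segmentation image
#'
#' @param segment_number integer >= 1; numbers must be consecutive from 1
#'   within one object.
#' @param label human-readable segment label.
#' @param property_category,property_type [coded_concept()]s describing what
#'   the segment represents (e.g. category "Morphologically abnormal
#'   structure", type "Tumor").
#' @param algorithm_type `"AUTOMATIC"`, `"SEMIAUTOMATIC"` or `"MANUAL"`.
#' @param algorithm_identification list with `name` and optional `version`;
#'   required unless `algorithm_type` is `"MANUAL"`.
#' @param tracking_id,tracking_uid optional tracking identifier string and
#'   UID, letting the same finding be followed across objects.
#' @return an object of class `segment_description`.
#' @export
segment_description <- function(segment_number, label, property_category,
                                property_type,
                                algorithm_type = c("AUTOMATIC", "SEMIAUTOMATIC", "MANUAL"),
                                algorithm_identification = NULL,
                                tracking_id = NULL, tracking_uid = NULL) {
  algorithm_type <- match.arg(algorithm_type)
  stopifnot(is.numeric(segment_number), segment_number >= 1,
            is.character(label), length(label) == 1,
            inherits(property_category, "coded_concept"),
            inherits(property_type, "coded_concept"))
  if (algorithm_type != "MANUAL" && is.null(algorithm_identification)) {
    stop("algorithm_identification is required unless algorithm_type is MANUAL",
         call. = FALSE)
  }
  if (!is.null(tracking_id) != !is.null(tracking_uid)) {
    stop("tracking_id and tracking_uid must be given together", call. = FALSE)
  }
  structure(list(segment_number = as.integer(segment_number), label = label,
                 property_category = property_category,
                 property_type = property_type,
                 algorithm_type = algorithm_type,
                 algorithm_identification = algorithm_identification,
                 tracking_id = tracking_id, tracking_uid = tracking_uid),
            class = "segment_description")
}

#' Encoding policy for a Segmentation image
#'
#' @param segmentation_type `"BINARY"` (bit-packed boolean masks) or
#'   `"FRACTIONAL"` (8-bit quantized decimals).
#' @param fractional_type `"PROBABILITY"` or `"OCCUPANCY"`; required iff
#'   `segmentation_type = "FRACTIONAL"`.
#' @param max_fractional_value integer in 1..255; stored value `v` maps back
#'   to `v / max_fractional_value`.
#' @param omit_empty_frames drop all-background frames at encode time
#'   (sparse storage); they are reconstructed as zeros on decode.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(segmentation_type = c("BINARY", "FRACTIONAL"),
                                fractional_type = NULL,
                                max_fractional_value = 255L,
                                omit_empty_frames = TRUE) {
  segmentation_type <- match.arg(segmentation_type)
  if (segmentation_type == "FRACTIONAL") {
    if (is.null(fractional_type) ||
        !fractional_type %in% c("PROBABILITY", "OCCUPANCY")) {
      stop("fractional_type (PROBABILITY or OCCUPANCY) is required for FRACTIONAL",
           call. = FALSE)
    }
  } else if (!is.null(fractional_type)) {
    stop("fractional_type is only meaningful for FRACTIONAL type", call. = FALSE)
  }
  if (max_fractional_value < 1 || max_fractional_value > 255) {
    stop("max_fractional_value must be in 1..255", call. = FALSE)
  }
  structure(list(segmentation_type = segmentation_type,
                 fractional_type = fractional_type,
                 max_fractional_value = as.integer(max_fractional_value),
                 omit_empty_frames = isTRUE(omit_empty_frames)),
            class = "segmentation_params")
}

# --- bit packing ---------------------------------------------------------

#' Pack boolean frames into DICOM 1-bit pixel data
#'
#' Pixels are flattened row-major within each frame; frames are concatenated
#' without per-frame byte alignment. Bit `k` of byte `b` encodes pixel
#' `8*b + k` (least-significant bit first). The final byte is zero-padded
#' and the total length padded to an even number of bytes.
#'
#' @param planes logical matrix `(rows, cols)` or array `(frames, rows, cols)`.
#' @return raw vector.
#' @export
pack_bits <- function(planes) {
  if (!is.logical(planes)) stop("pack_bits requires logical input", call. = FALSE)
  if (is.matrix(planes)) planes <- array(planes, c(1, dim(planes)))
  stopifnot(length(dim(planes)) == 3)
  n_frames <- dim(planes)[1]
  bits <- logical(0)
  bits <- unlist(lapply(seq_len(n_frames), function(f) {
    as.vector(t(planes[f, , ]))  # row-major flatten
  }))
  if (length(bits) %% 8 != 0) {
    bits <- c(bits, rep(FALSE, 8 - length(bits) %% 8))
  }
  out <- packBits(bits, type = "raw")
  if (length(out) %% 2 == 1) out <- c(out, as.raw(0L))
  out
}

#' Unpack DICOM 1-bit pixel data into boolean frames
#'
#' Inverse of [pack_bits()]: `unpack_bits(pack_bits(x), dim(x)[1], dim(x)[2],
#' dim(x)[3])` is the identity.
#'
#' @param bytes raw vector as produced by [pack_bits()].
#' @param n_frames,rows,cols expected frame geometry.
#' @return logical array `(n_frames, rows, cols)`.
#' @export
unpack_bits <- function(bytes, n_frames, rows, cols) {
  total_bits <- n_frames * rows * cols
  need <- ceiling(total_bits / 8)
  need_padded <- need + need %% 2
  if (length(bytes) != need && length(bytes) != need_padded) {
    stop(sprintf("framing error: %d bytes cannot hold %d frames of %dx%d bits",
                 length(bytes), n_frames, rows, cols), call. = FALSE)
  }
  bits <- as.logical(rawToBits(bytes))[seq_len(total_bits)]
  out <- array(FALSE, c(n_frames, rows, cols))
  per_frame <- rows * cols
  for (f in seq_len(n_frames)) {
    m <- matrix(bits[((f - 1) * per_frame + 1):(f * per_frame)],
                nrow = rows, ncol = cols, byrow = TRUE)
    out[f, , ] <- m
  }
  out
}

# quantize probabilities: round-half-up of p * max
quantize_fractional <- function(p, max_value) {
  storage.mode(p) <- "double"
  as.integer(floor(p * max_value + 0.5))
}

# --- source frame table --------------------------------------------------

# Normalizes source images into a per-frame table:
# list of list(sop_class, sop_uid, frame_number, position-info)
source_frame_table <- function(source_images) {
  first <- source_images[[1]]
  if (length(source_images) == 1 &&
      !is.null(ds_get(first, "NumberOfFrames")) &&
      ds_get(first, "NumberOfFrames") > 1) {
    # tiled / multi-frame source (slide microscopy)
    n <- as.integer(ds_get(first, "NumberOfFrames"))
    pfg <- ds_get(first, "PerFrameFunctionalGroupsSequence")
    lapply(seq_len(n), function(f) {
      pps <- ds_get(pfg[[f]], "PlanePositionSlideSequence")[[1]]
      list(kind = "SLIDE",
           sop_class = ds_get(first, "SOPClassUID"),
           sop_uid = ds_get(first, "SOPInstanceUID"),
           frame_number = f,
           row_position = ds_get(pps, "RowPositionInTotalImagePixelMatrix"),
           col_position = ds_get(pps, "ColumnPositionInTotalImagePixelMatrix"),
           offsets = c(ds_get(pps, "XOffsetInSlideCoordinateSystem"),
                       ds_get(pps, "YOffsetInSlideCoordinateSystem"),
                       ds_get(pps, "ZOffsetInSlideCoordinateSystem", 0)))
    })
  } else {
    orientations <- unique(vapply(source_images, function(s) {
      paste(ds_get(s, "ImageOrientationPatient"), collapse = ",")
    }, character(1)))
    if (length(orientations) > 1) {
      stop("source images have varying plane orientation; not supported",
           call. = FALSE)
    }
    lapply(source_images, function(s) {
      list(kind = "PATIENT",
           sop_class = ds_get(s, "SOPClassUID"),
           sop_uid = ds_get(s, "SOPInstanceUID"),
           frame_number = 1L,
           position = ds_get(s, "ImagePositionPatient"))
    })
  }
}

source_pixel_desc <- function(source_images) {
  first <- source_images[[1]]
  list(rows = ds_get(first, "Rows"), cols = ds_get(first, "Columns"),
       pixel_spacing = {
         if (ds_has(first, "PixelSpacing")) ds_get(first, "PixelSpacing")
         else {
           shared <- ds_get(first, "SharedFunctionalGroupsSequence")
           ds_get(ds_get(shared[[1]], "PixelMeasuresSequence")[[1]], "PixelSpacing")
         }
       },
       orientation_patient = ds_get(first, "ImageOrientationPatient"),
       orientation_slide = ds_get(first, "ImageOrientationSlide"))
}

# --- encoder -------------------------------------------------------------

#' Encode a mask array as a DICOM Segmentation image
#'
#' Accepts a boolean array (single segment, or per-segment bit planes in the
#' 4th dimension), an integer label map (value `k` maps to segment `k`, 0 is
#' background) or, for FRACTIONAL type, floating-point values in `[0, 1]`
#' that are quantized to `0..max_fractional_value` (round-half-up). One
#' encoded frame is produced per (segment, source frame) pair; with
#' `omit_empty_frames` all-background frames are dropped, and decoders
#' restore them as zeros.
#'
#' @param pixel_array mask: `(rows, cols)`, `(frames, rows, cols)` or
#'   `(frames, rows, cols, segments)`; frames align 1:1 with the source
#'   frames.
#' @param source_images list of source image datasets: single-frame
#'   patient-based slices, or one tiled multi-frame slide image.
#' @param descriptions list of [segment_description()], one per segment,
#'   numbered 1..N.
#' @param params a [segmentation_params()].
#' @param series_number series number for the derived series.
#' @return a `dcm_dataset` that passes [validate_sop()] for
#'   `"segmentation"`.
#' @export
encode_segmentation <- function(pixel_array, source_images, descriptions,
                                params = segmentation_params(),
                                series_number = 10L) {
  stopifnot(inherits(params, "segmentation_params"),
            is.list(descriptions), length(descriptions) > 0)
  nums <- vapply(descriptions, function(d) d$segment_number, integer(1))
  if (!identical(sort(nums), seq_along(descriptions))) {
    stop("segment numbers must be consecutive 1..N and unique", call. = FALSE)
  }
  descriptions <- descriptions[order(nums)]
  n_seg <- length(descriptions)

  if (is.matrix(pixel_array)) pixel_array <- array(pixel_array, c(1, dim(pixel_array)))
  nd <- length(dim(pixel_array))
  stopifnot(nd %in% c(3, 4))
  frames <- dim(pixel_array)[1]
  rows <- dim(pixel_array)[2]; cols <- dim(pixel_array)[3]

  # storage mode picks the interpretation: logical = bit planes, integer =
  # label map, double = probabilities (FRACTIONAL only)
  is_float <- is.double(pixel_array)
  if (is_float) {
    if (params$segmentation_type == "BINARY") {
      stop("floating-point input requires FRACTIONAL segmentation type",
           call. = FALSE)
    }
    if (any(pixel_array < 0 | pixel_array > 1)) {
      stop("floating-point mask values must lie in [0, 1]", call. = FALSE)
    }
  }

  # per-segment integer planes (quantized for FRACTIONAL, 0/1 otherwise)
  seg_plane <- function(k) {
    if (nd == 4) {
      if (dim(pixel_array)[4] != n_seg) {
        stop("4th dimension must match the number of segment descriptions",
             call. = FALSE)
      }
      pl <- pixel_array[, , , k, drop = FALSE]
      dim(pl) <- dim(pixel_array)[1:3]
    } else if (is.logical(pixel_array)) {
      if (n_seg != 1) stop("a boolean 3D mask encodes exactly one segment",
                           call. = FALSE)
      pl <- pixel_array
    } else if (!is_float) {  # label map
      if (max(pixel_array) > n_seg) {
        stop("label map contains value ", max(pixel_array),
             " but only ", n_seg, " segment descriptions were given",
             call. = FALSE)
      }
      pl <- pixel_array == k
    } else {
      if (n_seg != 1) stop("a float 3D mask encodes exactly one segment; use a 4D array",
                           call. = FALSE)
      pl <- pixel_array
    }
    if (params$segmentation_type == "FRACTIONAL") {
      if (is.logical(pl)) {
        array(as.integer(pl) * params$max_fractional_value, dim(pl))
      } else if (is.double(pl)) {
        array(quantize_fractional(pl, params$max_fractional_value), dim(pl))
      } else {
        array(as.integer(pl > 0) * params$max_fractional_value, dim(pl))
      }
    } else {
      array(pl > 0, dim(pl))
    }
  }

  src_frames <- source_frame_table(source_images)
  if (length(src_frames) != frames) {
    stop(sprintf("mask has %d frames but sources provide %d", frames,
                 length(src_frames)), call. = FALSE)
  }
  px <- source_pixel_desc(source_images)
  if (!identical(as.integer(px$rows), as.integer(rows)) ||
      !identical(as.integer(px$cols), as.integer(cols))) {
    stop("mask rows/cols do not match the source images", call. = FALSE)
  }

  # collect encoded frames: (segment, source frame index) pairs
  enc <- list()
  planes <- list()
  for (k in seq_len(n_seg)) {
    pl <- seg_plane(k)
    for (f in seq_len(frames)) {
      frame_px <- pl[f, , ]
      if (params$omit_empty_frames && !any(frame_px != 0)) next
      enc[[length(enc) + 1]] <- list(segment = k, source_index = f)
      planes[[length(planes) + 1]] <- frame_px
    }
  }
  if (length(enc) == 0) {
    stop("all frames are empty; disable omit_empty_frames to encode an ",
         "explicit all-background object", call. = FALSE)
  }

  context <- harvest_context(source_images)
  ds <- derived_dataset_skeleton(context, DCM_UID$segmentation, "SEG",
                                 series_number = series_number)
  ds <- ds_set(ds, "ImageType", c("DERIVED", "PRIMARY"))
  ds <- ds_set(ds, "ContentCreatorName", "dcmannot")
  ds <- ds_set(ds, "FrameOfReferenceUID", context$frame_of_reference_uid)
  ds <- ds_set(ds, "SamplesPerPixel", 1L)
  ds <- ds_set(ds, "PhotometricInterpretation", "MONOCHROME2")
  ds <- ds_set(ds, "PixelRepresentation", 0L)
  ds <- ds_set(ds, "LossyImageCompression", "00")
  ds <- ds_set(ds, "Rows", as.integer(rows))
  ds <- ds_set(ds, "Columns", as.integer(cols))
  ds <- ds_set(ds, "NumberOfFrames", length(enc))
  ds <- ds_set(ds, "SegmentationType", params$segmentation_type)
  if (params$segmentation_type == "FRACTIONAL") {
    ds <- ds_set(ds, "SegmentationFractionalType", params$fractional_type)
    ds <- ds_set(ds, "MaximumFractionalValue", params$max_fractional_value)
    ds <- ds_set(ds, "BitsAllocated", 8L)
    ds <- ds_set(ds, "BitsStored", 8L)
    ds <- ds_set(ds, "HighBit", 7L)
  } else {
    ds <- ds_set(ds, "BitsAllocated", 1L)
    ds <- ds_set(ds, "BitsStored", 1L)
    ds <- ds_set(ds, "HighBit", 0L)
  }

  ds <- ds_set(ds, "SegmentSequence", lapply(descriptions, function(d) {
    item <- dcm_dataset(
      SegmentNumber = d$segment_number,
      SegmentLabel = d$label,
      SegmentAlgorithmType = d$algorithm_type,
      SegmentedPropertyCategoryCodeSequence = list(concept_to_ds(d$property_category)),
      SegmentedPropertyTypeCodeSequence = list(concept_to_ds(d$property_type))
    )
    if (!is.null(d$algorithm_identification)) {
      item <- ds_set(item, "SegmentAlgorithmName", d$algorithm_identification$name)
    }
    if (!is.null(d$tracking_id)) {
      item <- ds_set(item, "TrackingID", d$tracking_id)
      item <- ds_set(item, "TrackingUID", d$tracking_uid)
    }
    item
  }))

  # shared functional groups
  shared <- dcm_dataset(
    PixelMeasuresSequence = list(dcm_dataset(PixelSpacing = px$pixel_spacing))
  )
  if (!is.null(px$orientation_patient)) {
    shared <- ds_set(shared, "PlaneOrientationSequence",
                     list(dcm_dataset(ImageOrientationPatient = px$orientation_patient)))
  }
  ds <- ds_set(ds, "SharedFunctionalGroupsSequence", list(shared))

  dim_org_uid <- generate_uid()
  ds <- ds_set(ds, "DimensionOrganizationSequence",
               list(dcm_dataset(DimensionOrganizationUID = dim_org_uid)))
  ds <- ds_set(ds, "DimensionIndexSequence", list(
    dcm_dataset(DimensionOrganizationUID = dim_org_uid,
                DimensionIndexPointer = "0062000B",
                FunctionalGroupPointer = "0062000A"),
    dcm_dataset(DimensionOrganizationUID = dim_org_uid,
                DimensionIndexPointer = "00209157",
                FunctionalGroupPointer = "00209111")
  ))

  per_frame <- lapply(enc, function(e) {
    sf <- src_frames[[e$source_index]]
    item <- dcm_dataset(
      FrameContentSequence = list(dcm_dataset(
        DimensionIndexValues = c(e$segment, e$source_index))),
      SegmentIdentificationSequence = list(dcm_dataset(
        ReferencedSegmentNumber = e$segment)),
      DerivationImageSequence = list(dcm_dataset(
        SourceImageSequence = list({
          ref <- dcm_dataset(ReferencedSOPClassUID = sf$sop_class,
                             ReferencedSOPInstanceUID = sf$sop_uid)
          if (sf$kind == "SLIDE") ref <- ds_set(ref, "ReferencedFrameNumber",
                                                sf$frame_number)
          ref
        })))
    )
    if (sf$kind == "PATIENT") {
      item <- ds_set(item, "PlanePositionSequence",
                     list(dcm_dataset(ImagePositionPatient = sf$position)))
    } else {
      item <- ds_set(item, "PlanePositionSlideSequence", list(dcm_dataset(
        RowPositionInTotalImagePixelMatrix = sf$row_position,
        ColumnPositionInTotalImagePixelMatrix = sf$col_position,
        XOffsetInSlideCoordinateSystem = sf$offsets[1],
        YOffsetInSlideCoordinateSystem = sf$offsets[2],
        ZOffsetInSlideCoordinateSystem = sf$offsets[3]
      )))
    }
    item
  })
  ds <- ds_set(ds, "PerFrameFunctionalGroupsSequence", per_frame)

  ds <- ds_set(ds, "ReferencedSeriesSequence",
               evidence_to_series_seq(build_evidence(source_images)))

  n_enc <- length(enc)
  if (params$segmentation_type == "BINARY") {
    stack <- array(FALSE, c(n_enc, rows, cols))
    for (j in seq_len(n_enc)) stack[j, , ] <- planes[[j]]
    ds <- ds_set(ds, "PixelData", pack_bits(stack), vr = "OB")
  } else {
    bytes <- as.raw(unlist(lapply(planes, function(p) as.integer(t(p)))))
    if (length(bytes) %% 2 == 1) bytes <- c(bytes, as.raw(0L))
    ds <- ds_set(ds, "PixelData", bytes, vr = "OB")
  }
  ds
}

# --- decoding ------------------------------------------------------------

#' Filter the segments of a Segmentation image
#'
#' Returns the segment numbers matching all supplied filters (conjunctive),
#' in ascending order; with no filters, all segments.
#'
#' @param seg_dataset a Segmentation `dcm_dataset`.
#' @param label exact segment label.
#' @param property_category,property_type [coded_concept()] filters,
#'   compared with [concepts_equal()].
#' @param tracking_uid tracking UID filter.
#' @return integer vector of segment numbers (possibly empty).
#' @export
find_segments <- function(seg_dataset, label = NULL, property_category = NULL,
                          property_type = NULL, tracking_uid = NULL) {
  segs <- ds_get(seg_dataset, "SegmentSequence")
  if (is.null(segs)) stop("dataset has no SegmentSequence", call. = FALSE)
  hits <- vapply(segs, function(s) {
    if (!is.null(label) && !identical(ds_get(s, "SegmentLabel"), label)) return(FALSE)
    if (!is.null(property_category)) {
      c1 <- ds_to_concept(ds_get(s, "SegmentedPropertyCategoryCodeSequence")[[1]])
      if (!concepts_equal(c1, property_category)) return(FALSE)
    }
    if (!is.null(property_type)) {
      c2 <- ds_to_concept(ds_get(s, "SegmentedPropertyTypeCodeSequence")[[1]])
      if (!concepts_equal(c2, property_type)) return(FALSE)
    }
    if (!is.null(tracking_uid) && !identical(ds_get(s, "TrackingUID"), tracking_uid)) {
      return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(vapply(segs[hits], function(s) as.integer(ds_get(s, "SegmentNumber")),
              integer(1)))
}

# decode all stored frames of a SEG into an integer array (frames, rows, cols)
decode_stored_frames <- function(seg) {
  n <- as.integer(ds_get(seg, "NumberOfFrames"))
  rows <- ds_get(seg, "Rows"); cols <- ds_get(seg, "Columns")
  px <- ds_get(seg, "PixelData")
  if (identical(ds_get(seg, "SegmentationType"), "BINARY")) {
    out <- unpack_bits(px, n, rows, cols)
    array(as.integer(out), dim(out))
  } else {
    total <- n * rows * cols
    vals <- as.integer(px[seq_len(total)])
    out <- array(0L, c(n, rows, cols))
    for (f in seq_len(n)) {
      out[f, , ] <- matrix(vals[((f - 1) * rows * cols + 1):(f * rows * cols)],
                           nrow = rows, byrow = TRUE)
    }
    out
  }
}

# per stored frame: (segment number, source key) from functional groups
frame_index_table <- function(seg) {
  pfg <- ds_get(seg, "PerFrameFunctionalGroupsSequence")
  lapply(pfg, function(item) {
    seg_num <- ds_get(ds_get(item, "SegmentIdentificationSequence")[[1]],
                      "ReferencedSegmentNumber")
    src <- ds_get(ds_get(ds_get(item, "DerivationImageSequence")[[1]],
                         "SourceImageSequence")[[1]], "ReferencedSOPInstanceUID")
    frame_no <- ds_get(ds_get(ds_get(item, "DerivationImageSequence")[[1]],
                              "SourceImageSequence")[[1]],
                       "ReferencedFrameNumber", default = 1L)
    list(segment = as.integer(seg_num), source_uid = src,
         source_frame = as.integer(frame_no))
  })
}

#' Reconstruct a mask array from a Segmentation image
#'
#' Performs the decode steps: selecting the stored frames relevant to the
#' requested segments and source frames via the dimension/frame index,
#' sorting them into query order, restoring omitted all-background frames
#' as zeros, and optionally combining binary segments into a label map.
#'
#' @param seg_dataset a Segmentation `dcm_dataset`.
#' @param source_frames ordered query: a character vector of source SOP
#'   instance UIDs (patient-based, single-frame sources) or an integer
#'   vector of source frame numbers (tiled multi-frame source).
#' @param segment_numbers segments to reconstruct; default all.
#' @param combine collapse binary segments into one label map (value =
#'   segment number, 0 = background). BINARY only.
#' @param allow_overlap with `combine`, let overlapping segments resolve to
#'   the highest segment number instead of failing.
#' @param rescale_fractional divide stored fractional values by
#'   `MaximumFractionalValue`, returning decimals in `[0, 1]`.
#' @return array `(n_query, rows, cols, n_segments)`, or `(n_query, rows,
#'   cols)` when `combine`. For FRACTIONAL objects the values are the
#'   stored integers unless `rescale_fractional`.
#' @export
reconstruct_mask <- function(seg_dataset, source_frames,
                             segment_numbers = NULL, combine = FALSE,
                             allow_overlap = FALSE,
                             rescale_fractional = FALSE) {
  all_segs <- find_segments(seg_dataset)
  if (is.null(segment_numbers)) segment_numbers <- all_segs
  missing_segs <- setdiff(segment_numbers, all_segs)
  if (length(missing_segs) > 0) {
    stop("unknown segment number(s): ", paste(missing_segs, collapse = ", "),
         call. = FALSE)
  }
  seg_type <- ds_get(seg_dataset, "SegmentationType")
  if (combine && seg_type != "BINARY") {
    stop("combining into a label map is only defined for BINARY objects",
         call. = FALSE)
  }
  rows <- ds_get(seg_dataset, "Rows"); cols <- ds_get(seg_dataset, "Columns")
  idx <- frame_index_table(seg_dataset)
  stored <- decode_stored_frames(seg_dataset)

  # instances referenced by the object's source series (includes sources
  # whose every frame was omitted as background)
  rss <- ds_get(seg_dataset, "ReferencedSeriesSequence")
  referenced_uids <- if (!is.null(rss)) {
    unlist(lapply(rss, function(se) {
      vapply(ds_get(se, "ReferencedSOPSequence"), ds_get, character(1),
             keyword = "ReferencedSOPInstanceUID")
    }))
  } else {
    unique(vapply(idx, function(e) e$source_uid, character(1)))
  }
  if (is.character(source_frames)) {
    unknown <- setdiff(source_frames, referenced_uids)
    if (length(unknown) > 0) {
      stop("query source instance(s) not referenced by this object: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    key_of <- function(e) e$source_uid
    query_keys <- source_frames
  } else {
    max_frame <- max(vapply(idx, function(e) e$source_frame, integer(1)))
    if (any(source_frames < 1)) stop("frame numbers are 1-based", call. = FALSE)
    key_of <- function(e) as.character(e$source_frame)
    query_keys <- as.character(as.integer(source_frames))
  }

  nq <- length(query_keys); ns <- length(segment_numbers)
  out <- array(0L, c(nq, rows, cols, ns))
  for (j in seq_along(idx)) {
    e <- idx[[j]]
    si <- match(e$segment, segment_numbers)
    if (is.na(si)) next
    qi <- which(query_keys == key_of(e))
    for (q in qi) out[q, , , si] <- stored[j, , ]
  }

  if (combine) {
    lab <- array(0L, c(nq, rows, cols))
    for (si in order(segment_numbers)) {
      num <- segment_numbers[si]
      member <- out[, , , si, drop = FALSE] > 0
      dim(member) <- c(nq, rows, cols)
      if (!allow_overlap && any(lab[member] != 0)) {
        stop("segments overlap; pass allow_overlap = TRUE to resolve to the ",
             "highest segment number", call. = FALSE)
      }
      lab[member] <- num
    }
    return(lab)
  }
  if (seg_type == "FRACTIONAL" && rescale_fractional) {
    mx <- ds_get(seg_dataset, "MaximumFractionalValue")
    out <- out / mx
  }
  out
}
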