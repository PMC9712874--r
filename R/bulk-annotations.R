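# Microscopy Bulk Simple Annotations: very large collections of vector
# graphics stored as flat coordinate arrays with per-graphic index offsets.

ANN_GRAPHIC_TYPES <- c("POINT", "POLYLINE", "POLYGON", "ELLIPSE", "RECTANGLE")
# vertex count per graphic for fixed-size types; NA = variable
ANN_FIXED_VERTICES <- c(POINT = 1L, POLYLINE = NA, POLYGON = NA,
                        ELLIPSE = 4L, RECTANGLE = 4L)

#' An annotation group for Microscopy Bulk Simple Annotations
#'
#' Holds many graphics of one type sharing a coded category/type, stored as
#' a flat coordinate vector. Coordinates are ultimately stored as 32-bit
#' floats (bulk size is the point of this object type), so sub-float32
#' precision is lost on write. For variable-length graphic types
#' (POLYLINE, POLYGON) the `index_offsets` are 1-based positions into the
#' flattened value list marking each graphic's first value.
#'
#' @param group_number integer >= 1.
#' @param label group label.
#' @param property_category,property_type [coded_concept()]s.
#' @param graphic_type POINT, POLYLINE, POLYGON, ELLIPSE or RECTANGLE.
#' @param graphics list of per-graphic coordinate matrices (N x 2 image
#'   coordinates, or N x 3 frame-of-reference mm).
#' @param generation_type AUTOMATIC, SEMIAUTOMATIC or MANUAL.
#' @param uid group UID; generated when omitted.
#' @return object of class `annotation_group`.
#' @export
annotation_group <- function(group_number, label, property_category,
                             property_type, graphic_type, graphics,
                             generation_type = c("AUTOMATIC", "SEMIAUTOMATIC", "MANUAL"),
                             uid = NULL) {
  generation_type <- match.arg(generation_type)
  graphic_type <- match.arg(graphic_type, ANN_GRAPHIC_TYPES)
  stopifnot(is.numeric(group_number), group_number >= 1,
            inherits(property_category, "coded_concept"),
            inherits(property_type, "coded_concept"),
            is.list(graphics))
  if (length(graphics) == 0) stop("annotation group must be non-empty", call. = FALSE)
  dims <- unique(vapply(graphics, ncol, integer(1)))
  if (length(dims) != 1 || !dims %in% c(2, 3)) {
    stop("all graphics in a group must share one dimensionality (2 or 3)",
         call. = FALSE)
  }
  fixed <- ANN_FIXED_VERTICES[[graphic_type]]
  for (g in graphics) {
    n <- nrow(g)
    if (!is.na(fixed) && n != fixed) {
      stop(sprintf("%s requires exactly %d vertices, got %d", graphic_type,
                   fixed, n), call. = FALSE)
    }
    if (is.na(fixed) && graphic_type == "POLYGON" && n < 3) {
      stop("POLYGON requires at least 3 vertices", call. = FALSE)
    }
    if (is.na(fixed) && graphic_type == "POLYLINE" && n < 2) {
      stop("POLYLINE requires at least 2 vertices", call. = FALSE)
    }
    if (!all(is.finite(g))) stop("graphic coordinates must be finite", call. = FALSE)
  }
  structure(list(group_number = as.integer(group_number),
                 uid = if (is.null(uid)) generate_uid() else uid,
                 label = label, property_category = property_category,
                 property_type = property_type, graphic_type = graphic_type,
                 dimensionality = dims, graphics = graphics,
                 generation_type = generation_type),
            class = "annotation_group")
}

# flat point data + offsets from a group
group_point_data <- function(group) {
  flat <- unlist(lapply(group$graphics, function(g) as.numeric(t(g))))
  fixed <- ANN_FIXED_VERTICES[[group$graphic_type]]
  offsets <- NULL
  if (is.na(fixed)) {
    sizes <- vapply(group$graphics, function(g) nrow(g) * group$dimensionality,
                    numeric(1))
    offsets <- cumsum(c(1, sizes[-length(sizes)]))
  }
  list(point_data = flat, index_offsets = offsets)
}

#' Encode annotation groups as a Microscopy Bulk Simple Annotations object
#'
#' @param groups list of [annotation_group()]s; all must share one
#'   coordinate dimensionality.
#' @param source_image the slide microscopy image dataset the annotations
#'   refer to.
#' @param series_number series number of the derived series.
#' @return a `dcm_dataset` passing [validate_sop()] for
#'   `"bulk_annotations"`.
#' @export
encode_bulk_annotations <- function(groups, source_image, series_number = 30L) {
  stopifnot(is.list(groups), length(groups) > 0,
            all(vapply(groups, inherits, logical(1), "annotation_group")))
  dims <- unique(vapply(groups, function(g) g$dimensionality, numeric(1)))
  if (length(dims) != 1) {
    stop("all groups in one object must share coordinate dimensionality",
         call. = FALSE)
  }
  context <- harvest_context(list(source_image))
  ds <- derived_dataset_skeleton(context, DCM_UID$bulk_annotations, "ANN",
                                 series_number = series_number)
  ds <- ds_set(ds, "AnnotationCoordinateType", if (dims == 2) "2D" else "3D")
  if (dims == 3) {
    ds <- ds_set(ds, "FrameOfReferenceUID", context$frame_of_reference_uid)
  }
  ds <- ds_set(ds, "ReferencedSeriesSequence",
               evidence_to_series_seq(build_evidence(list(source_image))))
  ds <- ds_set(ds, "AnnotationGroupSequence", lapply(groups, function(g) {
    pd <- group_point_data(g)
    item <- dcm_dataset(
      AnnotationGroupNumber = g$group_number,
      AnnotationGroupUID = g$uid,
      AnnotationGroupLabel = g$label,
      AnnotationGroupGenerationType = g$generation_type,
      AnnotationPropertyCategoryCodeSequence = list(concept_to_ds(g$property_category)),
      AnnotationPropertyTypeCodeSequence = list(concept_to_ds(g$property_type)),
      GraphicType = g$graphic_type,
      NumberOfAnnotations = length(g$graphics),
      PointCoordinatesData = pd$point_data
    )
    if (!is.null(pd$index_offsets)) {
      item <- ds_set(item, "LongPrimitivePointIndexList", pd$index_offsets)
    }
    item
  }))
  ds
}

ann_group_item <- function(ann_dataset, group_number) {
  groups <- ds_get(ann_dataset, "AnnotationGroupSequence")
  if (is.null(groups)) stop("dataset has no AnnotationGroupSequence", call. = FALSE)
  for (g in groups) {
    if (ds_get(g, "AnnotationGroupNumber") == group_number) return(g)
  }
  stop("no annotation group with number ", group_number, call. = FALSE)
}

#' Decode the graphics of one annotation group
#'
#' Splits the flat coordinate array back into per-graphic vertex matrices
#' using the fixed vertex count of the graphic type or, for variable-length
#' types, the 1-based index offsets.
#'
#' @param ann_dataset a bulk-annotation `dcm_dataset`.
#' @param group_number the group to decode.
#' @return list of per-graphic coordinate matrices.
#' @export
decode_graphics <- function(ann_dataset, group_number) {
  g <- ann_group_item(ann_dataset, group_number)
  dim_n <- if (identical(ds_get(ann_dataset, "AnnotationCoordinateType"), "2D")) 2 else 3
  flat <- ds_get(g, "PointCoordinatesData")
  n_ann <- as.integer(ds_get(g, "NumberOfAnnotations"))
  gtype <- ds_get(g, "GraphicType")
  fixed <- ANN_FIXED_VERTICES[[gtype]]
  if (!is.na(fixed)) {
    per <- fixed * dim_n
    starts <- seq(1, by = per, length.out = n_ann)
    ends <- starts + per - 1
  } else {
    starts <- ds_get(g, "LongPrimitivePointIndexList")
    ends <- c(starts[-1] - 1, length(flat))
  }
  lapply(seq_len(n_ann), function(i) {
    matrix(flat[starts[i]:ends[i]], ncol = dim_n, byrow = TRUE)
  })
}

#' Filter annotation groups by coded type or label
#'
#' @inheritParams decode_graphics
#' @param property_type [coded_concept()] filter.
#' @param label exact label filter.
#' @return integer vector of matching group numbers (all groups when no
#'   filter is given).
#' @export
find_annotation_groups <- function(ann_dataset, property_type = NULL,
                                   label = NULL) {
  groups <- ds_get(ann_dataset, "AnnotationGroupSequence")
  if (is.null(groups)) stop("dataset has no AnnotationGroupSequence", call. = FALSE)
  hits <- vapply(groups, function(g) {
    if (!is.null(label) && !identical(ds_get(g, "AnnotationGroupLabel"), label)) {
      return(FALSE)
    }
    if (!is.null(property_type)) {
      pt <- ds_to_concept(ds_get(g, "AnnotationPropertyTypeCodeSequence")[[1]])
      if (!suppressWarnings(concepts_equal(pt, property_type))) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(vapply(groups[hits], function(g)
    as.integer(ds_get(g, "AnnotationGroupNumber")), integer(1)))
}
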