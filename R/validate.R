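# Constructor-time IOD validation: deterministic rule checks over built
# datasets. The report is empty exactly when the object conforms to the
# IOD schema as implemented by this package's builders.

new_report <- function() {
  structure(data.frame(path = character(0), rule = character(0),
                       severity = character(0), message = character(0),
                       stringsAsFactors = FALSE),
            class = c("validation_report", "data.frame"))
}

add_violation <- function(report, path, rule, message, severity = "error") {
  row <- data.frame(path = path, rule = rule, severity = severity,
                    message = message, stringsAsFactors = FALSE)
  structure(rbind(as.data.frame(report), row),
            class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("validation report: no violations\n")
  } else {
    cat(sprintf("validation report: %d violation(s)\n", nrow(x)))
    print(as.data.frame(x))
  }
  invisible(x)
}

#' Count of error-severity violations
#' @param report a validation report from [validate_sop()].
#' @return integer.
#' @export
n_errors <- function(report) sum(report$severity == "error")

require_attrs <- function(report, ds, attrs, prefix = "") {
  for (kw in attrs) {
    if (!ds_has(ds, kw)) {
      report <- add_violation(report, paste0(prefix, kw), "required-attribute",
                              paste0(kw, " is required but absent"))
    }
  }
  report
}

validate_common <- function(report, ds, expected_sop_class, expected_modality) {
  report <- require_attrs(report, ds, c(
    "SOPClassUID", "SOPInstanceUID", "StudyInstanceUID", "SeriesInstanceUID",
    "Modality", "PatientID"))
  if (ds_has(ds, "SOPClassUID") &&
      !identical(ds_get(ds, "SOPClassUID"), expected_sop_class)) {
    report <- add_violation(report, "SOPClassUID", "sop-class-mismatch",
                            paste0("expected ", expected_sop_class))
  }
  if (ds_has(ds, "SOPInstanceUID") && !is_valid_uid(ds_get(ds, "SOPInstanceUID"))) {
    report <- add_violation(report, "SOPInstanceUID", "uid-syntax",
                            "invalid UID syntax")
  }
  if (ds_has(ds, "Modality") &&
      !identical(ds_get(ds, "Modality"), expected_modality)) {
    report <- add_violation(report, "Modality", "modality-mismatch",
                            paste0("expected ", expected_modality))
  }
  report
}

check_code_seq <- function(report, parent, kw, path) {
  seq <- ds_get(parent, kw)
  if (is.null(seq) || length(seq) == 0) {
    return(add_violation(report, path, "required-attribute",
                         paste0(kw, " is required but absent")))
  }
  item <- seq[[1]]
  for (code_kw in c("CodeValue", "CodingSchemeDesignator", "CodeMeaning")) {
    if (!ds_has(item, code_kw)) {
      report <- add_violation(report, paste0(path, "/", code_kw),
                              "required-attribute",
                              paste0(code_kw, " missing from code sequence"))
    }
  }
  report
}

# --- segmentation --------------------------------------------------------

validate_segmentation <- function(report, ds) {
  report <- validate_common(report, ds, DCM_UID$segmentation, "SEG")
  report <- require_attrs(report, ds, c(
    "Rows", "Columns", "NumberOfFrames", "SamplesPerPixel",
    "PhotometricInterpretation", "BitsAllocated", "PixelRepresentation",
    "SegmentationType", "FrameOfReferenceUID", "ImageType",
    "ContentCreatorName", "PixelData",
    "SharedFunctionalGroupsSequence", "PerFrameFunctionalGroupsSequence"))
  st <- ds_get(ds, "SegmentationType")
  if (!is.null(st)) {
    if (!st %in% c("BINARY", "FRACTIONAL")) {
      report <- add_violation(report, "SegmentationType", "enum",
                              "must be BINARY or FRACTIONAL")
    }
    if (st == "FRACTIONAL") {
      report <- require_attrs(report, ds, c("SegmentationFractionalType",
                                            "MaximumFractionalValue"))
      if (!identical(ds_get(ds, "BitsAllocated"), 8L)) {
        report <- add_violation(report, "BitsAllocated", "pixel-encoding",
                                "FRACTIONAL requires 8 bits allocated")
      }
    } else if (!identical(ds_get(ds, "BitsAllocated"), 1L)) {
      report <- add_violation(report, "BitsAllocated", "pixel-encoding",
                              "BINARY requires 1 bit allocated")
    }
  }
  segs <- ds_get(ds, "SegmentSequence")
  if (is.null(segs) || length(segs) == 0) {
    report <- add_violation(report, "SegmentSequence", "required-attribute",
                            "SegmentSequence is required but absent or empty")
  } else {
    nums <- vapply(segs, function(s)
      as.integer(ds_get(s, "SegmentNumber", -1L)), integer(1))
    if (!identical(sort(nums), seq_along(segs))) {
      report <- add_violation(report, "SegmentSequence/SegmentNumber",
                              "segment-numbering",
                              "segment numbers must be consecutive 1..N")
    }
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      p <- sprintf("SegmentSequence[%d]", i)
      report <- require_attrs(report, s,
                              c("SegmentLabel", "SegmentAlgorithmType"),
                              prefix = paste0(p, "/"))
      report <- check_code_seq(report, s, "SegmentedPropertyCategoryCodeSequence",
                               paste0(p, "/SegmentedPropertyCategoryCodeSequence"))
      report <- check_code_seq(report, s, "SegmentedPropertyTypeCodeSequence",
                               paste0(p, "/SegmentedPropertyTypeCodeSequence"))
      alg <- ds_get(s, "SegmentAlgorithmType")
      if (!is.null(alg) && alg != "MANUAL" && !ds_has(s, "SegmentAlgorithmName")) {
        report <- add_violation(report, paste0(p, "/SegmentAlgorithmName"),
                                "conditional-attribute",
                                "algorithm name required when type is not MANUAL")
      }
    }
  }
  n <- ds_get(ds, "NumberOfFrames")
  pfg <- ds_get(ds, "PerFrameFunctionalGroupsSequence")
  if (!is.null(n) && !is.null(pfg) && length(pfg) != n) {
    report <- add_violation(report, "PerFrameFunctionalGroupsSequence",
                            "frame-count",
                            "item count must equal NumberOfFrames")
  }
  rows <- ds_get(ds, "Rows"); cols <- ds_get(ds, "Columns")
  px <- ds_get(ds, "PixelData")
  if (!is.null(n) && !is.null(rows) && !is.null(px) && !is.null(st)) {
    need <- if (st == "BINARY") ceiling(n * rows * cols / 8) else n * rows * cols
    need_padded <- need + need %% 2
    if (!length(px) %in% c(need, need_padded)) {
      report <- add_violation(report, "PixelData", "pixel-data-length",
                              sprintf("expected %d (or %d) bytes, found %d",
                                      need, need_padded, length(px)))
    }
  }
  if (!is.null(pfg) && !is.null(segs)) {
    valid_nums <- vapply(segs, function(s)
      as.integer(ds_get(s, "SegmentNumber", -1L)), integer(1))
    for (i in seq_along(pfg)) {
      sid <- ds_get(pfg[[i]], "SegmentIdentificationSequence")
      if (is.null(sid)) {
        report <- add_violation(
          report, sprintf("PerFrameFunctionalGroupsSequence[%d]/SegmentIdentificationSequence", i),
          "required-attribute", "segment identification missing")
      } else {
        ref <- ds_get(sid[[1]], "ReferencedSegmentNumber")
        if (!is.null(ref) && !ref %in% valid_nums) {
          report <- add_violation(
            report, sprintf("PerFrameFunctionalGroupsSequence[%d]/ReferencedSegmentNumber", i),
            "segment-reference", "frame references an undefined segment")
        }
      }
    }
  }
  report
}

# --- structured reports --------------------------------------------------

SR_VALUE_TYPES_2D <- c("TEXT", "CODE", "NUM", "DATETIME", "DATE", "TIME",
                       "UIDREF", "PNAME", "IMAGE", "SCOORD", "CONTAINER",
                       "COMPOSITE", "WAVEFORM")
SR_VALUE_TYPES_3D <- c(SR_VALUE_TYPES_2D, "SCOORD3D")

validate_content_item <- function(report, item, path, allowed, is_root = FALSE) {
  vt <- ds_get(item, "ValueType")
  if (is.null(vt)) {
    return(add_violation(report, paste0(path, "/ValueType"),
                         "required-attribute", "ValueType missing"))
  }
  if (!vt %in% allowed) {
    report <- add_violation(report, paste0(path, "/ValueType"), "value-type",
                            paste0("value type ", vt,
                                   " not permitted in this IOD"))
  }
  if (!is_root && !ds_has(item, "RelationshipType")) {
    report <- add_violation(report, paste0(path, "/RelationshipType"),
                            "required-attribute",
                            "non-root items must carry a relationship")
  }
  report <- check_code_seq(report, item, "ConceptNameCodeSequence",
                           paste0(path, "/ConceptNameCodeSequence"))
  if (vt == "CONTAINER" && !ds_has(item, "ContinuityOfContent")) {
    report <- add_violation(report, paste0(path, "/ContinuityOfContent"),
                            "required-attribute",
                            "containers require ContinuityOfContent")
  }
  if (vt == "NUM") {
    mv <- ds_get(item, "MeasuredValueSequence")
    if (is.null(mv) || length(mv) == 0) {
      report <- add_violation(report, paste0(path, "/MeasuredValueSequence"),
                              "required-attribute", "NUM requires a measured value")
    } else {
      if (!ds_has(mv[[1]], "NumericValue")) {
        report <- add_violation(report, paste0(path, "/MeasuredValueSequence/NumericValue"),
                                "required-attribute", "numeric value missing")
      }
      report <- check_code_seq(report, mv[[1]], "MeasurementUnitsCodeSequence",
                               paste0(path, "/MeasuredValueSequence/MeasurementUnitsCodeSequence"))
    }
  }
  if (vt == "CODE") {
    report <- check_code_seq(report, item, "ConceptCodeSequence",
                             paste0(path, "/ConceptCodeSequence"))
  }
  if (vt %in% c("SCOORD", "SCOORD3D")) {
    gd <- ds_get(item, "GraphicData")
    gt <- ds_get(item, "GraphicType")
    dim_n <- if (vt == "SCOORD") 2 else 3
    if (is.null(gd) || is.null(gt)) {
      report <- add_violation(report, paste0(path, "/GraphicData"),
                              "required-attribute",
                              "graphic type and data are required")
    } else if (length(gd) %% dim_n != 0) {
      report <- add_violation(report, paste0(path, "/GraphicData"),
                              "graphic-data-length",
                              sprintf("length must be a multiple of %d", dim_n))
    } else if (vt == "SCOORD3D") {
      pts <- matrix(gd, ncol = 3, byrow = TRUE)
      msg <- check_scoord3d_geometry(gt, pts)
      if (!is.null(msg)) {
        report <- add_violation(report, paste0(path, "/GraphicData"),
                                "graphic-geometry", msg)
      }
      if (!ds_has(item, "ReferencedFrameOfReferenceUID")) {
        report <- add_violation(report,
                                paste0(path, "/ReferencedFrameOfReferenceUID"),
                                "required-attribute",
                                "SCOORD3D requires a frame of reference UID")
      }
    }
  }
  children <- ds_get(item, "ContentSequence", list())
  for (i in seq_along(children)) {
    report <- validate_content_item(report, children[[i]],
                                    sprintf("%s/ContentSequence[%d]", path, i),
                                    allowed)
  }
  report
}

validate_sr <- function(report, ds, kind) {
  sop_class <- if (kind == "comprehensive_sr") DCM_UID$comprehensive_sr
               else DCM_UID$comprehensive_3d_sr
  allowed <- if (kind == "comprehensive_sr") SR_VALUE_TYPES_2D
             else SR_VALUE_TYPES_3D
  report <- validate_common(report, ds, sop_class, "SR")
  report <- require_attrs(report, ds, c(
    "CompletionFlag", "VerificationFlag", "ContentDate", "ContentTime"))
  if (!ds_has(ds, "ValueType")) {
    return(add_violation(report, "ValueType", "required-attribute",
                         "document has no root content item"))
  }
  if (!identical(ds_get(ds, "ValueType"), "CONTAINER")) {
    report <- add_violation(report, "ValueType", "root-type",
                            "document root must be a CONTAINER")
  }
  cts <- ds_get(ds, "ContentTemplateSequence")
  if (is.null(cts) || !ds_has(cts[[1]], "TemplateIdentifier")) {
    report <- add_violation(report, "ContentTemplateSequence/TemplateIdentifier",
                            "required-attribute",
                            "root template identification missing")
  }
  validate_content_item(report, ds, "", allowed, is_root = TRUE)
}

# --- bulk annotations ----------------------------------------------------

validate_ann <- function(report, ds) {
  report <- validate_common(report, ds, DCM_UID$bulk_annotations, "ANN")
  ct <- ds_get(ds, "AnnotationCoordinateType")
  if (is.null(ct) || !ct %in% c("2D", "3D")) {
    report <- add_violation(report, "AnnotationCoordinateType", "enum",
                            "must be 2D or 3D")
  }
  dim_n <- if (identical(ct, "3D")) 3 else 2
  groups <- ds_get(ds, "AnnotationGroupSequence")
  if (is.null(groups) || length(groups) == 0) {
    return(add_violation(report, "AnnotationGroupSequence", "required-attribute",
                         "at least one annotation group is required"))
  }
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    p <- sprintf("AnnotationGroupSequence[%d]", i)
    report <- require_attrs(report, g, c(
      "AnnotationGroupNumber", "AnnotationGroupUID", "AnnotationGroupLabel",
      "AnnotationGroupGenerationType", "GraphicType", "NumberOfAnnotations",
      "PointCoordinatesData"), prefix = paste0(p, "/"))
    report <- check_code_seq(report, g, "AnnotationPropertyCategoryCodeSequence",
                             paste0(p, "/AnnotationPropertyCategoryCodeSequence"))
    report <- check_code_seq(report, g, "AnnotationPropertyTypeCodeSequence",
                             paste0(p, "/AnnotationPropertyTypeCodeSequence"))
    gt <- ds_get(g, "GraphicType")
    pd <- ds_get(g, "PointCoordinatesData")
    n_ann <- ds_get(g, "NumberOfAnnotations")
    if (!is.null(gt) && !gt %in% ANN_GRAPHIC_TYPES) {
      report <- add_violation(report, paste0(p, "/GraphicType"), "enum",
                              "invalid graphic type")
    }
    if (!is.null(pd)) {
      if (length(pd) %% dim_n != 0) {
        report <- add_violation(report, paste0(p, "/PointCoordinatesData"),
                                "point-data-length",
                                sprintf("length must be a multiple of %d", dim_n))
      }
      if (!is.null(gt) && !is.na(ANN_FIXED_VERTICES[gt]) && !is.null(n_ann)) {
        expected <- n_ann * ANN_FIXED_VERTICES[[gt]] * dim_n
        if (length(pd) != expected) {
          report <- add_violation(report, paste0(p, "/PointCoordinatesData"),
                                  "point-data-length",
                                  sprintf("expected %d values, found %d",
                                          expected, length(pd)))
        }
      }
      offs <- ds_get(g, "LongPrimitivePointIndexList")
      if (!is.null(offs)) {
        if (offs[1] != 1 || any(diff(offs) <= 0) || any(offs > length(pd))) {
          report <- add_violation(report, paste0(p, "/LongPrimitivePointIndexList"),
                                  "index-offsets",
                                  "offsets must start at 1, increase strictly and stay in range")
        }
      } else if (!is.null(gt) && is.na(ANN_FIXED_VERTICES[gt])) {
        report <- add_violation(report, paste0(p, "/LongPrimitivePointIndexList"),
                                "required-attribute",
                                "variable-length graphic types require index offsets")
      }
    }
  }
  report
}

#' Validate a dataset against an IOD schema
#'
#' Deterministic constructor-style validation: checks required attributes,
#' enumerated values, segment numbering, pixel-data length, content-item
#' value types (SCOORD3D is rejected in non-3D Comprehensive SR documents),
#' graphic-type vertex rules (including POLYGON ring closure) and
#' annotation-group index offsets. Every builder in this package produces
#' objects that yield an empty report.
#'
#' @param dataset a `dcm_dataset`.
#' @param iod_id one of `"segmentation"`, `"comprehensive_sr"`,
#'   `"comprehensive_3d_sr"`, `"bulk_annotations"`.
#' @return a `validation_report` data.frame with columns `path`, `rule`,
#'   `severity`, `message`; zero rows mean the object conforms.
#' @export
validate_sop <- function(dataset, iod_id) {
  if (!is.character(iod_id) || length(iod_id) != 1 ||
      !iod_id %in% c("segmentation", "comprehensive_sr",
                     "comprehensive_3d_sr", "bulk_annotations")) {
    stop("unknown iod_id: ", paste(iod_id, collapse = ","), call. = FALSE)
  }
  report <- new_report()
  switch(iod_id,
    segmentation = validate_segmentation(report, dataset),
    comprehensive_sr = validate_sr(report, dataset, "comprehensive_sr"),
    comprehensive_3d_sr = validate_sr(report, dataset, "comprehensive_3d_sr"),
    bulk_annotations = validate_ann(report, dataset))
}

# sanity checks for generated source images (used by the fixture module)
check_source_image <- function(ds) {
  report <- new_report()
  report <- require_attrs(report, ds, c(
    "SOPClassUID", "SOPInstanceUID", "StudyInstanceUID", "SeriesInstanceUID",
    "PatientID", "Modality", "Rows", "Columns", "FrameOfReferenceUID",
    "PixelData", "BitsAllocated"))
  if (ds_has(ds, "SOPInstanceUID") && !is_valid_uid(ds_get(ds, "SOPInstanceUID"))) {
    report <- add_violation(report, "SOPInstanceUID", "uid-syntax",
                            "invalid UID syntax")
  }
  if (identical(ds_get(ds, "SOPClassUID"), DCM_UID$sm_image)) {
    report <- require_attrs(report, ds, c(
      "TotalPixelMatrixRows", "TotalPixelMatrixColumns", "ImageOrientationSlide",
      "ContainerIdentifier", "SpecimenDescriptionSequence", "NumberOfFrames",
      "PerFrameFunctionalGroupsSequence"))
  } else {
    report <- require_attrs(report, ds, c(
      "ImagePositionPatient", "ImageOrientationPatient", "PixelSpacing"))
  }
  report
}
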