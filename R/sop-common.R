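# Shared machinery for derived objects: UID generation, harvesting of
# patient/study/specimen context from source images, evidence references.

#' Generate a DICOM unique identifier
#'
#' UIDs use the UUID-derived `"2.25.<decimal>"` form so no registered
#' organisation root is needed: 16 random bytes are converted to their
#' decimal representation. Randomness comes from the R RNG, so UID streams
#' are reproducible under `set.seed()`.
#'
#' @param prefix dotted-decimal prefix, default `"2.25."`.
#' @return a UID string, at most 64 characters, matching
#'   `^[0-9]+(\.[0-9]+)*$` with no leading zeros in any component.
#' @export
generate_uid <- function(prefix = "2.25.") {
  bytes <- sample.int(256L, 16L, replace = TRUE) - 1L
  if (all(bytes == 0L)) bytes[16] <- 1L
  # base-256 digit vector -> decimal string by repeated division
  digits <- integer(0)
  while (length(bytes) > 0 && any(bytes != 0L)) {
    quotient <- integer(length(bytes))
    rem <- 0L
    for (i in seq_along(bytes)) {
      cur <- rem * 256L + bytes[i]
      quotient[i] <- cur %/% 10L
      rem <- cur %% 10L
    }
    digits <- c(rem, digits)
    while (length(quotient) > 0 && quotient[1] == 0L) quotient <- quotient[-1]
    bytes <- quotient
  }
  if (length(digits) == 0) digits <- 0L
  uid <- paste0(prefix, paste(digits, collapse = ""))
  stopifnot(nchar(uid) <= 64)
  uid
}

is_valid_uid <- function(uid) {
  is.character(uid) && length(uid) == 1 && !is.na(uid) &&
    nchar(uid) >= 1 && nchar(uid) <= 64 &&
    grepl("^[0-9]+(\\.[0-9]+)*$", uid) &&
    !grepl("(^|\\.)0[0-9]", uid)
}

PATIENT_ATTRS <- c("PatientID", "PatientName", "PatientBirthDate", "PatientSex")
STUDY_ATTRS <- c("StudyInstanceUID", "StudyDate", "StudyTime",
                 "AccessionNumber", "ReferringPhysicianName", "StudyID",
                 "StudyDescription")
SPECIMEN_ATTRS <- c("ContainerIdentifier", "SpecimenDescriptionSequence")

#' Harvest patient/study/specimen context from source images
#'
#' Copies the descriptive metadata that derived objects must share with
#' their source images: the Patient and General Study module attributes,
#' and - for slide-based sources - the Specimen module attributes. All
#' sources must belong to one study and one patient.
#'
#' @param source_datasets non-empty list of source image `dcm_dataset`s.
#' @return an object of class `context_metadata` with fields `patient`,
#'   `study`, `specimen` (each a named list of copied elements) and
#'   `frame_of_reference_uid`.
#' @export
harvest_context <- function(source_datasets) {
  if (!is.list(source_datasets) || length(source_datasets) == 0) {
    stop("at least one source dataset is required", call. = FALSE)
  }
  study_uids <- unique(vapply(source_datasets, ds_get, character(1),
                              keyword = "StudyInstanceUID"))
  patient_ids <- unique(vapply(source_datasets, ds_get, character(1),
                               keyword = "PatientID"))
  if (length(study_uids) > 1) {
    stop("source datasets span multiple studies: ",
         paste(study_uids, collapse = ", "), call. = FALSE)
  }
  if (length(patient_ids) > 1) {
    stop("source datasets span multiple patients: ",
         paste(patient_ids, collapse = ", "), call. = FALSE)
  }
  if (!is_valid_uid(study_uids)) {
    stop("source study instance UID is not valid UID syntax: ", study_uids,
         call. = FALSE)
  }
  src <- source_datasets[[1]]
  copy_attrs <- function(attrs) {
    out <- list()
    for (kw in attrs) if (ds_has(src, kw)) out[[kw]] <- ds_get(src, kw)
    out
  }
  structure(list(
    patient = copy_attrs(PATIENT_ATTRS),
    study = copy_attrs(STUDY_ATTRS),
    specimen = if (ds_has(src, "ContainerIdentifier")) copy_attrs(SPECIMEN_ATTRS),
    frame_of_reference_uid = ds_get(src, "FrameOfReferenceUID")
  ), class = "context_metadata")
}

# Write harvested context into a derived dataset.
apply_context <- function(ds, context) {
  stopifnot(inherits(context, "context_metadata"))
  for (grp in list(context$patient, context$study, context$specimen)) {
    for (kw in names(grp)) ds <- ds_set(ds, kw, grp[[kw]])
  }
  ds
}

#' Build evidence references for a set of source images
#'
#' Groups the source instances study -> series -> instance; every input
#' instance is referenced exactly once (duplicates are dropped with a
#' warning).
#'
#' @inheritParams harvest_context
#' @return a list with one `evidence_reference` per study (always length 1:
#'   sources must share a study), each holding `study_uid` and a list of
#'   `series`, each with `series_uid` and `instances` (SOP class/instance
#'   UID pairs).
#' @export
build_evidence <- function(source_datasets) {
  context <- harvest_context(source_datasets)  # reuses consistency checks
  seen <- character(0)
  series <- list()
  for (src in source_datasets) {
    sop_uid <- ds_get(src, "SOPInstanceUID")
    if (sop_uid %in% seen) {
      warning("duplicate source instance dropped: ", sop_uid, call. = FALSE)
      next
    }
    seen <- c(seen, sop_uid)
    ser_uid <- ds_get(src, "SeriesInstanceUID")
    if (is.null(series[[ser_uid]])) {
      series[[ser_uid]] <- list(series_uid = ser_uid, instances = list())
    }
    series[[ser_uid]]$instances[[length(series[[ser_uid]]$instances) + 1]] <-
      list(sop_class_uid = ds_get(src, "SOPClassUID"),
           sop_instance_uid = sop_uid)
  }
  list(structure(list(study_uid = context$study$StudyInstanceUID,
                      series = unname(series)),
                 class = "evidence_reference"))
}

# CurrentRequestedProcedureEvidenceSequence items for an SR document.
evidence_to_seq <- function(evidence) {
  lapply(evidence, function(ev) {
    dcm_dataset(
      StudyInstanceUID = ev$study_uid,
      ReferencedSeriesSequence = lapply(ev$series, function(se) {
        dcm_dataset(
          SeriesInstanceUID = se$series_uid,
          ReferencedSOPSequence = lapply(se$instances, function(inst) {
            dcm_dataset(ReferencedSOPClassUID = inst$sop_class_uid,
                        ReferencedSOPInstanceUID = inst$sop_instance_uid)
          })
        )
      })
    )
  })
}

# ReferencedSeriesSequence items (image-level reference idiom used by SEG).
evidence_to_series_seq <- function(evidence) {
  unlist(lapply(evidence, function(ev) {
    lapply(ev$series, function(se) {
      dcm_dataset(
        SeriesInstanceUID = se$series_uid,
        ReferencedSOPSequence = lapply(se$instances, function(inst) {
          dcm_dataset(ReferencedSOPClassUID = inst$sop_class_uid,
                      ReferencedSOPInstanceUID = inst$sop_instance_uid)
        })
      )
    })
  }), recursive = FALSE)
}

# Shared skeleton for derived objects: context + identifiers + equipment.
derived_dataset_skeleton <- function(context, sop_class_uid, modality,
                                     series_number = 1L,
                                     manufacturer = "dcmannot project",
                                     model_name = "dcmannot",
                                     software_version = IMPLEMENTATION_VERSION) {
  ds <- dcm_dataset(
    SpecificCharacterSet = "ISO_IR 192",
    SOPClassUID = sop_class_uid,
    SOPInstanceUID = generate_uid(),
    SeriesInstanceUID = generate_uid(),
    SeriesNumber = series_number,
    InstanceNumber = 1L,
    Modality = modality,
    Manufacturer = manufacturer,
    ManufacturerModelName = model_name,
    SoftwareVersions = software_version,
    ContentDate = format(Sys.Date(), "%Y%m%d"),
    ContentTime = format(Sys.time(), "%H%M%S")
  )
  apply_context(ds, context)
}
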