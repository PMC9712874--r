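#' SR content items
#'
#' Structured Report documents are trees of *content items*: typed
#' name-value pairs. The name is always a [coded_concept()]; the value type
#' determines the payload (a code, a number with unit, text, a UID, an
#' image reference, 2D or 3D spatial coordinates, or a container of further
#' items). Non-root items carry a relationship to their parent; only
#' CONTAINER items have children.
#'
#' @name sr_items
NULL

SR_RELATIONSHIPS <- c("CONTAINS", "HAS CONCEPT MOD", "HAS OBS CONTEXT",
                      "HAS ACQ CONTEXT", "INFERRED FROM", "SELECTED FROM")

new_sr_item <- function(value_type, name, relationship, fields = list()) {
  stopifnot(inherits(name, "coded_concept"))
  if (!is.null(relationship) && !relationship %in% SR_RELATIONSHIPS) {
    stop("invalid relationship type: ", relationship, call. = FALSE)
  }
  structure(c(list(value_type = value_type, name = name,
                   relationship = relationship), fields),
            class = c(paste0("sr_", tolower(value_type), "_item"), "sr_item"))
}

#' @rdname sr_items
#' @param name concept name of the item (a [coded_concept()]).
#' @param children ordered list of child `sr_item`s (CONTAINER only).
#' @param relationship relationship to the parent item; `NULL` at the root.
#' @param template TID of the template the container instantiates (e.g.
#'   `"1500"`), or `NULL`.
#' @export
item_container <- function(name, children = list(), relationship = "CONTAINS",
                           template = NULL) {
  stopifnot(all(vapply(children, inherits, logical(1), what = "sr_item")))
  for (ch in children) {
    if (is.null(ch$relationship)) {
      stop("non-root content items must carry a relationship", call. = FALSE)
    }
  }
  new_sr_item("CONTAINER", name, relationship,
              list(children = children, template = template))
}

#' @rdname sr_items
#' @param value payload: a [coded_concept()] for CODE, numeric scalar for
#'   NUM, string for TEXT/DATETIME, a UID string for UIDREF.
#' @export
item_code <- function(name, value, relationship = "CONTAINS") {
  stopifnot(inherits(value, "coded_concept"))
  new_sr_item("CODE", name, relationship, list(value = value))
}

#' @rdname sr_items
#' @param unit UCUM unit as a [coded_concept()] (NUM only).
#' @export
item_num <- function(name, value, unit, relationship = "CONTAINS") {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value),
            inherits(unit, "coded_concept"))
  new_sr_item("NUM", name, relationship, list(value = as.numeric(value),
                                              unit = unit))
}

#' @rdname sr_items
#' @export
item_text <- function(name, value, relationship = "CONTAINS") {
  stopifnot(is.character(value), length(value) == 1)
  new_sr_item("TEXT", name, relationship, list(value = value))
}

#' @rdname sr_items
#' @export
item_uidref <- function(name, value, relationship = "CONTAINS") {
  stopifnot(is_valid_uid(value))
  new_sr_item("UIDREF", name, relationship, list(value = value))
}

#' @rdname sr_items
#' @export
item_datetime <- function(name, value, relationship = "CONTAINS") {
  stopifnot(is.character(value), length(value) == 1)
  new_sr_item("DATETIME", name, relationship, list(value = value))
}

SCOORD_TYPES <- c("POINT", "MULTIPOINT", "POLYLINE", "CIRCLE", "ELLIPSE")
SCOORD3D_TYPES <- c("POINT", "MULTIPOINT", "POLYLINE", "POLYGON", "ELLIPSE",
                    "ELLIPSOID")

#' @rdname sr_items
#' @param graphic_type geometry kind; SCOORD: POINT, MULTIPOINT, POLYLINE,
#'   CIRCLE, ELLIPSE; SCOORD3D: POINT, MULTIPOINT, POLYLINE, POLYGON,
#'   ELLIPSE, ELLIPSOID.
#' @param graphic_data N x 2 pixel `(column, row)` coordinates (SCOORD) or
#'   N x 3 mm coordinates (SCOORD3D).
#' @param referenced_sop_class_uid,referenced_sop_instance_uid image the 2D
#'   coordinates refer to.
#' @param referenced_frame optional frame number within that image.
#' @export
item_scoord <- function(name, graphic_type, graphic_data,
                        referenced_sop_class_uid, referenced_sop_instance_uid,
                        referenced_frame = NULL, relationship = "CONTAINS") {
  graphic_type <- match.arg(graphic_type, SCOORD_TYPES)
  graphic_data <- as_index_matrix(graphic_data)
  new_sr_item("SCOORD", name, relationship, list(
    graphic_type = graphic_type, graphic_data = graphic_data,
    referenced_sop_class_uid = referenced_sop_class_uid,
    referenced_sop_instance_uid = referenced_sop_instance_uid,
    referenced_frame = referenced_frame))
}

check_scoord3d_geometry <- function(graphic_type, graphic_data,
                                    planarity_tol_mm = 1e-3) {
  n <- nrow(graphic_data)
  if (graphic_type == "POINT" && n != 1) {
    return("POINT requires exactly 1 point")
  }
  if (graphic_type == "ELLIPSE" && n != 4) {
    return("ELLIPSE requires exactly 4 points")
  }
  if (graphic_type == "ELLIPSOID" && n != 6) {
    return("ELLIPSOID requires exactly 6 points")
  }
  if (graphic_type == "POLYGON") {
    if (n < 4 || any(graphic_data[1, ] != graphic_data[n, ])) {
      return("POLYGON must be a closed ring (first point repeated last)")
    }
    ok <- tryCatch({
      polygon_area_mm2(graphic_data, planarity_tol_mm = planarity_tol_mm)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(ok)) return(ok)
  }
  NULL
}

#' @rdname sr_items
#' @param frame_of_reference_uid UID of the 3D frame of reference (patient
#'   or slide coordinate system) the coordinates live in (SCOORD3D only).
#' @export
item_scoord3d <- function(name, graphic_type, graphic_data,
                          frame_of_reference_uid, relationship = "CONTAINS") {
  graphic_type <- match.arg(graphic_type, SCOORD3D_TYPES)
  graphic_data <- as_coord_matrix(graphic_data)
  msg <- check_scoord3d_geometry(graphic_type, graphic_data)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  stopifnot(is_valid_uid(frame_of_reference_uid))
  new_sr_item("SCOORD3D", name, relationship, list(
    graphic_type = graphic_type, graphic_data = graphic_data,
    frame_of_reference_uid = frame_of_reference_uid))
}

#' @rdname sr_items
#' @param sop_class_uid,sop_instance_uid referenced image object.
#' @param segments optional referenced segment number(s).
#' @param frames optional referenced frame number(s).
#' @export
item_image <- function(name, sop_class_uid, sop_instance_uid,
                       segments = NULL, frames = NULL,
                       relationship = "CONTAINS") {
  new_sr_item("IMAGE", name, relationship, list(
    sop_class_uid = sop_class_uid, sop_instance_uid = sop_instance_uid,
    segments = if (!is.null(segments)) as.integer(segments),
    frames = if (!is.null(frames)) as.integer(frames)))
}

# --- item <-> dataset ----------------------------------------------------

item_to_ds <- function(item) {
  ds <- dcm_dataset(ValueType = item$value_type,
                    ConceptNameCodeSequence = list(concept_to_ds(item$name)))
  if (!is.null(item$relationship)) {
    ds <- ds_set(ds, "RelationshipType", item$relationship)
  }
  children <- list()
  switch(item$value_type,
    CONTAINER = {
      ds <- ds_set(ds, "ContinuityOfContent", "SEPARATE")
      if (!is.null(item$template)) {
        ds <- ds_set(ds, "ContentTemplateSequence", list(
          dcm_dataset(MappingResource = "DCMR",
                      TemplateIdentifier = item$template)))
      }
      children <- item$children
    },
    CODE = { ds <- ds_set(ds, "ConceptCodeSequence", list(concept_to_ds(item$value))) },
    NUM = {
      ds <- ds_set(ds, "MeasuredValueSequence", list(dcm_dataset(
        NumericValue = item$value,
        MeasurementUnitsCodeSequence = list(concept_to_ds(item$unit)))))
    },
    TEXT = { ds <- ds_set(ds, "TextValue", item$value) },
    DATETIME = { ds <- ds_set(ds, "DateTime", item$value) },
    UIDREF = { ds <- ds_set(ds, "UID", item$value) },
    SCOORD = {
      ds <- ds_set(ds, "GraphicType", item$graphic_type)
      ds <- ds_set(ds, "GraphicData", as.numeric(t(item$graphic_data)))
      ref <- dcm_dataset(ReferencedSOPClassUID = item$referenced_sop_class_uid,
                         ReferencedSOPInstanceUID = item$referenced_sop_instance_uid)
      if (!is.null(item$referenced_frame)) {
        ref <- ds_set(ref, "ReferencedFrameNumber", item$referenced_frame)
      }
      sel <- dcm_dataset(RelationshipType = "SELECTED FROM",
                         ValueType = "IMAGE",
                         ConceptNameCodeSequence = list(concept_to_ds(
                           registry_lookup("DCM", "SourceOfMeasurement"))),
                         ReferencedSOPSequence = list(ref))
      ds <- ds_set(ds, "ContentSequence", list(sel))
    },
    SCOORD3D = {
      ds <- ds_set(ds, "GraphicType", item$graphic_type)
      ds <- ds_set(ds, "GraphicData", as.numeric(t(item$graphic_data)))
      ds <- ds_set(ds, "ReferencedFrameOfReferenceUID",
                   item$frame_of_reference_uid)
    },
    IMAGE = {
      ref <- dcm_dataset(ReferencedSOPClassUID = item$sop_class_uid,
                         ReferencedSOPInstanceUID = item$sop_instance_uid)
      if (!is.null(item$segments)) ref <- ds_set(ref, "ReferencedSegmentNumber",
                                                 item$segments)
      if (!is.null(item$frames)) ref <- ds_set(ref, "ReferencedFrameNumber",
                                               item$frames)
      ds <- ds_set(ds, "ReferencedSOPSequence", list(ref))
    },
    stop("unsupported value type: ", item$value_type, call. = FALSE)
  )
  if (length(children) > 0) {
    ds <- ds_set(ds, "ContentSequence", lapply(children, item_to_ds))
  }
  ds
}

ds_to_item <- function(ds) {
  vt <- ds_get(ds, "ValueType")
  name <- ds_to_concept(ds_get(ds, "ConceptNameCodeSequence")[[1]])
  rel <- ds_get(ds, "RelationshipType")
  content <- ds_get(ds, "ContentSequence", list())
  switch(vt,
    CONTAINER = {
      tpl <- NULL
      cts <- ds_get(ds, "ContentTemplateSequence")
      if (!is.null(cts)) tpl <- ds_get(cts[[1]], "TemplateIdentifier")
      item_container(name, children = lapply(content, ds_to_item),
                     relationship = rel, template = tpl)
    },
    CODE = item_code(name, ds_to_concept(ds_get(ds, "ConceptCodeSequence")[[1]]),
                     relationship = rel),
    NUM = {
      mv <- ds_get(ds, "MeasuredValueSequence")[[1]]
      item_num(name, ds_get(mv, "NumericValue"),
               ds_to_concept(ds_get(mv, "MeasurementUnitsCodeSequence")[[1]]),
               relationship = rel)
    },
    TEXT = item_text(name, ds_get(ds, "TextValue"), relationship = rel),
    DATETIME = item_datetime(name, ds_get(ds, "DateTime"), relationship = rel),
    UIDREF = item_uidref(name, ds_get(ds, "UID"), relationship = rel),
    SCOORD = {
      gd <- matrix(ds_get(ds, "GraphicData"), ncol = 2, byrow = TRUE)
      ref <- ds_get(content[[1]], "ReferencedSOPSequence")[[1]]
      item_scoord(name, ds_get(ds, "GraphicType"), gd,
                  ds_get(ref, "ReferencedSOPClassUID"),
                  ds_get(ref, "ReferencedSOPInstanceUID"),
                  referenced_frame = ds_get(ref, "ReferencedFrameNumber"),
                  relationship = rel)
    },
    SCOORD3D = {
      gd <- matrix(ds_get(ds, "GraphicData"), ncol = 3, byrow = TRUE)
      item_scoord3d(name, ds_get(ds, "GraphicType"), gd,
                    ds_get(ds, "ReferencedFrameOfReferenceUID"),
                    relationship = rel)
    },
    IMAGE = {
      ref <- ds_get(ds, "ReferencedSOPSequence")[[1]]
      segs <- ds_get(ref, "ReferencedSegmentNumber")
      item_image(name, ds_get(ref, "ReferencedSOPClassUID"),
                 ds_get(ref, "ReferencedSOPInstanceUID"),
                 segments = segs,
                 frames = ds_get(ref, "ReferencedFrameNumber"),
                 relationship = rel)
    },
    stop("unsupported value type in document: ", vt, call. = FALSE)
  )
}

# --- TID 1500 ------------------------------------------------------------

#' Observation context of a measurement report
#'
#' @param observer_name optional person observer name.
#' @param device_uid optional device observer UID.
#' @return object of class `observation_context`.
#' @export
observation_context <- function(observer_name = NULL, device_uid = NULL) {
  structure(list(observer_name = observer_name, device_uid = device_uid),
            class = "observation_context")
}

#' A single measurement: name, value, UCUM unit
#'
#' @param name measurement concept (a [coded_concept()], e.g. Area).
#' @param value numeric value.
#' @param unit UCUM unit concept.
#' @return a NUM `sr_item`.
#' @export
measurement <- function(name, value, unit) item_num(name, value, unit)

#' A measurement group: one annotated entity
#'
#' Groups a tracked finding with its region of interest, measurements and
#' qualitative evaluations. `kind` selects the sub-template: `"image"`
#' (whole-image annotation, no region), `"planar"` (a 2D region or a
#' single-plane 3D region) or `"volumetric"` (multi-plane regions or
#' segment references).
#'
#' @param tracking_id,tracking_uid tracking identifier string and UID.
#' @param finding_type [coded_concept()] describing the finding (e.g.
#'   Tumor).
#' @param finding_sites list of [coded_concept()] anatomic sites.
#' @param region an SCOORD, SCOORD3D or IMAGE (segment reference) `sr_item`,
#'   or a list of them (volumetric only); `NULL` for image-level groups.
#' @param measurements list of NUM items (see [measurement()]).
#' @param evaluations list of CODE items (qualitative evaluations).
#' @param kind group sub-template.
#' @return object of class `measurement_group`.
#' @export
measurement_group <- function(tracking_id, tracking_uid, finding_type,
                              finding_sites = list(), region = NULL,
                              measurements = list(), evaluations = list(),
                              kind = c("planar", "volumetric", "image")) {
  kind <- match.arg(kind)
  stopifnot(is.character(tracking_id), is_valid_uid(tracking_uid),
            inherits(finding_type, "coded_concept"))
  regions <- if (is.null(region)) list()
             else if (inherits(region, "sr_item")) list(region)
             else region
  vts <- vapply(regions, function(r) r$value_type, character(1))
  if (!all(vts %in% c("SCOORD", "SCOORD3D", "IMAGE"))) {
    stop("regions must be SCOORD, SCOORD3D or IMAGE items", call. = FALSE)
  }
  if (any(vts == "SCOORD") && any(vts == "SCOORD3D")) {
    stop("a group cannot mix 2D (SCOORD) and 3D (SCOORD3D) regions",
         call. = FALSE)
  }
  if (kind == "image" && length(regions) > 0) {
    stop("image-level groups carry no region", call. = FALSE)
  }
  if (kind != "image" && length(regions) == 0) {
    stop("planar and volumetric groups require a region", call. = FALSE)
  }
  if (kind == "planar" && length(regions) > 1) {
    stop("planar groups reference a single region", call. = FALSE)
  }
  stopifnot(all(vapply(finding_sites, inherits, logical(1), "coded_concept")),
            all(vapply(measurements, function(m)
              inherits(m, "sr_item") && m$value_type == "NUM", logical(1))),
            all(vapply(evaluations, function(e)
              inherits(e, "sr_item") && e$value_type == "CODE", logical(1))))
  structure(list(tracking_id = tracking_id, tracking_uid = tracking_uid,
                 finding_type = finding_type, finding_sites = finding_sites,
                 regions = regions, measurements = measurements,
                 evaluations = evaluations, kind = kind),
            class = "measurement_group")
}

group_to_item <- function(group) {
  children <- list(
    item_text(registry_lookup("DCM", "TrackingIdentifier"),
              group$tracking_id, relationship = "HAS OBS CONTEXT"),
    item_uidref(registry_lookup("DCM", "TrackingUniqueIdentifier"),
                group$tracking_uid, relationship = "HAS OBS CONTEXT"),
    item_code(registry_lookup("DCM", "Finding"), group$finding_type,
              relationship = "CONTAINS")
  )
  for (site in group$finding_sites) {
    children <- c(children, list(
      item_code(registry_lookup("SCT", "FindingSite"), site,
                relationship = "HAS CONCEPT MOD")))
  }
  for (r in group$regions) {
    r$relationship <- "CONTAINS"
    children <- c(children, list(r))
  }
  children <- c(children, lapply(group$measurements, function(m) {
    m$relationship <- "CONTAINS"; m
  }))
  children <- c(children, lapply(group$evaluations, function(e) {
    e$relationship <- "CONTAINS"; e
  }))
  item_container(registry_lookup("DCM", "MeasurementGroup"),
                 children = children, relationship = "CONTAINS")
}

#' Build a TID 1500 Measurement Report content tree
#'
#' Produces the deterministic document tree of the "Measurement Report"
#' template: a root CONTAINER carrying template identifier `"1500"`, the
#' observation-context and procedure items, and one sub-container per
#' measurement group with its tracking identifiers, finding type and sites,
#' region, measurements and qualitative evaluations. Rebuilding from
#' identical inputs yields a byte-identical encoding.
#'
#' @param context an [observation_context()].
#' @param procedure [coded_concept()] for the procedure reported.
#' @param groups list of [measurement_group()]s (may be empty).
#' @return the root `sr_item` (CONTAINER, template `"1500"`).
#' @export
build_measurement_report <- function(context = observation_context(),
                                     procedure, groups = list()) {
  stopifnot(inherits(context, "observation_context"),
            inherits(procedure, "coded_concept"),
            all(vapply(groups, inherits, logical(1), "measurement_group")))
  children <- list(
    item_code(registry_lookup("DCM", "LanguageOfContentItemAndDescendants"),
              coded_concept("en", "RFC5646", "English"),
              relationship = "HAS CONCEPT MOD"))
  if (!is.null(context$observer_name)) {
    children <- c(children, list(
      item_text(registry_lookup("DCM", "PersonObserverName"),
                context$observer_name, relationship = "HAS OBS CONTEXT")))
  }
  if (!is.null(context$device_uid)) {
    children <- c(children, list(
      item_uidref(registry_lookup("DCM", "DeviceObserverUID"),
                  context$device_uid, relationship = "HAS OBS CONTEXT")))
  }
  children <- c(children, list(
    item_code(registry_lookup("DCM", "ProcedureReported"), procedure,
              relationship = "HAS CONCEPT MOD"),
    item_container(registry_lookup("DCM", "ImagingMeasurements"),
                   children = lapply(groups, group_to_item),
                   relationship = "CONTAINS")))
  item_container(registry_lookup("DCM", "ImagingMeasurementReport"),
                 children = children, relationship = NULL, template = "1500")
}

# recursive scan for a value type within a tree
tree_contains_value_type <- function(item, vt) {
  if (item$value_type == vt) return(TRUE)
  if (item$value_type == "CONTAINER") {
    for (ch in item$children) if (tree_contains_value_type(ch, vt)) return(TRUE)
  }
  FALSE
}

#' Create a Comprehensive (3D) SR document from a content tree
#'
#' @param tree root `sr_item` (see [build_measurement_report()]).
#' @param evidence evidence references from [build_evidence()].
#' @param context harvested [harvest_context()] metadata.
#' @param kind `"comprehensive"` or `"comprehensive_3d"`. Comprehensive
#'   (non-3D) documents must not contain SCOORD3D items; the 3D variant
#'   exists precisely to carry them.
#' @param series_number series number of the derived series.
#' @return a `dcm_dataset` passing [validate_sop()] for the matching IOD.
#' @export
create_sr_document <- function(tree, evidence, context,
                               kind = c("comprehensive_3d", "comprehensive"),
                               series_number = 20L) {
  kind <- match.arg(kind)
  stopifnot(inherits(tree, "sr_item"), tree$value_type == "CONTAINER")
  if (kind == "comprehensive" && tree_contains_value_type(tree, "SCOORD3D")) {
    stop("value type SCOORD3D is not permitted in a Comprehensive SR; ",
         "use kind = 'comprehensive_3d'", call. = FALSE)
  }
  sop_class <- if (kind == "comprehensive") DCM_UID$comprehensive_sr
               else DCM_UID$comprehensive_3d_sr
  ds <- derived_dataset_skeleton(context, sop_class, "SR",
                                 series_number = series_number)
  root <- item_to_ds(tree)
  for (tag in names(root)) ds[[tag]] <- root[[tag]]
  ds <- ds_set(ds, "CompletionFlag", "COMPLETE")
  ds <- ds_set(ds, "VerificationFlag", "UNVERIFIED")
  ds <- ds_set(ds, "CurrentRequestedProcedureEvidenceSequence",
               evidence_to_seq(evidence))
  ds
}

#' Extract the content tree of an SR document
#'
#' @param sr_dataset an SR `dcm_dataset` (e.g. from [read_dicom()]).
#' @return the root `sr_item`.
#' @export
sr_document_tree <- function(sr_dataset) {
  if (!ds_has(sr_dataset, "ValueType")) {
    stop("dataset carries no SR content", call. = FALSE)
  }
  ds_to_item(sr_dataset)
}

# --- queries -------------------------------------------------------------

#' Find content items in a document tree
#'
#' Walks the children of `root` (depth-first, pre-order, so results are in
#' document order) and returns the items matching all supplied filters,
#' each with the child-index path from the root.
#'
#' @param root a CONTAINER `sr_item`.
#' @param name filter on the concept name ([concepts_equal()]).
#' @param value_type filter on the value type string.
#' @param relationship filter on the relationship type.
#' @param recursive descend into nested containers; if `FALSE` only direct
#'   children are examined.
#' @return list of `list(item =, path =)`, where `path` is an integer
#'   vector of child indices.
#' @export
find_content_items <- function(root, name = NULL, value_type = NULL,
                               relationship = NULL, recursive = TRUE) {
  stopifnot(inherits(root, "sr_item"), root$value_type == "CONTAINER")
  out <- list()
  walk <- function(item, path) {
    for (i in seq_along(item$children)) {
      ch <- item$children[[i]]
      p <- c(path, i)
      keep <- TRUE
      if (!is.null(name) && !suppressWarnings(concepts_equal(ch$name, name))) keep <- FALSE
      if (keep && !is.null(value_type) && ch$value_type != value_type) keep <- FALSE
      if (keep && !is.null(relationship) &&
          !identical(ch$relationship, relationship)) keep <- FALSE
      if (keep) out[[length(out) + 1]] <<- list(item = ch, path = p)
      if (recursive && ch$value_type == "CONTAINER") walk(ch, p)
    }
  }
  walk(root, integer(0))
  out
}

item_to_group <- function(container) {
  ids <- find_content_items(container, recursive = FALSE)
  tracking_id <- NULL; tracking_uid <- NULL; finding <- NULL
  sites <- list(); regions <- list(); meas <- list(); evals <- list()
  dcm_tracking_id <- registry_lookup("DCM", "TrackingIdentifier")
  dcm_tracking_uid <- registry_lookup("DCM", "TrackingUniqueIdentifier")
  dcm_finding <- registry_lookup("DCM", "Finding")
  sct_site <- registry_lookup("SCT", "FindingSite")
  for (e in ids) {
    it <- e$item
    if (it$value_type == "TEXT" &&
        suppressWarnings(concepts_equal(it$name, dcm_tracking_id))) {
      tracking_id <- it$value
    } else if (it$value_type == "UIDREF" &&
               suppressWarnings(concepts_equal(it$name, dcm_tracking_uid))) {
      tracking_uid <- it$value
    } else if (it$value_type == "CODE" &&
               suppressWarnings(concepts_equal(it$name, dcm_finding))) {
      finding <- it$value
    } else if (it$value_type == "CODE" &&
               suppressWarnings(concepts_equal(it$name, sct_site))) {
      sites[[length(sites) + 1]] <- it$value
    } else if (it$value_type %in% c("SCOORD", "SCOORD3D", "IMAGE")) {
      regions[[length(regions) + 1]] <- it
    } else if (it$value_type == "NUM") {
      meas[[length(meas) + 1]] <- it
    } else if (it$value_type == "CODE") {
      evals[[length(evals) + 1]] <- it
    }
  }
  kind <- if (length(regions) == 0) "image"
          else if (length(regions) == 1) "planar" else "volumetric"
  measurement_group(tracking_id = tracking_id, tracking_uid = tracking_uid,
                    finding_type = finding, finding_sites = sites,
                    region = if (length(regions)) regions,
                    measurements = meas, evaluations = evals, kind = kind)
}

#' Query the measurement groups of a TID 1500 document
#'
#' @param sr_document an SR `dcm_dataset` or the root `sr_item` of its tree;
#'   the root must carry template identifier `"1500"`.
#' @param finding_type,finding_site [coded_concept()] filters
#'   (conjunctive, like all filters here).
#' @param tracking_uid tracking UID filter.
#' @param graphic_type filter on the graphic type of the group's region(s).
#' @return list of [measurement_group()]s in document order.
#' @export
get_measurement_groups <- function(sr_document, finding_type = NULL,
                                   finding_site = NULL, tracking_uid = NULL,
                                   graphic_type = NULL) {
  root <- if (inherits(sr_document, "sr_item")) sr_document
          else sr_document_tree(sr_document)
  if (!identical(root$template, "1500")) {
    stop("document root does not instantiate template 1500", call. = FALSE)
  }
  meas_containers <- find_content_items(
    root, name = registry_lookup("DCM", "ImagingMeasurements"),
    value_type = "CONTAINER", recursive = FALSE)
  groups <- list()
  for (mc in meas_containers) {
    gcs <- find_content_items(
      mc$item, name = registry_lookup("DCM", "MeasurementGroup"),
      value_type = "CONTAINER", recursive = FALSE)
    groups <- c(groups, lapply(gcs, function(g) item_to_group(g$item)))
  }
  keep <- vapply(groups, function(g) {
    if (!is.null(finding_type) &&
        !suppressWarnings(concepts_equal(g$finding_type, finding_type))) return(FALSE)
    if (!is.null(finding_site)) {
      if (!any(vapply(g$finding_sites, function(s)
        suppressWarnings(concepts_equal(s, finding_site)), logical(1)))) return(FALSE)
    }
    if (!is.null(tracking_uid) && !identical(g$tracking_uid, tracking_uid)) {
      return(FALSE)
    }
    if (!is.null(graphic_type)) {
      gts <- vapply(g$regions, function(r) {
        if (is.null(r$graphic_type)) "" else r$graphic_type
      }, character(1))
      if (!any(gts == graphic_type)) return(FALSE)
    }
    TRUE
  }, logical(1))
  groups[keep]
}

#' Filter the measurements / qualitative evaluations of a group
#'
#' @param group a [measurement_group()].
#' @param name optional concept-name filter; all entries when absent.
#' @return `get_measurements`: list of NUM items (value + unit);
#'   `get_qualitative_evaluations`: list of CODE items.
#' @export
get_measurements <- function(group, name = NULL) {
  stopifnot(inherits(group, "measurement_group"))
  if (is.null(name)) return(group$measurements)
  Filter(function(m) suppressWarnings(concepts_equal(m$name, name)),
         group$measurements)
}

#' @rdname get_measurements
#' @export
get_qualitative_evaluations <- function(group, name = NULL) {
  stopifnot(inherits(group, "measurement_group"))
  if (is.null(name)) return(group$evaluations)
  Filter(function(e) suppressWarnings(concepts_equal(e$name, name)),
         group$evaluations)
}
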