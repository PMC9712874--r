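#' DICOM datasets in memory
#'
#' A `dcm_dataset` is a named list of data elements keyed by tag
#' (`"GGGGEEEE"` uppercase hex). Each element is a `list(vr =, value =)`;
#' sequence (SQ) elements hold an unnamed list of nested `dcm_dataset`
#' objects. String values are character vectors (one entry per value
#' multiplicity), numeric VRs (US, UL, SS, SL, FL, FD, DS, IS, OF, OL) are
#' numeric vectors, and OB/OW payloads are raw vectors.
#'
#' @param ... named initial attributes, `keyword = value`, resolved through
#'   the built-in dictionary.
#' @return an object of class `dcm_dataset`.
#' @export
dcm_dataset <- function(...) {
  ds <- structure(list(), class = "dcm_dataset")
  args <- list(...)
  for (kw in names(args)) ds <- ds_set(ds, kw, args[[kw]])
  ds
}

new_element <- function(vr, value) list(vr = vr, value = value)

#' Set a data element by keyword
#'
#' @param ds a `dcm_dataset`.
#' @param keyword attribute keyword from the built-in dictionary (or a raw
#'   `"GGGGEEEE"` tag for attributes outside it, in which case `vr` is
#'   required).
#' @param value element value; a list of `dcm_dataset` objects for SQ.
#' @param vr override the dictionary VR (needed e.g. for OW pixel data).
#' @return the modified dataset.
#' @export
ds_set <- function(ds, keyword, value, vr = NULL) {
  if (grepl("^[0-9A-F]{8}$", keyword)) {
    tag <- keyword
    if (is.null(vr)) {
      vr <- vr_for_tag(tag)
      if (is.null(vr)) stop("vr required for tag ", tag, call. = FALSE)
    }
  } else {
    tag <- lookup_tag(keyword)
    if (is.null(vr)) vr <- vr_for_tag(tag)
  }
  if (vr == "SQ" && !is.null(value)) {
    stopifnot(is.list(value))
  }
  ds[[tag]] <- new_element(vr, value)
  ds
}

#' Get a data element value by keyword
#'
#' @inheritParams ds_set
#' @param default value returned when the attribute is absent.
#' @return the element value, or `default`.
#' @export
ds_get <- function(ds, keyword, default = NULL) {
  tag <- if (grepl("^[0-9A-F]{8}$", keyword)) keyword else lookup_tag(keyword)
  el <- ds[[tag]]
  if (is.null(el)) default else el$value
}

#' Test presence of an attribute
#' @inheritParams ds_get
#' @return logical scalar.
#' @export
ds_has <- function(ds, keyword) {
  tag <- if (grepl("^[0-9A-F]{8}$", keyword)) keyword else lookup_tag(keyword)
  !is.null(ds[[tag]])
}

ds_remove <- function(ds, keyword) {
  tag <- if (grepl("^[0-9A-F]{8}$", keyword)) keyword else lookup_tag(keyword)
  ds[[tag]] <- NULL
  ds
}

#' @export
print.dcm_dataset <- function(x, ..., indent = 0) {
  pad <- strrep("  ", indent)
  tags <- sort(names(x), method = "radix")
  for (tag in tags) {
    el <- x[[tag]]
    kw <- unname(dcm_keyword_by_tag[tag])
    if (is.na(kw)) kw <- "?"
    if (el$vr == "SQ") {
      cat(sprintf("%s(%s,%s) SQ %s: %d item(s)\n", pad,
                  substr(tag, 1, 4), substr(tag, 5, 8), kw,
                  length(el$value)))
      for (item in el$value) print(item, indent = indent + 1)
    } else {
      v <- el$value
      shown <- if (is.raw(v)) {
        sprintf("<%d bytes>", length(v))
      } else {
        s <- paste(utils::head(v, 6), collapse = "\\")
        if (length(v) > 6) paste0(s, "\\...") else s
      }
      cat(sprintf("%s(%s,%s) %s %s: %s\n", pad,
                  substr(tag, 1, 4), substr(tag, 5, 8), el$vr, kw, shown))
    }
  }
  invisible(x)
}

# deep structural copy helpers -------------------------------------------

ds_sorted_tags <- function(ds) sort(names(ds), method = "radix")

# convenience: shallow equality of two datasets by serialized bytes
datasets_identical <- function(a, b) {
  identical(serialize_dataset(a), serialize_dataset(b))
}
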