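# DICOM Part-10 serialization: Explicit VR Little Endian only, which is the
# transfer syntax this package writes (and the only one it accepts on read).

IMPLEMENTATION_CLASS_UID <- "2.25.313898874684913734047020768752754652148"
IMPLEMENTATION_VERSION <- "dcmannot-0.1"

u16_raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32_raw <- function(x) {
  # values >= 2^31 (e.g. the undefined-length marker) via two half-words
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- (x - lo) / 65536
  writeBin(as.integer(c(lo, hi)), raw(), size = 2, endian = "little")
}

tag_raw <- function(tag) {
  g <- strtoi(substr(tag, 1, 4), 16L)
  e <- strtoi(substr(tag, 5, 8), 16L)
  c(u16_raw(g), u16_raw(e))
}

format_ds <- function(x) {
  s <- vapply(x, function(v) {
    out <- sprintf("%.8g", v)
    if (nchar(out) > 16) out <- sprintf("%.6g", v)
    out
  }, character(1))
  s
}

encode_value <- function(vr, value) {
  if (vr %in% c("OB", "OW", "UN")) {
    stopifnot(is.raw(value))
    out <- value
  } else if (vr == "OF" || vr == "FL") {
    out <- writeBin(as.numeric(value), raw(), size = 4, endian = "little")
  } else if (vr == "FD") {
    out <- writeBin(as.numeric(value), raw(), size = 8, endian = "little")
  } else if (vr %in% c("US", "SS")) {
    out <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else if (vr %in% c("UL", "SL", "OL")) {
    out <- do.call(c, lapply(as.numeric(value), u32_raw))
  } else if (vr == "AT") {
    out <- do.call(c, lapply(value, tag_raw))
  } else if (vr %in% VR_STRING) {
    s <- if (vr == "DS") format_ds(value)
         else if (vr == "IS") sprintf("%d", as.integer(value))
         else as.character(value)
    out <- charToRaw(paste(s, collapse = "\\"))
  } else {
    stop("cannot encode VR ", vr, call. = FALSE)
  }
  if (length(out) %% 2 == 1) {
    pad <- if (vr == "UI") as.raw(0L) else if (vr %in% VR_STRING) charToRaw(" ") else as.raw(0L)
    out <- c(out, pad)
  }
  out
}

serialize_element <- function(tag, el) {
  vr <- el$vr
  if (vr == "SQ") {
    body <- raw(0)
    for (item in el$value) {
      content <- serialize_dataset(item)
      body <- c(body, tag_raw("FFFEE000"), u32_raw(length(content)), content)
    }
    header <- c(tag_raw(tag), charToRaw("SQ"), as.raw(c(0, 0)),
                u32_raw(length(body)))
    return(c(header, body))
  }
  body <- encode_value(vr, el$value)
  if (vr %in% VR_LONG_FORM) {
    header <- c(tag_raw(tag), charToRaw(vr), as.raw(c(0, 0)),
                u32_raw(length(body)))
  } else {
    if (length(body) > 65534) stop("value too long for VR ", vr, call. = FALSE)
    header <- c(tag_raw(tag), charToRaw(vr), u16_raw(length(body)))
  }
  c(header, body)
}

serialize_dataset <- function(ds) {
  chunks <- lapply(ds_sorted_tags(ds), function(tag) {
    serialize_element(tag, ds[[tag]])
  })
  if (length(chunks) == 0) return(raw(0))
  do.call(c, chunks)
}

build_file_meta <- function(ds) {
  meta <- dcm_dataset(
    FileMetaInformationVersion = as.raw(c(0, 1)),
    MediaStorageSOPClassUID = ds_get(ds, "SOPClassUID"),
    MediaStorageSOPInstanceUID = ds_get(ds, "SOPInstanceUID"),
    TransferSyntaxUID = DCM_UID$explicit_vr_le,
    ImplementationClassUID = IMPLEMENTATION_CLASS_UID,
    ImplementationVersionName = IMPLEMENTATION_VERSION
  )
  body <- serialize_dataset(meta)
  glen <- dcm_dataset(FileMetaInformationGroupLength = length(body))
  c(serialize_dataset(glen), body)
}

#' Write a dataset as a DICOM Part-10 file
#'
#' Writes the 128-byte preamble, the `DICM` prefix, a file meta information
#' group and the dataset in Explicit VR Little Endian.
#'
#' @param ds a `dcm_dataset` with at least `SOPClassUID` and
#'   `SOPInstanceUID` set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(ds, path) {
  if (!ds_has(ds, "SOPClassUID") || !ds_has(ds, "SOPInstanceUID")) {
    stop("dataset lacks SOPClassUID/SOPInstanceUID", call. = FALSE)
  }
  out <- c(raw(128), charToRaw("DICM"), build_file_meta(ds),
           serialize_dataset(ds))
  writeBin(out, path)
  invisible(path)
}

# --- parsing -------------------------------------------------------------

rd_u16 <- function(r, i) {
  as.integer(r[i]) + 256L * as.integer(r[i + 1L])
}
rd_u32 <- function(r, i) {
  as.numeric(r[i]) + 256 * as.numeric(r[i + 1L]) +
    65536 * as.numeric(r[i + 2L]) + 16777216 * as.numeric(r[i + 3L])
}
rd_tag <- function(r, i) {
  sprintf("%04X%04X", rd_u16(r, i), rd_u16(r, i + 2L))
}

decode_value <- function(vr, bytes) {
  n <- length(bytes)
  if (vr %in% c("OB", "OW", "UN")) return(bytes)
  if (n == 0) return(if (vr %in% VR_STRING) character(0) else numeric(0))
  if (vr == "OF" || vr == "FL") {
    return(readBin(bytes, "numeric", n = n / 4, size = 4, endian = "little"))
  }
  if (vr == "FD") {
    return(readBin(bytes, "numeric", n = n / 8, size = 8, endian = "little"))
  }
  if (vr %in% c("US")) {
    return(readBin(bytes, "integer", n = n / 2, size = 2, signed = FALSE,
                   endian = "little"))
  }
  if (vr == "SS") {
    return(readBin(bytes, "integer", n = n / 2, size = 2, signed = TRUE,
                   endian = "little"))
  }
  if (vr %in% c("UL", "OL")) {
    k <- n / 4
    return(vapply(seq_len(k), function(j) rd_u32(bytes, 4 * (j - 1) + 1),
                  numeric(1)))
  }
  if (vr == "SL") {
    return(as.numeric(readBin(bytes, "integer", n = n / 4, size = 4,
                              endian = "little")))
  }
  if (vr == "AT") {
    k <- n / 4
    return(vapply(seq_len(k), function(j) rd_tag(bytes, 4 * (j - 1) + 1),
                  character(1)))
  }
  if (vr %in% VR_STRING) {
    while (length(bytes) > 0 &&
           (bytes[length(bytes)] == as.raw(0L) ||
            bytes[length(bytes)] == charToRaw(" "))) {
      bytes <- bytes[-length(bytes)]
    }
    if (length(bytes) == 0) return(character(0))
    s <- rawToChar(bytes)
    Encoding(s) <- "UTF-8"
    parts <- strsplit(s, "\\", fixed = TRUE)[[1]]
    parts <- sub("^ +", "", sub(" +$", "", parts))
    if (vr %in% c("DS", "IS")) return(as.numeric(parts))
    return(parts)
  }
  stop("cannot decode VR ", vr, call. = FALSE)
}

# Parse elements from `r` starting at `pos` (1-based) up to `end`.
# Returns list(ds = dcm_dataset, pos = next position).
parse_dataset <- function(r, pos, end, in_item = FALSE) {
  ds <- structure(list(), class = "dcm_dataset")
  while (pos <= end) {
    tag <- rd_tag(r, pos)
    if (tag == "FFFEE00D" || tag == "FFFEE0DD") {  # delimitation
      pos <- pos + 8
      if (in_item && tag == "FFFEE00D") break
      if (!in_item) break
      next
    }
    vr <- rawToChar(r[(pos + 4):(pos + 5)])
    if (vr %in% VR_LONG_FORM) {
      len <- rd_u32(r, pos + 8)
      pos <- pos + 12
    } else {
      len <- rd_u16(r, pos + 6)
      pos <- pos + 8
    }
    undefined <- len >= 4294967295
    if (vr == "SQ" || (vr == "UN" && undefined)) {
      items <- list()
      sq_end <- if (undefined) end else pos + len - 1
      while (pos <= sq_end) {
        it_tag <- rd_tag(r, pos)
        if (it_tag == "FFFEE0DD") { pos <- pos + 8; break }
        if (it_tag != "FFFEE000") stop("malformed sequence at offset ", pos,
                                       call. = FALSE)
        it_len <- rd_u32(r, pos + 4)
        pos <- pos + 8
        if (it_len >= 4294967295) {
          res <- parse_dataset(r, pos, end, in_item = TRUE)
        } else {
          res <- parse_dataset(r, pos, pos + it_len - 1, in_item = FALSE)
        }
        items[[length(items) + 1]] <- res$ds
        pos <- res$pos
      }
      ds[[tag]] <- new_element("SQ", items)
    } else {
      if (undefined) stop("undefined length on non-SQ element ", tag,
                          call. = FALSE)
      bytes <- if (len > 0) r[pos:(pos + len - 1)] else raw(0)
      known_vr <- vr_for_tag(tag)
      use_vr <- if (!is.null(known_vr) && vr == "UN") known_vr else vr
      ds[[tag]] <- new_element(use_vr, decode_value(use_vr, bytes))
      pos <- pos + len
    }
  }
  list(ds = ds, pos = pos)
}

#' Read a DICOM Part-10 file
#'
#' Accepts Explicit VR Little Endian files (the transfer syntax this package
#' writes; also the syntax pydicom and most archives can emit). Sequences
#' with defined or undefined lengths are both supported.
#'
#' @param path file path.
#' @return a `dcm_dataset`; the file meta group is attached as the
#'   `"file_meta"` attribute.
#' @export
read_dicom <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM") {
    stop("not a DICOM Part-10 file: ", path, call. = FALSE)
  }
  pos <- 133
  # file meta group is always explicit VR little endian
  glen_tag <- rd_tag(r, pos)
  if (glen_tag != "00020000") stop("missing file meta group length", call. = FALSE)
  glen <- decode_value("UL", r[(pos + 8):(pos + 11)])
  pos <- pos + 12
  meta <- parse_dataset(r, pos, pos + glen - 1)
  ts <- ds_get(meta$ds, "TransferSyntaxUID")
  if (!identical(ts, DCM_UID$explicit_vr_le)) {
    stop("unsupported transfer syntax: ", ts, call. = FALSE)
  }
  main <- parse_dataset(r, meta$pos, length(r))
  attr(main$ds, "file_meta") <- meta$ds
  main$ds
}
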