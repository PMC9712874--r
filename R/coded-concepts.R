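#' Coded concepts
#'
#' A coded concept is the atom of DICOM structured content: a code value, a
#' coding scheme designator, a human-readable meaning and an optional coding
#' scheme version. Concepts replace free text with terms from controlled
#' terminologies (SNOMED-CT, the DICOM Controlled Terminology, UCUM).
#'
#' @param value code value, 1-16 characters, no control characters.
#' @param scheme coding scheme designator, 1-16 characters (e.g. `"SCT"`,
#'   `"DCM"`, `"UCUM"`, or a custom `"99..."` scheme).
#' @param meaning human-readable meaning, 1-64 characters. Display text
#'   only: it never participates in equality.
#' @param version optional coding scheme version.
#' @return an object of class `coded_concept`.
#' @examples
#' tumor <- coded_concept("108369006", "SCT", "Tumor")
#' @export
coded_concept <- function(value, scheme, meaning, version = NULL) {
  check_code_string <- function(x, what, max) {
    if (!is.character(x) || length(x) != 1 || is.na(x) || nchar(x) == 0) {
      stop(what, " must be a non-empty string", call. = FALSE)
    }
    if (nchar(x) > max) stop(what, " exceeds ", max, " characters", call. = FALSE)
    if (grepl("[[:cntrl:]]", x)) stop(what, " contains control characters", call. = FALSE)
    x
  }
  structure(list(
    value = check_code_string(value, "code value", 16),
    scheme = check_code_string(scheme, "scheme designator", 16),
    meaning = check_code_string(meaning, "meaning", 64),
    version = if (!is.null(version)) check_code_string(version, "version", 16)
  ), class = "coded_concept")
}

#' @export
print.coded_concept <- function(x, ...) {
  v <- if (is.null(x$version)) "" else paste0(", version ", x$version)
  cat(sprintf("(%s, %s, \"%s\"%s)\n", x$value, x$scheme, x$meaning, v))
  invisible(x)
}

#' @export
format.coded_concept <- function(x, ...) {
  sprintf("%s:%s", x$scheme, x$value)
}

#' Compare two coded concepts for equality
#'
#' Equality compares code values, coding scheme designators (exact,
#' case-sensitive match) and coding scheme versions. The version only
#' discriminates when *both* operands carry one: the standard treats it as a
#' disambiguator, so a versioned and an unversioned concept with equal value
#' and designator compare equal. The meaning is display text and never
#' participates; concepts that compare equal but disagree on meaning raise a
#' warning.
#'
#' @param a,b `coded_concept` objects.
#' @return logical scalar.
#' @export
concepts_equal <- function(a, b) {
  stopifnot(inherits(a, "coded_concept"), inherits(b, "coded_concept"))
  eq <- a$value == b$value && a$scheme == b$scheme
  if (eq && !is.null(a$version) && !is.null(b$version)) {
    eq <- a$version == b$version
  }
  if (eq && a$meaning != b$meaning) {
    warning(sprintf("concepts %s compare equal but meanings differ: '%s' vs '%s'",
                    format(a), a$meaning, b$meaning), call. = FALSE)
  }
  eq
}

#' Hash key for a coded concept
#'
#' A string key consistent with [concepts_equal()]: concepts that compare
#' equal always share a key. The version is excluded because equality treats
#' it as a disambiguator only.
#' @param x a `coded_concept`.
#' @return character scalar.
#' @export
concept_key <- function(x) paste(x$scheme, x$value, sep = "|")

#' @export
`==.coded_concept` <- function(e1, e2) concepts_equal(e1, e2)

# --- registries ----------------------------------------------------------

the_registries <- new.env(parent = emptyenv())

load_registries <- function() {
  if (!is.null(the_registries$tbl)) return(invisible())
  path <- system.file("extdata", "coding_schemes.csv", package = "dcmannot")
  if (path == "") path <- file.path("inst", "extdata", "coding_schemes.csv")
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  the_registries$tbl <- tbl
  invisible()
}

#' Look up a concept in a shipped code registry
#'
#' The package ships small vetted registries for the DCM, SCT and UCUM
#' coding schemes (the finding types, anatomy, units, measurement names and
#' tracking-context codes used by the builders); the full set is listed in
#' `inst/extdata/coding_schemes.csv`.
#'
#' @param scheme registry id: `"SCT"`, `"DCM"` or `"UCUM"`.
#' @param keyword registry keyword, e.g. `"Tumor"`.
#' @return a `coded_concept`.
#' @examples
#' registry_lookup("SCT", "Tumor")$value  # "108369006"
#' @export
registry_lookup <- function(scheme, keyword) {
  load_registries()
  tbl <- the_registries$tbl
  if (!scheme %in% tbl$scheme) {
    stop("no such code registry: ", scheme, call. = FALSE)
  }
  row <- tbl[tbl$scheme == scheme & tbl$keyword == keyword, ]
  if (nrow(row) == 0) {
    stop(sprintf("keyword '%s' not found in registry '%s'", keyword, scheme),
         call. = FALSE)
  }
  coded_concept(row$value[1], row$scheme[1], row$meaning[1])
}

#' List all entries of a shipped registry
#' @inheritParams registry_lookup
#' @return a data.frame of (keyword, value, scheme, meaning).
#' @export
registry_entries <- function(scheme = NULL) {
  load_registries()
  tbl <- the_registries$tbl
  if (is.null(scheme)) tbl else tbl[tbl$scheme == scheme, ]
}

#' Classify a coding scheme designator
#'
#' Custom (site-defined) coding schemes follow the convention of a `"99"`
#' prefix followed by an identifying string; the schemes shipped with the
#' package (`SCT`, `DCM`, `UCUM`) are standard; everything else is unknown.
#'
#' @param designator non-empty scheme designator string.
#' @return `"custom"`, `"standard"` or `"unknown"`.
#' @examples
#' classify_scheme("99ACME")  # "custom"
#' @export
classify_scheme <- function(designator) {
  if (!is.character(designator) || length(designator) != 1 ||
      is.na(designator) || nchar(designator) == 0) {
    stop("designator must be a non-empty string", call. = FALSE)
  }
  if (grepl("^99.+", designator)) return("custom")
  load_registries()
  if (designator %in% unique(the_registries$tbl$scheme)) return("standard")
  "unknown"
}

# --- DICOM (de)serialization of concepts --------------------------------

concept_to_ds <- function(x) {
  ds <- dcm_dataset(CodeValue = x$value, CodingSchemeDesignator = x$scheme,
                    CodeMeaning = x$meaning)
  if (!is.null(x$version)) ds <- ds_set(ds, "CodingSchemeVersion", x$version)
  ds
}

ds_to_concept <- function(ds) {
  coded_concept(ds_get(ds, "CodeValue"), ds_get(ds, "CodingSchemeDesignator"),
                ds_get(ds, "CodeMeaning"),
                version = ds_get(ds, "CodingSchemeVersion"))
}
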