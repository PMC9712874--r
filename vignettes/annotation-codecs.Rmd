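---
title: "Encoding and decoding DICOM image annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding and decoding DICOM image annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmannot)
```

## The problem

Machine-learning models for radiology and pathology consume images and
produce annotations: segmentation masks, class labels with scores, and
detected regions with bounding boxes. For these outputs to move between
clinical systems they must be encoded in DICOM, the interchange standard of
medical imaging, together with the patient, study and specimen context of
the source images and with terms drawn from controlled terminologies rather
than free text. `dcmannot` provides builders and readers for the three
DICOM object families that cover the common annotation tasks:

* **Segmentation images (SEG)** — raster masks; each *segment* is one
  labeled entity, stored as bit-packed binary planes or as 8-bit quantized
  fractional (probability/occupancy) frames.
* **Comprehensive / Comprehensive 3D Structured Reports (SR)** — trees of
  coded name–value *content items* following the TID 1500 "Measurement
  Report" template: tracked findings, regions of interest as 3D
  coordinates, measurements with UCUM units, qualitative evaluations.
* **Microscopy Bulk Simple Annotations (ANN)** — flat coordinate arrays
  with per-graphic index offsets, for the very large vector-graphic
  collections produced in whole-slide pathology.

Because no DICOM toolkit is part of this package's R dependency set, the
package carries its own DICOM Part-10 reader and writer. It supports the
Explicit VR Little Endian transfer syntax (which is also what it writes),
defined- and undefined-length sequences on read, and UTF-8 strings. Files
it writes are read back by independent implementations (the test suite
cross-checks against pydicom), and vice versa for files in the supported
transfer syntax.

## Coded concepts

A `coded_concept(value, scheme, meaning, version)` is the atom of all
structured content. Equality follows the standard's semantics:

* code value and scheme designator must match exactly (case-sensitive — the
  standard registers designators as case-sensitive symbols, so we do not
  fold case);
* the scheme **version participates only when both operands carry one**.
  The standard treats the version as a disambiguator, not a discriminator:
  an unversioned concept matches any version of the same code.
* the `meaning` is display text and never participates. Two concepts that
  compare equal but disagree on meaning raise a warning rather than an
  error.

Custom coding schemes are recognized by the conventional `"99"` designator
prefix followed by at least one identifying character (`classify_scheme()`
returns `"custom"`, `"standard"` or `"unknown"`).

The package ships small vetted registries for the DCM, SCT and UCUM
schemes — only the entries its own builders and examples need (finding
types such as Tumor `108369006`, anatomy, measurement names such as Area,
UCUM units, and the tracking/report concepts of TID 1500). The full list
lives in `inst/extdata/coding_schemes.csv`; `registry_entries()` returns
it. These registries are deliberately minimal: this is not a terminology
server, and no hierarchy traversal or cross-scheme translation is
attempted.

## Shared object machinery

All derived objects are produced by constructor-style builders that:

1. **harvest context** — the Patient and General Study module attributes,
   plus the Specimen module for slide-based sources, are copied verbatim
   from the source images (`harvest_context()`); sources spanning more than
   one study or patient are rejected with the conflicting identifiers;
2. **reference evidence** — every source instance is referenced exactly
   once, grouped study → series → instance (`build_evidence()`);
3. **validate at construction** — `validate_sop()` re-checks every built
   object against the IOD schema as implemented and returns a report of
   `(path, rule, severity)` rows; builders must produce empty reports, and
   the public API offers no mutation after construction.

UIDs use the UUID-derived `2.25.<decimal>` form, so no registered
organization root is required; randomness comes from the R RNG so fixture
generation is reproducible down to the byte under a seed. Equipment
attributes of derived objects default to this package's identity and are
caller-overridable.

## Segmentation encode/decode

`encode_segmentation()` accepts three mask conventions, selected by the
array's storage mode: logical arrays are bit planes (4th dimension indexes
segments), integer arrays are label maps (value *k* → segment *k*, 0 =
background), and double arrays are probabilities in [0, 1], allowed only
for FRACTIONAL type. One frame is encoded per (segment, source frame)
pair. Numerical choices:

* **Quantization** is round-half-up: stored value `floor(p * M + 0.5)`
  with `M = MaximumFractionalValue` (default 255). The decode rescaling is
  division by `M`, so the round-trip error is at most `1/(2M)` (1/510 at
  the default).
* An **empty frame** is one whose pixels are all zero *after*
  quantization; with `omit_empty_frames` (the default) such frames are not
  stored, matching the sparse-storage purpose of the rule, and decoders
  must restore them as zeros. A mask that is empty everywhere is refused
  with instructions to disable omission — a zero-frame object is never
  emitted.
* **Bit packing**: pixels are flattened row-major per frame, frames
  concatenated without per-frame byte alignment, least-significant bit
  first, final byte zero-padded, total padded to even length.

`reconstruct_mask()` performs the decode steps explicitly: it selects the
stored frames relevant to the requested segments and source frames via the
per-frame index (never the storage order — the tests shuffle stored frames
to prove it), sorts them into query order, restores omitted frames as
background, and optionally combines binary segments into a label map.
Combination is defined only for BINARY objects; overlap is an error unless
`allow_overlap = TRUE`, in which case the highest segment number wins — a
deterministic rule that callers can rely on. Sources with varying plane
orientation within one series are rejected rather than resampled.

## Structured reports

The TID 1500 realization covers the Measurement Report root (template
identifier `"1500"`), language and observation context, procedure
reported, and measurement groups for image-level, planar-ROI and
volumetric-ROI annotations with tracking identifier/UID, finding type,
finding sites, regions (SCOORD, SCOORD3D or segment references),
NUM measurements with UCUM units and CODE qualitative evaluations.
Optional sub-trees of the template (image library, time points, real-world
value maps) are intentionally not implemented. Class *scores* at image
level are encoded as NUM measurements with the dimensionless UCUM unit
`1`; a code-with-qualifier encoding would also be standard-conformant, but
a numeric measurement keeps scores filterable with the same query
operation as any other measurement.

Construction enforces the geometry rules of each graphic type: POLYGON
rings must be explicitly closed (first point repeated last) and planar —
unclosed rings are rejected rather than auto-closed, since a mismatch is
almost always a caller bug; ELLIPSE takes exactly 4 points and ELLIPSOID
6. A Comprehensive (non-3D) SR refuses SCOORD3D content at construction
*and* in `validate_sop()`: the 3D variant exists precisely to carry those
items.

Queries (`find_content_items()`, `get_measurement_groups()`,
`get_measurements()`, `get_qualitative_evaluations()`) are conjunctive
filters in depth-first pre-order, so results are always in document order
and sibling order is never disturbed.

## Spatial conventions

All conversions use one convention, stated here once: pixel indices are
`(column, row)`, 0-based, at pixel centers; the geometry `position` is the
mm coordinate of the center of the top-left pixel; `row_direction` /
`col_direction` are unit vectors along increasing row/column index;
`pixel_spacing` is `(between-rows, between-columns)` mm. The affine is

    (x, y, z, 1)' = [ c*dc | r*dr | n | p ] (col, row, 0, 1)'

`reference_to_pixel()` projects onto the plane and returns fractional
indices (rounding is the caller's concern); points farther from the plane
than `tolerance_mm` — default half the smaller pixel spacing — are
rejected with the measured distance. Polygon areas use the magnitude of
the summed cross products (Newell's method), equivalent to the shoelace
formula in the plane's 2D basis and orientation-independent. Bounding
boxes are axis-aligned in the pixel basis; a degenerate (single-point) box
is expanded to one pixel's extent so that every emitted POLYGON has
nonzero area. For tiled slide images, coordinates always refer to
total-pixel-matrix indices, not tile-local ones.

## Bulk annotations

Annotation groups store all vertices of all graphics in one flat vector;
for variable-length types (POLYLINE, POLYGON) the 1-based index offsets
mark each graphic's first value, and offsets and per-graphic vertex counts
are mutually reconstructible. Coordinates are serialized as 32-bit floats —
bulk size is the point of this object type — so sub-float32 precision is
lost on write; callers needing exact round-trips should use
float32-representable values. No maximum group size or chunking is
imposed.

## ROI pipelines

`probabilities_to_seg()` wraps the segmentation encoder to produce
FRACTIONAL/PROBABILITY objects with one segment per class; class
probabilities are treated as independent (no cross-class sum constraint).
Thresholding is deliberately the caller's step (`threshold_probabilities()`,
default 0.5 in the CLI), because the choice is application-specific.
`extract_rois()` labels connected components (default 8-connectivity, with
the complementary convention for background) and traces each component's
outer border with Moore-neighbor following — holes are ignored, since the
downstream use (bounding boxes) never needs them. Contours start at the
top-most, then left-most border pixel and ROIs are ordered by box
top-left, so output is deterministic. Low-resolution probability maps
(e.g. one pixel per slide frame) are contoured at native resolution and
converted with the correspondingly coarse geometry rather than upsampled.
`rois_to_sr()` emits one measurement group per ROI: the box as an SCOORD3D
POLYGON in frame-of-reference mm, the class as the finding type, the score
as a dimensionless NUM measurement.

## Synthetic fixtures

`generate_ct_series()` and `generate_sm_image()` emulate the two source
geometries the codecs must handle: an axial CT series with patient
frame-of-reference metadata (default 3 slices of 32×32 at 0.7 mm spacing,
2.5 mm slice spacing — small but geometrically faithful), and a tiled
slide-microscopy image with slide frame-of-reference and specimen
metadata (default 64×64 matrix in 16×16 tiles at 1 µm spacing). Pixel
content is smoothed noise plus planted blob intensities: enough structure
for nontrivial masks, with no attempt at photorealism.
`generate_scenario()` adds per-class probability maps with planted
rectangular blobs, ground-truth masks at the 0.5 threshold, and tight
ground-truth boxes (overlapping same-class blobs are merged with a
warning). Fixtures are byte-deterministic given their seed.

What passing tests on these fixtures do show: the codecs are lossless (or
quantization-bounded), the geometry algebra is exact, and the pipeline
recovers planted structure through full write/read cycles. What they do
not show: behavior on real scanner output — compressed transfer syntaxes,
vendor private tags, imperfectly orthonormal orientations, multi-resolution
slide pyramids — none of which the fixtures emulate and the first three of
which the package explicitly rejects or ignores.

## Problem sizes and runtime choices

The shipped tests use masks up to 8 frames × 64 × 64 × 4 segments (100
random cases for the binary round-trip), 50 randomized SR documents for
the closure check, random masks up to 64 × 64 against the flood-fill
oracle, and annotation groups up to 10⁴ points; these sizes exercise every
code path (sparsity, multi-segment, padding boundaries) while keeping the
whole suite around half a minute in plain R.

## Known limitations

* Explicit VR Little Endian only; no compressed or encapsulated pixel
  data.
* TID 1500 sub-trees beyond the measurement groups (image library, time
  points) are absent.
* Verification workflow is represented by the completion/verification
  flags only; predecessor-document chains are out of scope.
* Surface segmentations, parametric maps and spatial registration objects
  are out of scope.
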