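# dcmannot

Encode and decode DICOM image annotations for machine learning in
radiology and pathology, in pure R.

Models that segment, classify or detect structures in medical images
produce arrays and coordinates; clinical systems exchange DICOM objects.
`dcmannot` bridges the two with high-level builders and readers for:

* **Segmentation images (SEG)** — binary masks stored as bit-packed
  planes, or probability maps quantized to 8-bit fractional frames
  (stored value `floor(p·M + 0.5)`, recovered as `v/M` with
  `M = MaximumFractionalValue`), with sparse storage of background frames
  and reconstruction back to arrays or label maps;
* **Comprehensive / Comprehensive 3D Structured Reports** following the
  TID 1500 "Measurement Report" template — tracked findings encoded as
  coded concepts (SNOMED-CT, DCM, UCUM), regions as SCOORD3D polygons in
  the patient or slide frame of reference, measurements with units, and
  conjunctive query operations over the document tree;
* **Microscopy Bulk Simple Annotations (ANN)** — flat coordinate arrays
  with 1-based index offsets for very large vector-graphic collections;
* the **affine pixel ↔ frame-of-reference transforms**
  (`P = p₀ + c·Δc·ĉ + r·Δr·r̂`), physical-unit polygon areas and bounding
  boxes;
* the **ROI post-processing pipeline**: probability maps → fractional SEG
  → threshold → connected components and border following → bounding
  boxes → Comprehensive 3D SR;
* **synthetic fixtures** (axial CT series, tiled slide-microscopy images,
  blob scenarios) so everything is testable without external data.

The package includes its own DICOM Part-10 reader/writer (Explicit VR
Little Endian); its files are interoperable with pydicom, which the test
suite uses as an independent cross-check.

## Worked example

```r
library(dcmannot)
set.seed(1)

# a synthetic 3-slice axial CT study
ct <- generate_ct_series(ct_series_spec(n_slices = 3, rows = 32, cols = 32))

# encode a tumor mask as a binary Segmentation image
mask <- array(FALSE, c(3, 32, 32)); mask[2, 10:14, 8:15] <- TRUE
seg <- encode_segmentation(
  mask, ct,
  list(segment_description(1, "tumor",
                           registry_lookup("SCT", "MorphologicallyAbnormalStructure"),
                           registry_lookup("SCT", "Tumor"),
                           "AUTOMATIC", list(name = "unet"))),
  segmentation_params("BINARY"))
validate_sop(seg, "segmentation")
#> validation report: no violations

write_dicom(seg, "tumor_seg.dcm")
back <- reconstruct_mask(read_dicom("tumor_seg.dcm"),
                         sapply(ct, ds_get, keyword = "SOPInstanceUID"))
identical(array(back > 0, dim(mask)), mask)
#> [1] TRUE

# a measurement report: the tumor region in mm with its area
geom <- geometry_from_dataset(ct[[2]])
ring <- pixel_to_reference(rbind(c(8, 10), c(15, 10), c(15, 14),
                                 c(8, 14), c(8, 10)), geom)
polygon_area_mm2(ring)
#> [1] 13.72
grp <- measurement_group(
  "Lesion-1", generate_uid(), registry_lookup("SCT", "Tumor"),
  finding_sites = list(registry_lookup("SCT", "Lung")),
  region = item_scoord3d(registry_lookup("DCM", "ImageRegion"), "POLYGON",
                         ring, ds_get(ct[[1]], "FrameOfReferenceUID")),
  measurements = list(measurement(registry_lookup("SCT", "Area"),
                                  polygon_area_mm2(ring),
                                  registry_lookup("UCUM", "SquareMillimeter"))))
doc <- create_sr_document(
  build_measurement_report(observation_context(device_uid = generate_uid()),
                           registry_lookup("SCT", "Imaging"), list(grp)),
  build_evidence(ct), harvest_context(ct), "comprehensive_3d")
write_dicom(doc, "report.dcm")

g <- get_measurement_groups(read_dicom("report.dcm"),
                            finding_type = registry_lookup("SCT", "Tumor"))[[1]]
get_measurements(g, name = registry_lookup("SCT", "Area"))[[1]]$value
#> [1] 13.72
```

The area (13.72 mm²) is the shoelace area of the 7 × 4 pixel rectangle at
0.7 mm spacing: `(7·0.7) · (4·0.7)`; it survives the write/read cycle
because the report stores it as a decimal string with its UCUM unit.

A thin CLI over the same functions lives at `inst/cli/dcmannot`
(`validate`, `fixture`, `seg-info`, `sr-query` subcommands).

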