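Package: dcmannot
Title: Encode and Decode DICOM Image Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: High-level builders and readers for DICOM objects that carry
    image annotations for machine learning in radiology and pathology:
    Segmentation images (binary and fractional masks), Comprehensive and
    Comprehensive 3D Structured Reports following the TID 1500 "Measurement
    Report" template, and Microscopy Bulk Simple Annotations. Includes the
    coded-concept machinery (SNOMED-CT, DICOM Controlled Terminology, UCUM),
    affine transforms between pixel indices and the patient or slide frame
    of reference, ROI post-processing pipelines (probability maps to
    fractional segmentations, connected components and border following to
    3D structured reports), a pure-R DICOM Part-10 reader and writer for
    these objects, and synthetic CT and slide-microscopy fixture generators
    so every codec is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
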