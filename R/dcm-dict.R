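# Internal data-element dictionary: the subset of the DICOM data dictionary
# needed by the Segmentation, SR, Bulk Annotation, CT and Slide Microscopy
# objects this package reads and writes. Tags are "GGGGEEEE" uppercase hex.

dcm_dict_raw <- c(
  # file meta (group 0002)
  "00020000", "FileMetaInformationGroupLength", "UL",
  "00020001", "FileMetaInformationVersion", "OB",
  "00020002", "MediaStorageSOPClassUID", "UI",
  "00020003", "MediaStorageSOPInstanceUID", "UI",
  "00020010", "TransferSyntaxUID", "UI",
  "00020012", "ImplementationClassUID", "UI",
  "00020013", "ImplementationVersionName", "SH",
  # general / identification
  "00080005", "SpecificCharacterSet", "CS",
  "00080008", "ImageType", "CS",
  "00080016", "SOPClassUID", "UI",
  "00080018", "SOPInstanceUID", "UI",
  "00080020", "StudyDate", "DA",
  "00080023", "ContentDate", "DA",
  "00080030", "StudyTime", "TM",
  "00080033", "ContentTime", "TM",
  "00080050", "AccessionNumber", "SH",
  "00080060", "Modality", "CS",
  "00080070", "Manufacturer", "LO",
  "00080090", "ReferringPhysicianName", "PN",
  "00080100", "CodeValue", "SH",
  "00080102", "CodingSchemeDesignator", "SH",
  "00080103", "CodingSchemeVersion", "SH",
  "00080104", "CodeMeaning", "LO",
  "00080105", "MappingResource", "CS",
  "00081030", "StudyDescription", "LO",
  "0008103E", "SeriesDescription", "LO",
  "00081090", "ManufacturerModelName", "LO",
  "00081115", "ReferencedSeriesSequence", "SQ",
  "00081150", "ReferencedSOPClassUID", "UI",
  "00081155", "ReferencedSOPInstanceUID", "UI",
  "00081160", "ReferencedFrameNumber", "IS",
  "00081199", "ReferencedSOPSequence", "SQ",
  "00082112", "SourceImageSequence", "SQ",
  "00089124", "DerivationImageSequence", "SQ",
  # patient
  "00100010", "PatientName", "PN",
  "00100020", "PatientID", "LO",
  "00100030", "PatientBirthDate", "DA",
  "00100040", "PatientSex", "CS",
  # acquisition geometry
  "00180050", "SliceThickness", "DS",
  "00180088", "SpacingBetweenSlices", "DS",
  "00181020", "SoftwareVersions", "LO",
  # study / series / frame of reference
  "0020000D", "StudyInstanceUID", "UI",
  "0020000E", "SeriesInstanceUID", "UI",
  "00200010", "StudyID", "SH",
  "00200011", "SeriesNumber", "IS",
  "00200013", "InstanceNumber", "IS",
  "00200032", "ImagePositionPatient", "DS",
  "00200037", "ImageOrientationPatient", "DS",
  "00200052", "FrameOfReferenceUID", "UI",
  "00201040", "PositionReferenceIndicator", "LO",
  "00209111", "FrameContentSequence", "SQ",
  "00209113", "PlanePositionSequence", "SQ",
  "00209116", "PlaneOrientationSequence", "SQ",
  "00209157", "DimensionIndexValues", "UL",
  "00209164", "DimensionOrganizationUID", "UI",
  "00209165", "DimensionIndexPointer", "AT",
  "00209167", "FunctionalGroupPointer", "AT",
  "00209221", "DimensionOrganizationSequence", "SQ",
  "00209222", "DimensionIndexSequence", "SQ",
  "00209311", "DimensionOrganizationType", "CS",
  # image pixel
  "00280002", "SamplesPerPixel", "US",
  "00280004", "PhotometricInterpretation", "CS",
  "00280008", "NumberOfFrames", "IS",
  "00280010", "Rows", "US",
  "00280011", "Columns", "US",
  "00280030", "PixelSpacing", "DS",
  "00280100", "BitsAllocated", "US",
  "00280101", "BitsStored", "US",
  "00280102", "HighBit", "US",
  "00280103", "PixelRepresentation", "US",
  "00281052", "RescaleIntercept", "DS",
  "00281053", "RescaleSlope", "DS",
  "00282110", "LossyImageCompression", "CS",
  "00289110", "PixelMeasuresSequence", "SQ",
  # SR document
  "0040072A", "XOffsetInSlideCoordinateSystem", "DS",
  "0040073A", "YOffsetInSlideCoordinateSystem", "DS",
  "0040074A", "ZOffsetInSlideCoordinateSystem", "DS",
  "004008EA", "MeasurementUnitsCodeSequence", "SQ",
  "00400512", "ContainerIdentifier", "LO",
  "00400551", "SpecimenIdentifier", "LO",
  "00400554", "SpecimenUID", "UI",
  "00400560", "SpecimenDescriptionSequence", "SQ",
  "0040A010", "RelationshipType", "CS",
  "0040A040", "ValueType", "CS",
  "0040A043", "ConceptNameCodeSequence", "SQ",
  "0040A050", "ContinuityOfContent", "CS",
  "0040A120", "DateTime", "DT",
  "0040A124", "UID", "UI",
  "0040A160", "TextValue", "UT",
  "0040A168", "ConceptCodeSequence", "SQ",
  "0040A300", "MeasuredValueSequence", "SQ",
  "0040A30A", "NumericValue", "DS",
  "0040A375", "CurrentRequestedProcedureEvidenceSequence", "SQ",
  "0040A491", "CompletionFlag", "CS",
  "0040A493", "VerificationFlag", "CS",
  "0040A504", "ContentTemplateSequence", "SQ",
  "0040A730", "ContentSequence", "SQ",
  "0040DB00", "TemplateIdentifier", "CS",
  # slide microscopy
  "00480006", "TotalPixelMatrixColumns", "UL",
  "00480007", "TotalPixelMatrixRows", "UL",
  "00480008", "TotalPixelMatrixOriginSequence", "SQ",
  "00480102", "ImageOrientationSlide", "DS",
  "0048021A", "PlanePositionSlideSequence", "SQ",
  "0048021E", "ColumnPositionInTotalImagePixelMatrix", "SL",
  "0048021F", "RowPositionInTotalImagePixelMatrix", "SL",
  # segmentation
  "00620001", "SegmentationType", "CS",
  "00620002", "SegmentSequence", "SQ",
  "00620003", "SegmentedPropertyCategoryCodeSequence", "SQ",
  "00620004", "SegmentNumber", "US",
  "00620005", "SegmentLabel", "LO",
  "00620008", "SegmentAlgorithmType", "CS",
  "00620009", "SegmentAlgorithmName", "LO",
  "0062000A", "SegmentIdentificationSequence", "SQ",
  "0062000B", "ReferencedSegmentNumber", "US",
  "0062000E", "MaximumFractionalValue", "US",
  "0062000F", "SegmentedPropertyTypeCodeSequence", "SQ",
  "00620010", "SegmentationFractionalType", "CS",
  "00620020", "TrackingID", "UT",
  "00620021", "TrackingUID", "UI",
  # bulk annotations
  "00660016", "PointCoordinatesData", "OF",
  "00660040", "LongPrimitivePointIndexList", "OL",
  "006A0001", "AnnotationCoordinateType", "CS",
  "006A0002", "AnnotationGroupSequence", "SQ",
  "006A0003", "AnnotationGroupNumber", "UL",
  "006A0005", "AnnotationGroupUID", "UI",
  "006A0006", "AnnotationGroupLabel", "LO",
  "006A0007", "AnnotationGroupGenerationType", "CS",
  "006A0009", "AnnotationPropertyCategoryCodeSequence", "SQ",
  "006A000A", "AnnotationPropertyTypeCodeSequence", "SQ",
  "006A000C", "NumberOfAnnotations", "UL",
  # multi-frame functional groups
  "52009229", "SharedFunctionalGroupsSequence", "SQ",
  "52009230", "PerFrameFunctionalGroupsSequence", "SQ",
  # graphics (SR + ANN)
  "00700022", "GraphicData", "FL",
  "00700023", "GraphicType", "CS",
  "00700084", "ContentCreatorName", "PN",
  "30060024", "ReferencedFrameOfReferenceUID", "UI",
  # pixel data
  "7FE00010", "PixelData", "OB"
)

dcm_dict <- local({
  m <- matrix(dcm_dict_raw, ncol = 3, byrow = TRUE)
  data.frame(tag = m[, 1], keyword = m[, 2], vr = m[, 3],
             stringsAsFactors = FALSE)
})

dcm_tag_by_keyword <- local({
  x <- dcm_dict$tag
  names(x) <- dcm_dict$keyword
  x
})

dcm_vr_by_tag <- local({
  x <- dcm_dict$vr
  names(x) <- dcm_dict$tag
  x
})

dcm_keyword_by_tag <- local({
  x <- dcm_dict$keyword
  names(x) <- dcm_dict$tag
  x
})

vr_for_tag <- function(tag) {
  vr <- unname(dcm_vr_by_tag[tag])
  if (is.na(vr)) NULL else vr
}

lookup_tag <- function(keyword) {
  tag <- unname(dcm_tag_by_keyword[keyword])
  if (is.na(tag)) stop("unknown attribute keyword: ", keyword, call. = FALSE)
  tag
}

# Well-known UIDs
DCM_UID <- list(
  explicit_vr_le       = "1.2.840.10008.1.2.1",
  ct_image             = "1.2.840.10008.5.1.4.1.1.2",
  sm_image             = "1.2.840.10008.5.1.4.1.1.77.1.6",
  segmentation         = "1.2.840.10008.5.1.4.1.1.66.4",
  comprehensive_sr     = "1.2.840.10008.5.1.4.1.1.88.33",
  comprehensive_3d_sr  = "1.2.840.10008.5.1.4.1.1.88.34",
  bulk_annotations     = "1.2.840.10008.5.1.4.1.1.91.1"
)

# VR families
VR_STRING <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
               "SH", "ST", "TM", "UC", "UI", "UR", "UT")
VR_LONG_FORM <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UC", "UR", "UT", "UN")
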