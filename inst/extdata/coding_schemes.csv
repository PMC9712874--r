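keyword,value,scheme,meaning
ImagingMeasurementReport,126000,DCM,Imaging Measurement Report
ImagingMeasurements,126010,DCM,Imaging Measurements
MeasurementGroup,125007,DCM,Measurement Group
Finding,121071,DCM,Finding
TrackingIdentifier,112039,DCM,Tracking Identifier
TrackingUniqueIdentifier,112040,DCM,Tracking Unique Identifier
ImageRegion,111030,DCM,Image Region
ReferencedSegment,121191,DCM,Referenced Segment
LanguageOfContentItemAndDescendants,121049,DCM,Language of Content Item and Descendants
PersonObserverName,121008,DCM,Person Observer Name
DeviceObserverUID,121012,DCM,Device Observer UID
ProcedureReported,121058,DCM,Procedure reported
AlgorithmName,111001,DCM,Algorithm Name
AlgorithmVersion,111003,DCM,Algorithm Version
SourceOfMeasurement,121112,DCM,Source of Measurement
Score,246262008,SCT,Score
Tumor,108369006,SCT,Tumor
Normal,17621005,SCT,Normal
Lung,39607008,SCT,Lung
Nodule,27925004,SCT,Nodule
FindingSite,363698007,SCT,Finding site
Area,42798000,SCT,Area
Diameter,81827009,SCT,Diameter
Volume,118565006,SCT,Volume
TissueSpecimen,119376003,SCT,Tissue specimen
MorphologicallyAbnormalStructure,49755003,SCT,Morphologically abnormal structure
BodyStructure,123037004,SCT,Body structure
Imaging,363679005,SCT,Imaging
SquareMillimeter,mm2,UCUM,square millimeter
SquareMicrometer,um2,UCUM,square micrometer
Millimeter,mm,UCUM,millimeter
Micrometer,um,UCUM,micrometer
NoUnits,1,UCUM,no units
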