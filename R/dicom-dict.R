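# Curated DICOM data dictionary: the attributes the de-identification
# profiles, the fixture generator and the WSI pipeline touch. Not a
# transcription of the full standard dictionary -- unknown tags are still
# read and written faithfully (their VR travels with the element).

.dicom_dict <- local({
  d <- rbind(
    # keyword, group, element, vr
    c("FileMetaInformationVersion",   "0002", "0001", "OB"),
    c("MediaStorageSOPClassUID",      "0002", "0002", "UI"),
    c("MediaStorageSOPInstanceUID",   "0002", "0003", "UI"),
    c("TransferSyntaxUID",            "0002", "0010", "UI"),
    c("ImplementationClassUID",       "0002", "0012", "UI"),
    c("ImageType",                    "0008", "0008", "CS"),
    c("SOPClassUID",                  "0008", "0016", "UI"),
    c("SOPInstanceUID",               "0008", "0018", "UI"),
    c("StudyDate",                    "0008", "0020", "DA"),
    c("SeriesDate",                   "0008", "0021", "DA"),
    c("AcquisitionDate",              "0008", "0022", "DA"),
    c("ContentDate",                  "0008", "0023", "DA"),
    c("StudyTime",                    "0008", "0030", "TM"),
    c("SeriesTime",                   "0008", "0031", "TM"),
    c("AccessionNumber",              "0008", "0050", "SH"),
    c("Modality",                     "0008", "0060", "CS"),
    c("Manufacturer",                 "0008", "0070", "LO"),
    c("InstitutionName",              "0008", "0080", "LO"),
    c("InstitutionAddress",           "0008", "0081", "ST"),
    c("ReferringPhysicianName",       "0008", "0090", "PN"),
    c("StationName",                  "0008", "1010", "SH"),
    c("StudyDescription",             "0008", "1030", "LO"),
    c("SeriesDescription",            "0008", "103E", "LO"),
    c("InstitutionalDepartmentName",  "0008", "1040", "LO"),
    c("PerformingPhysicianName",      "0008", "1050", "PN"),
    c("OperatorsName",                "0008", "1070", "PN"),
    c("ManufacturerModelName",        "0008", "1090", "LO"),
    c("ReferencedStudySequence",      "0008", "1110", "SQ"),
    c("ReferencedImageSequence",      "0008", "1140", "SQ"),
    c("ReferencedSOPClassUID",        "0008", "1150", "UI"),
    c("ReferencedSOPInstanceUID",     "0008", "1155", "UI"),
    c("PatientName",                  "0010", "0010", "PN"),
    c("PatientID",                    "0010", "0020", "LO"),
    c("PatientBirthDate",             "0010", "0030", "DA"),
    c("PatientSex",                   "0010", "0040", "CS"),
    c("OtherPatientIDs",              "0010", "1000", "LO"),
    c("OtherPatientNames",            "0010", "1001", "PN"),
    c("PatientAge",                   "0010", "1010", "AS"),
    c("PatientSize",                  "0010", "1020", "DS"),
    c("PatientWeight",                "0010", "1030", "DS"),
    c("PatientAddress",               "0010", "1040", "LO"),
    c("MilitaryRank",                 "0010", "1080", "LO"),
    c("EthnicGroup",                  "0010", "2160", "SH"),
    c("Occupation",                   "0010", "2180", "SH"),
    c("AdditionalPatientHistory",     "0010", "21B0", "LT"),
    c("PatientComments",              "0010", "4000", "LT"),
    c("PatientIdentityRemoved",       "0012", "0062", "CS"),
    c("DeidentificationMethod",       "0012", "0063", "LO"),
    c("DeviceSerialNumber",           "0018", "1000", "LO"),
    c("SoftwareVersions",             "0018", "1020", "LO"),
    c("ProtocolName",                 "0018", "1030", "LO"),
    c("StudyInstanceUID",             "0020", "000D", "UI"),
    c("SeriesInstanceUID",            "0020", "000E", "UI"),
    c("StudyID",                      "0020", "0010", "SH"),
    c("SeriesNumber",                 "0020", "0011", "IS"),
    c("InstanceNumber",               "0020", "0013", "IS"),
    c("FrameOfReferenceUID",          "0020", "0052", "UI"),
    c("ImageComments",                "0020", "4000", "LT"),
    c("SamplesPerPixel",              "0028", "0002", "US"),
    c("PhotometricInterpretation",    "0028", "0004", "CS"),
    c("PlanarConfiguration",          "0028", "0006", "US"),
    c("NumberOfFrames",               "0028", "0008", "IS"),
    c("Rows",                         "0028", "0010", "US"),
    c("Columns",                      "0028", "0011", "US"),
    c("BitsAllocated",                "0028", "0100", "US"),
    c("BitsStored",                   "0028", "0101", "US"),
    c("HighBit",                      "0028", "0102", "US"),
    c("PixelRepresentation",          "0028", "0103", "US"),
    c("TotalPixelMatrixColumns",      "0048", "0006", "UL"),
    c("TotalPixelMatrixRows",         "0048", "0007", "UL"),
    c("PixelData",                    "7FE0", "0010", "OW")
  )
  data.frame(keyword = d[, 1],
             group = strtoi(d[, 2], 16L),
             element = strtoi(d[, 3], 16L),
             vr = d[, 4],
             stringsAsFactors = FALSE)
})

#' Look up a DICOM attribute by keyword
#'
#' @param keyword attribute keyword, e.g. `"PatientName"`.
#' @return list with `group`, `element`, `vr`, or `NULL` if unknown.
#' @keywords internal
dicom_lookup <- function(keyword) {
  i <- match(keyword, .dicom_dict$keyword)
  if (is.na(i)) return(NULL)
  as.list(.dicom_dict[i, c("group", "element", "vr")])
}

dicom_keyword <- function(group, element) {
  i <- which(.dicom_dict$group == group & .dicom_dict$element == element)
  if (length(i) == 0) return(NA_character_)
  .dicom_dict$keyword[i[1]]
}

#' @keywords internal
tag_string <- function(group, element) {
  sprintf("%04X%04X", group, element)
}

# Standard UIDs used by the writer and the WSI classifier
.uid_explicit_vr_le <- "1.2.840.10008.1.2.1"
.uid_mr_image_storage <- "1.2.840.10008.5.1.4.1.1.4"
.uid_vl_wsi_storage <- "1.2.840.10008.5.1.4.1.1.77.1.6"
.uid_implementation_class <- "1.2.826.0.1.3680043.10.1405.1"
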