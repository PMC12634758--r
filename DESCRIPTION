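Package: imdeid
Title: De-Identification of Medical Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: De-identifies medical imaging data across the formats found in
    clinical and research practice. Applies configurable action profiles
    (remove, zero, replace, UID remap, date cleaning) to DICOM metadata,
    scrubs the free-text fields of NIfTI-1 headers, performs byte-length
    preserving redaction of the ASCII protocol headers embedded in Siemens
    twix raw-data files, blanks the label image and redacts the overview
    image of DICOM whole-slide-image studies, removes burned-in text from
    2D images with a two-pass OCR pipeline, applies binary brain or face
    masks to volumes, and scores defacing results with a pluggable face
    detector. Ships a synthetic fixture generator so every pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    RNifti,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
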