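# imdeid

De-identification of medical imaging data, in one R package: DICOM metadata
via configurable action profiles, NIfTI-1 header scrubbing, byte-length
preserving redaction of Siemens twix raw-data headers, DICOM whole-slide
label/overview cleaning, two-pass OCR removal of burned-in text, binary
mask application for skull-stripping/defacing outputs, and a defacing-score
evaluator.

## Who this is for

Researchers and clinical data managers who must strip Protected Health
Information (PHI) from imaging data before sharing it. PHI hides in more
places than the obvious metadata header: the large protocol text inside MRI
raw files duplicates the whole patient record; a pathology slide's label
image is a photograph of the patient sticker; ultrasound exports burn
identifiers straight into the pixels; and a head scan's facial surface can
be reconstructed into an identifiable face. Each of these channels has its
own module here, behind one dispatching entry point.

## The core machinery

* **Profile engine** — ordered tag rules (`REMOVE`, `ZERO`,
  `REPLACE_FIXED`, `REMAP_UID`, `CLEAN_DATE`, `KEEP`), first match wins,
  with a curated built-in `basic` profile, extension overlays
  (`retain-device-identity`, `retain-patient-characteristics`,
  `retain-longitudinal-dates`) and user-suppliable YAML/JSON profile
  documents. UIDs are remapped injectively and consistently within a
  session, so study/series/instance cross-references survive.
* **Length-preserving twix scrub** — every ASCII header of every
  measurement is scanned for patient keys; quoted values become `x`-runs,
  numeric values `0`-runs of identical length, so no byte offset in the
  binary container moves: `|output| == |input|`, k-space untouched.
* **NIfTI scrub** — zeroes the only two patient-relatable header text
  fields (`descrip`, `intent_name`) and drops header extensions; every
  other byte of the file is copied verbatim.
* **WSI redaction** — label pixel array overwritten with zeros (or the
  label instance dropped for converted studies), left side of the overview
  zeroed, pyramid pixels conserved, metadata through the profile engine.
* **Two-pass text removal** — pass 1 runs OCR with a white rectangle over
  the image centre so detection focuses on the border; pass 2 removes the
  rectangle and re-detects, catching central text; the union of
  letter-containing boxes is filled. Engines are pluggable adapters; a
  deterministic stub ships for testing.
* **Defacing score** — `100 * (n_total - n_detected) / n_total` over a
  batch: the percentage of scans whose frontal rendering (maximum-intensity
  projection along the anterior axis after RAS reorientation) a face
  detector no longer classifies as a face.
* **Fixture generators** — every supported format, with high-entropy PHI
  sentinels and manifests, so the whole pipeline is testable offline.

## Worked example

```r
library(imdeid)

src <- file.path(tempdir(), "ex"); out <- file.path(tempdir(), "ex_out")
man <- make_dicom_series(file.path(src, "mr"), 3, seed = 42)
tw  <- make_twix(file.path(src, "scan.dat"), n_measurements = 2, seed = 42)
nf  <- make_nifti_with_phi(file.path(src, "brain.nii.gz"), seed = 42)

res <- imdeid_run(src, out, profile = "basic")
res$summary
#>      ok  failed skipped
#>       5       0       0
```

Five files (3 DICOM instances, 1 twix file, 1 NIfTI volume) were routed to
their modules and de-identified. The planted patient name is a random
sentinel, e.g. `"IY094ET71C6X^KOVH9DVR1ED7"`; a byte-level search for it
across every output file finds 0 occurrences. Re-reading a de-identified
instance shows what the basic profile did:

```r
ds <- read_dicom(list.files(file.path(out, "mr"), full.names = TRUE)[1])$attrs
dicom_get(ds, "PatientName")       # NULL       — removed
dicom_get(ds, "StudyDate")         # "19000101" — cleaned to the fixed anchor
dicom_get(ds, "StudyInstanceUID")  # "1.2.826.0.1.3680043.10.1405.2.2"
                                   #            — remapped, same in all 3 files
```

The twix scrubber replaces values in place, preserving every byte length:

```r
scrub_twix_text('tPatientName = "MUSTERMANN"\nPatientID = 12345678')$text
#> tPatientName = "xxxxxxxxxx"
#> PatientID = 00000000
```

And the defacing evaluator scores a batch of volumes against a detector
adapter (here a silhouette mock on a phantom before and after
skull-stripping):

```r
ph  <- make_head_phantom(with_face = TRUE, seed = 1)
det <- list(name = "silhouette",
            detect = function(img) as.integer(sum(img > 0) > 400))
defacing_score(list(ph$volume, apply_mask(ph$volume, ph$mask)), det)
#> Defacing score: 50.00% (1 of 2 scans no longer detected)
```

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/imdeid.R", package="imdeid"))')" \
    run --in input_dir --out output_dir --profile basic
```

## Documentation

`vignettes/deidentification-methods.Rmd` describes the models and
procedures, the parameters that matter and their defaults, what the
synthetic fixtures do and do not demonstrate, and known limitations.
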