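---
title: "De-identification methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De-identification methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imdeid)
```

## The problem

Medical images carry Protected Health Information (PHI) in several distinct
places: structured metadata headers (DICOM attributes, NIfTI free-text
fields, the ASCII protocol headers embedded in Siemens twix raw files),
photographic sub-images of a pathology slide's sticker, text burned into
the pixel raster itself (ubiquitous in ultrasound exports), and the
patient's facial anatomy in head scans, which modern reconstruction methods
can turn into an identifiable face. A de-identification tool that handles
only one of these channels leaves the others open; `imdeid` covers all of
them behind one dispatching entry point, with each format handled by a
dedicated module.

De-identification is the removal or concealment of direct identifiers. It
is deliberately weaker than anonymization (irreversible unlinkability) and
distinct from pseudonymization (reversible through a key). Several design
choices below follow from taking that scope seriously.

## Metadata profiles

The profile engine applies an ordered list of tag rules to an attribute
set. Each rule has a selector (exact tag, keyword, glob, `private:*` for
odd-group private tags, or `kind:` for a value class such as `uid` or
`date`) and one of six actions: `REMOVE`, `ZERO`, `REPLACE_FIXED`,
`REMAP_UID`, `CLEAN_DATE`, `KEEP`. The first matching rule wins and a
default action covers the remainder. First-match-wins was chosen over
specificity scoring because it is deterministic and auditable: the profile
document *is* the precedence order.

The built-in `basic` profile encodes a curated list: patient identity,
physician, institution, description and comment attributes are removed;
every UID is remapped; dates are cleaned; times are zeroed; all private
tags are removed; technical acquisition attributes fall through to `KEEP`.
The DICOM standard's full confidentiality table is far larger; the curated
list is shipped as data and extensible through profile documents (YAML or
JSON), which is the supported path for site-specific policy. Three common
extension profiles ship as rule overlays prepended to the basic rules --
`retain-device-identity`, `retain-patient-characteristics` (sex, age, size,
weight, ethnic group) and `retain-longitudinal-dates` -- and user documents
can define any further overlay.

Two decisions deserve justification:

* **`CLEAN_DATE` anchors rather than shifts.** Date shifting preserves
  intervals but requires a per-patient offset that must be stored somewhere
  to be consistent across studies -- that stored offset is a
  pseudonymization key. Since the tool's scope is de-identification, dates
  are replaced by a fixed anchor (`19000101`). Users who need longitudinal
  structure keep dates with the `retain-longitudinal-dates` overlay and
  accept the disclosure risk consciously.
* **Reports never contain removed values.** A modification record stores
  tag, keyword, action and value *kind* only. A report that quoted the old
  values would itself be PHI and could not be archived alongside the
  outputs.

UID remapping is session-scoped: one `uid_map()` is shared across all files
of an invocation, so a series that references its study, or an instance
that references another instance, keeps consistent (but fresh) identifiers.
Replacement UIDs are `<root><counter>` under a fixed dotted-numeric root,
which guarantees injectivity, the 64-character DICOM limit, and
recognisability: a UID already under the root is returned unchanged, which
is what makes profile application idempotent.

## DICOM handling

The package reads and writes DICOM Part 10 with its own small codec
(Explicit VR Little Endian, nested sequences with defined and undefined
lengths, native 8/16-bit pixel data). The file-meta group is regenerated on
write rather than rule-processed: its integrity is structural (the media
storage SOP instance UID must echo the dataset's remapped SOP instance
UID), not a policy matter. Outputs are stamped with
`DeidentificationMethod` and `PatientIdentityRemoved` so downstream readers
can see what was done. When pixels are untouched the decoded arrays are
bit-identical before and after, which the tests assert. Compressed transfer
syntaxes and DICOM networking are out of scope.

## NIfTI scrubbing

The NIfTI-1 fixed header contains exactly two free-text fields that can
carry patient-relatable content: `descrip` (80 bytes at offset 148) and
`intent_name` (16 bytes at offset 328). `scrub_nifti()` zeroes those byte
ranges directly in the file, which makes the conservation guarantee
trivial: every other header byte and the entire voxel payload are copied
verbatim. Header extension blocks are stripped entirely -- a deliberate
superset of the two-field rule, because extensions routinely embed DICOM
fragments or acquisition descriptions whose content cannot be audited
generically. Gzipped and plain files are both handled; output compression
follows the input. NIfTI-2 and CIFTI are out of scope.

## Twix raw-data scrubbing

A twix `.dat` container stores k-space samples plus one or more ASCII
protocol headers. The k-space is not viewable anatomy, so only headers need
scrubbing -- but *every* header copy must be scrubbed: the large protocol
text block duplicates the full patient record, and a tool that cleans only
the compact metadata block produces a file from which the identifiers can
be restored on the next save.

All replacements are length-preserving: quoted values are filled with `x`,
unquoted numeric values with `0`, character for character. This is stricter
than cosmetic fidelity: the container's measurement table stores absolute
byte offsets, so any length change would corrupt the file. Whether a value
is x-filled or zero-filled is decided by syntax (quoted vs. bare), not by
key, which resolves ambiguities like a birthdate stored as quoted text. The
default key list (name, ID, birthdate, sex, age, weight, height, position,
address, comment, referring physician, institution, device serial) ships as
data and is user-extensible; keys match exact-or-prefix, case-sensitively,
on either the full dotted parameter token or its final component. In files
with several measurements, every measurement is scrubbed -- scrubbing only
the most recent one would leave complete patient records in the earlier
ones.

The parser handles the simplified multi-measurement and single-measurement
layouts that the fixture generator emits (magic/count words, an
offset/length table, named header blocks with length prefixes, binary
payload). The layouts are structurally faithful to the real container --
table-addressed measurements, multiple named text blocks per measurement --
but the generator is not a scanner emulator; the scrubbing logic itself is
agnostic to how spans were located.

## WSI de-identification

A DICOM whole-slide study is classified into pyramid (VOLUME), OVERVIEW and
LABEL instances from the ImageType attribute. The label image is a
photograph of the slide sticker and is wholly identifying, so its entire
pixel array is set to zero, preserving geometry and photometric
interpretation. The overview often catches part of the sticker at its left
edge; columns left of `floor(fraction * width)` are zeroed in every
channel. The fraction defaults to 0.5 -- a deliberate over-redaction, since
the sticker's extent varies by scanner -- and is exposed as a parameter.
For studies converted from native vendor formats the label instance is
dropped from the output entirely rather than blanked, because converted
label pixel data does not always decode reliably; `converted` is an
explicit flag rather than an auto-detection, since conversion provenance
tags are inconsistent. Metadata of every instance goes through the same
profile engine and shared UID map as ordinary DICOM, and pyramid pixels are
copied untouched (checksummed in the tests). Native slide formats
(SVS/MRXS/NDPI) are out of scope.

## Burned-in text removal

Text removal runs an OCR engine twice. Pass 1 covers the centre of the
image with a white rectangle (default: half of each dimension, centred) so
detection concentrates on the border region, where scanner annotations
live; pass 2 removes the rectangle, fills the pass-1 boxes, and detects
again, picking up text in the image centre that the rectangle occluded.
The union of letter-containing boxes from both passes is filled. Two passes
are the default; the pass count is a parameter.

A box "contains letters" if its detected text, stripped, is non-empty with
at least one alphanumeric character and detector confidence of at least
0.3. The fill is white (the top of the value range) by default, matching
the visual convention of redacted ultrasound exports, and configurable to
black or any level. Pixels outside the union of boxes are never touched,
and the per-image report records geometry and confidence but not the
recognised text (which would be PHI). The batch score is all-or-nothing
per image: an image counts as de-identified only if every planted box is
fully covered.

The test double for OCR is deliberately occlusion-aware: the stub engine
returns a manifest box only while less than half of the box's area sits at
the white level. That single rule reproduces the behaviour the two-pass
design exploits -- a real engine stops seeing text that is covered -- and
makes the pass-1/pass-2 interaction deterministically testable without an
OCR binary. It also bounds what the tests show: they verify the pipeline's
logic (occlusion, union, fill locality, scoring), not the recognition
accuracy of any particular OCR engine on real scans. A real engine is
plugged in through the same one-function adapter (`detect(image)` returning
boxes).

## Masks, preprocessing, and the defacing score

Skull-strip and deface segmentation models are consumed, not shipped: the
package takes any binary mask on the volume's grid (nearest-neighbour
resampled if shapes differ) and zeroes voxels outside it, never altering a
voxel inside. The preprocessing mirrors what a segmentation network front
end needs: reorientation to RAS (axis permutation and flips derived from
the affine's dominant directions, with the affine updated so every voxel
keeps its world coordinate), min-max normalization, trilinear resize to
`(64, 224, 224)`, then standardization to zero mean and unit variance. The
resize uses endpoint-aligned separable linear interpolation, so resizing to
the native shape is exactly the identity; a constant-intensity volume maps
to all zeros rather than NaN.

The defacing score of a batch is `100 * (n_total - n_detected) / n_total`:
the percentage of scans whose frontal rendering a face detector no longer
classifies as a face. The frontal rendering is a maximum-intensity
projection along the anterior axis of the RAS-reoriented volume, min-max
scaled to 0..255, with the superior axis upward. An interactive volume
renderer would produce a shaded surface view instead; the projection is a
deterministic approximation that runs unattended, and the detector adapter
boundary (`detect(image)` returning a face count) accepts screenshots from
any renderer or any detection library. Scans on which the detector fails
are excluded from the total with a warning rather than silently counted
either way. The bundled detectors are mocks for testing; reproducing a
specific published score would additionally require the corresponding
trained defacing model and test cohort, which are outside this package's
scope.

## Synthetic fixtures and what passing tests mean

Every format has a generator that is a pure function of parameters and a
seed, and every generator returns a manifest that fully accounts for the
PHI it planted. Sentinels are 12-character high-entropy alphanumerics (or
12-digit runs for numeric fields), so a byte-level search of an output file
against the manifest is an unambiguous eradication oracle: the probability
of an accidental match in unrelated bytes is negligible.

The generators emulate structure, not content: geometric head phantoms
(ellipsoids with an optional anterior protrusion), noise backgrounds, solid
glyph blocks for text, random bytes for k-space. Passing tests therefore
demonstrate that the pipelines remove what the manifests planted, conserve
what they must conserve, and compose correctly -- they do not demonstrate
OCR accuracy on real ultrasound fonts, face-detector behaviour on real
renderings, or parser coverage of every scanner software version. Those
depend on the pluggable engines and on real data, and are explicitly
integration concerns.

Problem sizes in the test-suite and verification runs (tens of DICOM
instances, dozens of twix files, three-level pyramids, `32^3`-scale
phantoms) were chosen as the smallest sizes at which every structural
property -- nesting, multi-measurement layouts, multi-level studies,
orientation permutations -- is actually exercised.

## Numerical and degenerate-input choices

* Boxes and voxel indices are 0-based with half-open extents
  (`[x, x + w)`), top-left origin for images; affines map 0-based voxel
  indices to world millimetres.
* Orientation codes are derived greedily from the affine's
  largest-magnitude column components, resolving ties by axis order; a
  singular affine is an error.
* A profile with no matching rule falls to the profile's default action;
  unknown attributes are never an error.
* Zero-byte, truncated, or wrong-magic files produce a `failed` report
  entry and no partial output file.
* An empty input directory is a success with an empty report; a directory
  with failures exits with status 1 after processing everything it could.

## Known limitations

* The DICOM codec handles uncompressed Explicit VR Little Endian only;
  compressed syntaxes must be transcoded externally first.
* The twix locator parses the simplified layout documented above; real
  scanner files with vendor padding and evolved table formats may need an
  adapted locator (the scrubber is reusable as-is).
* Burned-in text removal removes *all* detected text, including clinically
  useful annotations -- it does not classify text as PHI vs. non-PHI.
* The basic profile is a curated subset of the standard's confidentiality
  table, not a transcription; sites with stricter requirements should
  supply their own profile documents (e.g. removing every string-valued
  tag).
* Free-text attributes that survive a permissive profile can contain
  manually entered patient information; that risk is a policy choice, not
  detectable by the engine.
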