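# DICOM file and directory de-identification.

#' De-identify a single DICOM file
#'
#' Reads a Part 10 file, applies the profile to its main dataset, stamps the
#' de-identification method attributes, regenerates the file-meta group (so
#' MediaStorageSOPInstanceUID echoes the remapped SOPInstanceUID) and writes
#' the result. Pixel data is untouched unless a pixel-cleaning policy asks
#' for burned-in text removal or mask application.
#'
#' @param in_path input DICOM file.
#' @param out_path output path (parent directories created).
#' @param profile a [deid_profile()] or a name/path accepted by
#'   [load_profile()].
#' @param map shared [uid_map()]; pass the same map for all files of a study
#'   so cross-references stay consistent.
#' @param pixel_clean optional policy list: `text_removal = TRUE` with an
#'   `ocr` engine (see [stub_ocr_engine()]) and optional `rect_fraction`,
#'   `fill`, `min_confidence`; or `mask = <array>` to zero voxels outside a
#'   binary mask.
#' @return a [report_entry()]. On failure, `status = "failed"` and no output
#'   file is written.
#' @export
deid_dicom_file <- function(in_path, out_path, profile = "basic",
                            map = uid_map(), pixel_clean = NULL) {
  profile <- load_profile(profile)
  res <- tryCatch({
    obj <- read_dicom(in_path)
    app <- apply_profile(obj$attrs, profile, map)
    attrs <- app$attrs
    attrs <- dicom_set(attrs, "PatientIdentityRemoved", "YES")
    attrs <- dicom_set(attrs, "DeidentificationMethod",
                       paste0("imdeid profile=", profile$name))
    pix_summary <- NULL
    if (!is.null(pixel_clean)) {
      cleaned <- clean_dicom_pixels(attrs, pixel_clean)
      attrs <- cleaned$attrs
      pix_summary <- cleaned$summary
    }
    dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
    write_dicom(attrs, out_path)
    report_entry(in_path, "dicom", status = "ok", records = app$records,
                 pixel_summary = pix_summary)
  }, error = function(e) {
    if (file.exists(out_path)) unlink(out_path)
    report_entry(in_path, "dicom", status = "failed",
                 error = conditionMessage(e))
  })
  res
}

clean_dicom_pixels <- function(attrs, policy) {
  summary <- list()
  if (isTRUE(policy$text_removal)) {
    if (is.null(policy$ocr)) stop("text_removal requires an 'ocr' engine")
    arr <- dicom_pixel_array(attrs)
    if (length(dim(arr)) != 2) {
      stop("text removal supports single-frame monochrome images")
    }
    rng <- range(arr)
    img <- if (rng[2] > rng[1]) (arr - rng[1]) / (rng[2] - rng[1]) else arr * 0
    fill <- if (identical(policy$fill, "black")) 0 else 1
    res <- remove_text(img, policy$ocr,
                       rect_fraction = policy$rect_fraction %||% 0.5,
                       fill_value = fill,
                       min_confidence = policy$min_confidence %||% 0.3)
    out <- round(res$image * (rng[2] - rng[1]) + rng[1])
    bits <- as.integer(dicom_get(attrs, "BitsAllocated"))
    attrs <- dicom_set(attrs, "PixelData",
                       dicom_encode_pixels(array(out, dim = dim(arr)), bits),
                       vr = "OW")
    summary$text_boxes <- nrow(res$report)
  }
  if (!is.null(policy$mask)) {
    arr <- dicom_pixel_array(attrs)
    mask <- policy$mask
    if (!identical(dim(mask), dim(arr))) stop("mask shape mismatch")
    arr[!mask] <- 0L
    bits <- as.integer(dicom_get(attrs, "BitsAllocated"))
    attrs <- dicom_set(attrs, "PixelData", dicom_encode_pixels(arr, bits),
                       vr = "OW")
    summary$masked <- TRUE
  }
  list(attrs = attrs, summary = if (length(summary)) summary else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' De-identify a directory of DICOM files
#'
#' Mirrors the directory tree under `out_dir`. All files share one
#' [uid_map()], so intra-study references (Study/Series UIDs, referenced SOP
#' instances) remain consistent across outputs. Non-DICOM files are recorded
#' as skipped; per-file failures are recorded and processing continues.
#'
#' @param in_dir input directory.
#' @param out_dir output directory (created).
#' @param profile profile or name accepted by [load_profile()].
#' @param map shared [uid_map()] (a fresh one by default).
#' @param pixel_clean optional pixel policy, see [deid_dicom_file()].
#' @param report_path optional path for a JSON-lines report.
#' @return list of [report_entry()] objects.
#' @export
deid_dicom_directory <- function(in_dir, out_dir, profile = "basic",
                                 map = uid_map(), pixel_clean = NULL,
                                 report_path = NULL) {
  if (!dir.exists(in_dir)) stop("input directory does not exist: ", in_dir)
  profile <- load_profile(profile)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(in_dir, recursive = TRUE, full.names = FALSE)
  entries <- list()
  for (f in files) {
    inp <- file.path(in_dir, f)
    outp <- file.path(out_dir, f)
    if (!is_dicom_file(inp)) {
      entries[[length(entries) + 1]] <-
        report_entry(inp, "unknown", status = "skipped",
                     error = "not a DICOM Part 10 file")
      next
    }
    entries[[length(entries) + 1]] <-
      deid_dicom_file(inp, outp, profile, map, pixel_clean)
  }
  if (!is.null(report_path)) write_report(entries, report_path)
  entries
}
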