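# DICOM whole-slide-image (WSI) de-identification.
#
# A DICOM-WSI study is a hierarchy: pyramid instances (the zoom levels), an
# overview (macro) image, and a label image photographing the slide sticker
# -- which is where patient identifiers live. The label is blanked to zeros
# (or dropped entirely for studies converted from other vendor formats,
# whose label pixel data may not decode reliably), the left region of the
# overview is overwritten, metadata goes through the shared profile engine,
# and pyramid pixels are copied untouched.

.wsi_roles <- c("VOLUME", "OVERVIEW", "LABEL")

instance_role <- function(ds) {
  sop <- dicom_get(ds, "SOPClassUID")
  if (is.null(sop) || !identical(sop, .uid_vl_wsi_storage)) return(NA_character_)
  it <- dicom_get(ds, "ImageType")
  role <- intersect(.wsi_roles, it)
  if (length(role) != 1) return(NA_character_)
  role
}

#' Classify the instances of a DICOM-WSI study
#'
#' Assigns each file a role from its ImageType attribute (VOLUME pyramid
#' level, OVERVIEW, LABEL). Files that are not WSI instances, or whose role
#' cannot be determined, are listed as skipped.
#'
#' @param paths character vector of DICOM file paths.
#' @return a `wsi_study` list: `pyramid` (paths), `overview` (path or
#'   `NULL`), `label` (path or `NULL`), `skipped` (data.frame path/reason).
#' @export
classify_wsi_instances <- function(paths) {
  pyramid <- character(0)
  overview <- NULL
  label <- NULL
  skipped <- list()
  skip <- function(p, why) {
    skipped[[length(skipped) + 1]] <<- list(path = p, reason = why)
  }
  for (p in paths) {
    if (!is_dicom_file(p)) { skip(p, "not a DICOM Part 10 file"); next }
    ds <- tryCatch(read_dicom(p)$attrs, error = function(e) NULL)
    if (is.null(ds)) { skip(p, "unreadable DICOM"); next }
    role <- instance_role(ds)
    if (is.na(role)) { skip(p, "not a WSI instance or unknown role"); next }
    if (role == "VOLUME") pyramid <- c(pyramid, p)
    else if (role == "OVERVIEW") {
      if (!is.null(overview)) skip(p, "duplicate overview") else overview <- p
    } else {
      if (!is.null(label)) skip(p, "duplicate label") else label <- p
    }
  }
  if (length(pyramid) == 0) stop("no pyramid (VOLUME) instances found")
  skipdf <- if (length(skipped)) {
    do.call(rbind, lapply(skipped, as.data.frame, stringsAsFactors = FALSE))
  } else data.frame(path = character(0), reason = character(0))
  structure(list(pyramid = pyramid, overview = overview, label = label,
                 skipped = skipdf),
            class = "wsi_study")
}

#' Blank a label instance's pixel data
#'
#' Overwrites the whole pixel array with zeros; dimensions, photometric
#' interpretation and every other attribute are unchanged.
#'
#' @param ds dataset of a label instance.
#' @return the dataset with all-zero PixelData.
#' @export
blank_label <- function(ds) {
  px <- dicom_get(ds, "PixelData")
  if (is.null(px)) stop("label instance has no pixel data")
  dicom_set(ds, "PixelData", raw(length(px)),
            vr = ds[[tag_string(0x7FE0, 0x0010)]]$vr)
}

#' Redact the left region of an overview image
#'
#' Sets pixel columns `[0, floor(fraction * width))` to zero in every frame
#' and channel; the remaining columns are untouched.
#'
#' @param ds dataset of an overview instance.
#' @param fraction fraction of the width to overwrite, in `(0, 1]`.
#' @return the dataset with redacted PixelData.
#' @export
redact_overview <- function(ds, fraction = 0.5) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  arr <- dicom_pixel_array(ds)
  d <- dim(arr)
  ncols <- d[2]
  cut <- floor(fraction * ncols)
  if (cut > 0) {
    if (length(d) == 2) arr[, seq_len(cut)] <- 0L
    else if (length(d) == 3) arr[, seq_len(cut), ] <- 0L
    else arr[, seq_len(cut), , ] <- 0L
  }
  bits <- as.integer(dicom_get(ds, "BitsAllocated"))
  dicom_set(ds, "PixelData", dicom_encode_pixels(arr, bits),
            vr = ds[[tag_string(0x7FE0, 0x0010)]]$vr)
}

#' De-identify a DICOM-WSI study
#'
#' Classifies the instances under `in_dir`, scrubs every instance's
#' metadata with the profile engine (one shared UID map keeps the study
#' coherent), blanks the label (or omits it when `converted = TRUE`),
#' redacts the overview, and copies pyramid pixel data untouched.
#'
#' @param in_dir directory with the study's DICOM files.
#' @param out_dir output directory.
#' @param profile profile or name accepted by [load_profile()].
#' @param map shared [uid_map()].
#' @param overview_fraction fraction of overview width to overwrite.
#' @param converted `TRUE` for studies converted from other slide formats:
#'   the label instance is then removed entirely instead of blanked.
#' @param report_path optional JSON-lines report path.
#' @return list of [report_entry()] objects.
#' @export
deid_wsi_study <- function(in_dir, out_dir, profile = "basic",
                           map = uid_map(), overview_fraction = 0.5,
                           converted = FALSE, report_path = NULL) {
  profile <- load_profile(profile)
  paths <- list.files(in_dir, recursive = TRUE, full.names = TRUE)
  study <- classify_wsi_instances(paths)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  process <- function(p, role) {
    entry <- tryCatch({
      obj <- read_dicom(p)
      app <- apply_profile(obj$attrs, profile, map)
      attrs <- app$attrs
      attrs <- dicom_set(attrs, "PatientIdentityRemoved", "YES")
      attrs <- dicom_set(attrs, "DeidentificationMethod",
                         paste0("imdeid profile=", profile$name))
      pix <- NULL
      if (role == "LABEL") {
        attrs <- blank_label(attrs)
        pix <- list(label_blanked = TRUE)
      } else if (role == "OVERVIEW") {
        attrs <- redact_overview(attrs, overview_fraction)
        pix <- list(overview_fraction = overview_fraction)
      }
      write_dicom(attrs, file.path(out_dir, basename(p)))
      report_entry(p, "dicom_wsi", status = "ok", records = app$records,
                   pixel_summary = pix)
    }, error = function(e) {
      report_entry(p, "dicom_wsi", status = "failed",
                   error = conditionMessage(e))
    })
    entries[[length(entries) + 1]] <<- entry
  }
  for (p in study$pyramid) process(p, "VOLUME")
  if (!is.null(study$overview)) process(study$overview, "OVERVIEW")
  if (!is.null(study$label)) {
    if (converted) {
      entries[[length(entries) + 1]] <-
        report_entry(study$label, "dicom_wsi", status = "ok",
                     pixel_summary = list(label_removed = TRUE))
    } else {
      process(study$label, "LABEL")
    }
  }
  for (i in seq_len(nrow(study$skipped))) {
    entries[[length(entries) + 1]] <-
      report_entry(study$skipped$path[i], "unknown", status = "skipped",
                   error = study$skipped$reason[i])
  }
  if (!is.null(report_path)) write_report(entries, report_path)
  entries
}
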