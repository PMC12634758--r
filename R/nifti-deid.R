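# NIfTI-1 header de-identification.
#
# The NIfTI-1 fixed header holds exactly two free-text fields that can carry
# patient-relatable information: descrip (80 bytes at offset 148) and
# intent_name (16 bytes at offset 328). The scrub operates directly on the
# file bytes so every other header field and the voxel payload are
# bit-identical by construction. Header extension blocks are stripped
# entirely: they may embed DICOM fragments with PHI. That is a deliberate
# superset of the two-field rule.

.nifti_descrip_offset <- 148L
.nifti_descrip_len <- 80L
.nifti_intent_name_offset <- 328L
.nifti_intent_name_len <- 16L

read_file_bytes <- function(path) {
  # transparently inflate gzip; report whether input was gzipped
  head <- readBin(path, "raw", n = 2)
  gz <- length(head) == 2 && head[1] == as.raw(0x1f) && head[2] == as.raw(0x8b)
  if (gz) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    chunks <- list()
    repeat {
      b <- readBin(con, "raw", n = 1048576L)
      if (length(b) == 0) break
      chunks[[length(chunks) + 1]] <- b
    }
    list(bytes = do.call(c, chunks), gz = TRUE)
  } else {
    list(bytes = readBin(path, "raw", n = file.info(path)$size), gz = FALSE)
  }
}

write_file_bytes <- function(bytes, path, gz) {
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  invisible(path)
}

nifti_endian <- function(bytes) {
  le <- readBin(bytes[1:4], "integer", size = 4, endian = "little")
  if (le == 348L) return("little")
  be <- readBin(bytes[1:4], "integer", size = 4, endian = "big")
  if (be == 348L) return("big")
  NA_character_
}

#' Scrub the patient-relatable text fields of a NIfTI-1 file
#'
#' Zeroes the `descrip` and `intent_name` header fields and drops any header
#' extension blocks; all other header fields and the voxel payload are
#' byte-identical to the input. Accepts plain or gzipped NIfTI-1; output
#' compression follows the input.
#'
#' @param in_path input `.nii` / `.nii.gz` file.
#' @param out_path output path.
#' @return a [report_entry()] (`status = "failed"` for non-NIfTI input, in
#'   which case no output is written).
#' @export
scrub_nifti <- function(in_path, out_path) {
  res <- tryCatch({
    f <- read_file_bytes(in_path)
    b <- f$bytes
    if (length(b) < 352) stop("not a NIfTI-1 file (too small)")
    magic <- rawToChar(b[345:347])
    if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")
    endian <- nifti_endian(b)
    if (is.na(endian)) stop("not a NIfTI-1 file (sizeof_hdr != 348)")
    records <- list()
    blank <- function(off, len, name) {
      span <- (off + 1):(off + len)
      if (any(b[span] != as.raw(0))) {
        b[span] <<- as.raw(0)
        records[[length(records) + 1]] <<- list(tag = name, keyword = name,
                                                action = "ZERO", kind = "text")
      }
    }
    blank(.nifti_descrip_offset, .nifti_descrip_len, "descrip")
    blank(.nifti_intent_name_offset, .nifti_intent_name_len, "intent_name")
    if (magic == "n+1") {
      vox_offset <- readBin(b[109:112], "numeric", size = 4, endian = endian)
      has_ext <- b[349] != as.raw(0)
      if (has_ext && vox_offset > 352) {
        payload <- b[(vox_offset + 1):length(b)]
        b <- c(b[1:348], as.raw(c(0, 0, 0, 0)), payload)
        b[109:112] <- writeBin(352, raw(), size = 4, endian = endian)
        records[[length(records) + 1]] <- list(tag = "extensions",
                                               keyword = "extensions",
                                               action = "REMOVE",
                                               kind = "binary")
      }
    }
    dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
    write_file_bytes(b, out_path, f$gz)
    recdf <- if (length(records)) {
      do.call(rbind, lapply(records, as.data.frame, stringsAsFactors = FALSE))
    } else {
      data.frame(tag = character(0), keyword = character(0),
                 action = character(0), kind = character(0))
    }
    report_entry(in_path, "nifti", status = "ok", records = recdf)
  }, error = function(e) {
    report_entry(in_path, "nifti", status = "failed",
                 error = conditionMessage(e))
  })
  res
}

#' Quick check whether a file looks like NIfTI-1
#' @keywords internal
is_nifti_file <- function(path) {
  ok <- tryCatch({
    f <- read_file_bytes(path)
    length(f$bytes) >= 348 &&
      rawToChar(f$bytes[345:347]) %in% c("n+1", "ni1") &&
      !is.na(nifti_endian(f$bytes))
  }, error = function(e) FALSE)
  ok
}
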