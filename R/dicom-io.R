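# Minimal DICOM Part 10 reader/writer.
#
# Scope: uncompressed Explicit VR Little Endian datasets, nested sequences
# (defined and undefined length), native 8/16-bit pixel data. That is the
# encoding the fixture generator emits and the de-identification pipeline
# rewrites; compressed transfer syntaxes are out of scope.
#
# Datasets are represented as ordered named lists of elements; each element
# is list(group, element, vr, value). Names are "GGGGEEEE" tag strings.
# Sequence (SQ) values are lists of item datasets.

.vr_long_form <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.vr_string <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                "PN", "SH", "ST", "TM", "UC", "UI", "UR", "UT")
.vr_no_split <- c("LT", "ST", "UT", "UR")
.vr_known <- c(.vr_string, .vr_long_form, "US", "UL", "SS", "SL", "FL",
               "FD", "AT")

u16_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256))
}

u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256,
           (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

raw_u16 <- function(b) as.integer(b[1]) + 256L * as.integer(b[2])

raw_u32 <- function(b) {
  as.numeric(b[1]) + 256 * as.numeric(b[2]) +
    65536 * as.numeric(b[3]) + 16777216 * as.numeric(b[4])
}

#' Construct a DICOM data element
#'
#' @param group,element tag numbers (integers).
#' @param vr two-letter value representation.
#' @param value element value: character vector for string VRs, numeric for
#'   binary numeric VRs, raw for OB/OW/UN, list of item datasets for SQ.
#' @return an element list, suitable for inclusion in a dataset.
#' @keywords internal
dicom_element <- function(group, element, vr, value) {
  list(group = as.integer(group), element = as.integer(element),
       vr = vr, value = value)
}

#' Build a DICOM dataset from keyword/value pairs
#'
#' Convenience constructor used by the fixture generator and tests. Values
#' are encoded with the dictionary VR for the keyword. Sequence values are
#' given as lists of datasets.
#'
#' @param ... named values; names are dictionary keywords.
#' @return an ordered dataset (named list of elements), sorted by tag.
#' @export
dicom_dataset <- function(...) {
  vals <- list(...)
  ds <- list()
  for (kw in names(vals)) {
    ent <- dicom_lookup(kw)
    if (is.null(ent)) stop("unknown DICOM keyword: ", kw)
    el <- dicom_element(ent$group, ent$element, ent$vr, vals[[kw]])
    ds[[tag_string(ent$group, ent$element)]] <- el
  }
  dicom_sort(ds)
}

dicom_sort <- function(ds) {
  if (length(ds) == 0) return(ds)
  keys <- vapply(ds, function(e) e$group * 65536 + e$element, numeric(1))
  ds[order(keys)]
}

#' Set or replace an element in a dataset by keyword
#' @keywords internal
dicom_set <- function(ds, keyword, value, vr = NULL) {
  ent <- dicom_lookup(keyword)
  if (is.null(ent)) stop("unknown DICOM keyword: ", keyword)
  if (is.null(vr)) vr <- ent$vr
  ds[[tag_string(ent$group, ent$element)]] <-
    dicom_element(ent$group, ent$element, vr, value)
  dicom_sort(ds)
}

#' Get an element value from a dataset by keyword
#'
#' @param ds a dataset as returned by [read_dicom()] or [dicom_dataset()].
#' @param keyword dictionary keyword.
#' @return the element value, or `NULL` if absent.
#' @export
dicom_get <- function(ds, keyword) {
  ent <- dicom_lookup(keyword)
  if (is.null(ent)) stop("unknown DICOM keyword: ", keyword)
  el <- ds[[tag_string(ent$group, ent$element)]]
  if (is.null(el)) NULL else el$value
}

# ---- encoding ----

encode_value <- function(vr, value) {
  if (vr %in% .vr_string) {
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2 == 1) {
      pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
      b <- c(b, pad)
    }
    return(b)
  }
  switch(vr,
    US = do.call(c, lapply(as.numeric(value), u16_raw)),
    SS = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = do.call(c, lapply(as.numeric(value), u32_raw)),
    SL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    FL = writeBin(as.numeric(value), raw(), size = 4, endian = "little"),
    FD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
    AT = do.call(c, lapply(value, function(v) c(u16_raw(v[1]), u16_raw(v[2])))),
    OB = , OW = , OF = , UN = {
      b <- as.raw(value)
      if (length(b) %% 2 == 1) b <- c(b, as.raw(0))
      b
    },
    stop("cannot encode VR ", vr)
  )
}

encode_element <- function(el) {
  head <- c(u16_raw(el$group), u16_raw(el$element))
  if (el$vr == "SQ") {
    body <- encode_sequence(el$value)
    return(c(head, charToRaw("SQ"), as.raw(c(0, 0)),
             as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)), body))
  }
  body <- encode_value(el$vr, el$value)
  if (el$vr %in% .vr_long_form) {
    c(head, charToRaw(el$vr), as.raw(c(0, 0)), u32_raw(length(body)), body)
  } else {
    if (length(body) > 65534) stop("value too long for short-form VR ", el$vr)
    c(head, charToRaw(el$vr), u16_raw(length(body)), body)
  }
}

encode_sequence <- function(items) {
  out <- list()
  for (item in items) {
    content <- encode_dataset(item)
    out[[length(out) + 1]] <- c(u16_raw(0xFFFE), u16_raw(0xE000),
                                as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)), content,
                                u16_raw(0xFFFE), u16_raw(0xE00D),
                                u32_raw(0))
  }
  out[[length(out) + 1]] <- c(u16_raw(0xFFFE), u16_raw(0xE0DD), u32_raw(0))
  do.call(c, out)
}

encode_dataset <- function(ds) {
  if (length(ds) == 0) return(raw(0))
  do.call(c, lapply(dicom_sort(ds), encode_element))
}

#' Write a DICOM Part 10 file
#'
#' Encodes the dataset as Explicit VR Little Endian and regenerates the
#' file-meta group (0002) from the dataset's SOP Class/Instance UIDs.
#'
#' @param ds dataset (no group-0002 elements required; any present are
#'   ignored in favour of regenerated file meta).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(ds, path) {
  ds <- ds[vapply(ds, function(e) e$group != 2L, logical(1))]
  sop_class <- dicom_get(ds, "SOPClassUID")
  sop_inst <- dicom_get(ds, "SOPInstanceUID")
  if (is.null(sop_class) || is.null(sop_inst)) {
    stop("dataset must carry SOPClassUID and SOPInstanceUID")
  }
  meta <- list(
    dicom_element(2L, 1L, "OB", as.raw(c(0, 1))),
    dicom_element(2L, 2L, "UI", sop_class),
    dicom_element(2L, 3L, "UI", sop_inst),
    dicom_element(2L, 16L, "UI", .uid_explicit_vr_le),
    dicom_element(2L, 18L, "UI", .uid_implementation_class)
  )
  meta_body <- do.call(c, lapply(meta, encode_element))
  group_len <- encode_element(dicom_element(2L, 0L, "UL", length(meta_body)))
  payload <- c(raw(128), charToRaw("DICM"), group_len, meta_body,
               encode_dataset(ds))
  writeBin(payload, path)
  invisible(path)
}

# ---- decoding ----

decode_value <- function(vr, bytes) {
  if (vr %in% .vr_string) {
    while (length(bytes) > 0 && bytes[length(bytes)] == as.raw(0)) {
      bytes <- bytes[-length(bytes)]
    }
    s <- rawToChar(bytes)
    s <- sub(" +$", "", s)
    if (vr %in% .vr_no_split) return(s)
    return(strsplit(s, "\\", fixed = TRUE)[[1]])
  }
  switch(vr,
    US = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    SS = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = TRUE, endian = "little"),
    UL = vapply(seq_len(length(bytes) / 4),
                function(i) raw_u32(bytes[(4 * i - 3):(4 * i)]), numeric(1)),
    SL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FL = readBin(bytes, "numeric", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FD = readBin(bytes, "numeric", n = length(bytes) / 8, size = 8,
                 endian = "little"),
    AT = lapply(seq_len(length(bytes) / 4), function(i) {
      c(raw_u16(bytes[(4 * i - 3):(4 * i - 2)]),
        raw_u16(bytes[(4 * i - 1):(4 * i)]))
    }),
    bytes  # OB/OW/OF/UN: raw passthrough
  )
}

# Parse elements from buf[pos..end] (1-based, end inclusive). Stops at end
# or when stop_tag (c(group, element)) is encountered (delimiters).
parse_elements <- function(buf, pos, end, stop_group_element = NULL) {
  ds <- list()
  while (pos <= end) {
    if (pos + 7 > length(buf) + 1) stop("truncated DICOM element header")
    group <- raw_u16(buf[pos:(pos + 1)])
    element <- raw_u16(buf[(pos + 2):(pos + 3)])
    if (!is.null(stop_group_element) &&
        group == stop_group_element[1] && element == stop_group_element[2]) {
      len <- raw_u32(buf[(pos + 4):(pos + 7)])
      return(list(ds = ds, pos = pos + 8 + len))
    }
    if (group == 0xFFFE) stop("unexpected item delimiter in dataset")
    vr <- rawToChar(buf[(pos + 4):(pos + 5)])
    if (!vr %in% .vr_known) {
      stop(sprintf("unsupported or implicit VR %s at tag (%04X,%04X)",
                   vr, group, element))
    }
    if (vr %in% .vr_long_form) {
      len <- raw_u32(buf[(pos + 8):(pos + 11)])
      pos <- pos + 12
    } else {
      len <- raw_u16(buf[(pos + 6):(pos + 7)])
      pos <- pos + 8
    }
    undefined <- (len >= 4294967295)
    if (vr == "SQ") {
      sq <- parse_sequence(buf, pos, if (undefined) NA else pos + len - 1)
      value <- sq$items
      pos <- sq$pos
    } else {
      if (undefined) stop("undefined length outside SQ unsupported")
      if (pos + len - 1 > length(buf)) stop("element value exceeds file size")
      value <- decode_value(vr, if (len > 0) buf[pos:(pos + len - 1)] else raw(0))
      pos <- pos + len
    }
    el <- dicom_element(group, element, vr, value)
    ds[[tag_string(group, element)]] <- el
  }
  list(ds = ds, pos = pos)
}

parse_sequence <- function(buf, pos, end) {
  items <- list()
  repeat {
    if (!is.na(end) && pos > end) break
    if (pos + 7 > length(buf) + 1) {
      if (is.na(end)) stop("unterminated sequence")
      break
    }
    group <- raw_u16(buf[pos:(pos + 1)])
    element <- raw_u16(buf[(pos + 2):(pos + 3)])
    len <- raw_u32(buf[(pos + 4):(pos + 7)])
    pos <- pos + 8
    if (group == 0xFFFE && element == 0xE0DD) break  # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000)) {
      stop("malformed sequence: expected item tag")
    }
    if (len >= 4294967295) {
      res <- parse_elements(buf, pos, length(buf),
                            stop_group_element = c(0xFFFE, 0xE00D))
    } else {
      res <- parse_elements(buf, pos, pos + len - 1)
    }
    items[[length(items) + 1]] <- res$ds
    pos <- res$pos
  }
  list(items = items, pos = pos)
}

#' Read a DICOM Part 10 file
#'
#' @param path path to a Part 10 file (128-byte preamble + "DICM").
#' @return list with `meta` (group-0002 dataset) and `attrs` (main dataset).
#' @export
read_dicom <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n < 140) stop("not a DICOM Part 10 file (too small): ", path)
  buf <- readBin(path, "raw", n = n)
  if (rawToChar(buf[129:132]) != "DICM") {
    stop("not a DICOM Part 10 file (missing DICM magic): ", path)
  }
  pos <- 133
  meta <- list()
  # file meta group is always Explicit VR LE; read until group != 0002
  while (pos + 7 <= n + 1 && raw_u16(buf[pos:(pos + 1)]) == 2L) {
    res <- parse_single_element(buf, pos)
    meta[[tag_string(res$el$group, res$el$element)]] <- res$el
    pos <- res$pos
  }
  ts <- meta[[tag_string(2L, 16L)]]
  if (!is.null(ts) && !identical(ts$value, .uid_explicit_vr_le)) {
    stop("unsupported transfer syntax: ", ts$value)
  }
  attrs <- parse_elements(buf, pos, n)$ds
  list(meta = meta, attrs = attrs)
}

parse_single_element <- function(buf, pos) {
  res <- tryCatch(parse_one(buf, pos), error = function(e) stop(e))
  res
}

parse_one <- function(buf, pos) {
  group <- raw_u16(buf[pos:(pos + 1)])
  element <- raw_u16(buf[(pos + 2):(pos + 3)])
  vr <- rawToChar(buf[(pos + 4):(pos + 5)])
  if (!vr %in% .vr_known) stop("unsupported VR in file meta: ", vr)
  if (vr %in% .vr_long_form) {
    len <- raw_u32(buf[(pos + 8):(pos + 11)])
    pos <- pos + 12
  } else {
    len <- raw_u16(buf[(pos + 6):(pos + 7)])
    pos <- pos + 8
  }
  value <- decode_value(vr, if (len > 0) buf[pos:(pos + len - 1)] else raw(0))
  list(el = dicom_element(group, element, vr, value), pos = pos + len)
}

#' Quick check whether a file looks like DICOM Part 10
#' @keywords internal
is_dicom_file <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n < 132) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 132)
  length(head) == 132 && identical(rawToChar(head[129:132]), "DICM")
}

# ---- pixel codec (native, little endian, interleaved samples) ----

#' Decode the pixel array of a dataset
#'
#' @param ds dataset with image-pixel attributes and PixelData.
#' @return integer array: `(rows, cols)` for single-frame monochrome,
#'   `(rows, cols, samples)` for colour, `(rows, cols, samples, frames)`
#'   for multi-frame.
#' @export
dicom_pixel_array <- function(ds) {
  px <- dicom_get(ds, "PixelData")
  if (is.null(px)) stop("dataset has no PixelData")
  rows <- as.integer(dicom_get(ds, "Rows"))
  cols <- as.integer(dicom_get(ds, "Columns"))
  samples <- dicom_get(ds, "SamplesPerPixel")
  samples <- if (is.null(samples)) 1L else as.integer(samples)
  frames <- dicom_get(ds, "NumberOfFrames")
  frames <- if (is.null(frames)) 1L else as.integer(frames)
  bits <- as.integer(dicom_get(ds, "BitsAllocated"))
  npix <- rows * cols * samples * frames
  if (bits == 8) {
    v <- as.integer(px[seq_len(npix)])
  } else if (bits == 16) {
    v <- readBin(px, "integer", n = npix, size = 2, signed = FALSE,
                 endian = "little")
  } else stop("unsupported BitsAllocated: ", bits)
  # DICOM is row-major with sample interleave; R arrays are column-major
  arr <- array(v, dim = c(samples, cols, rows, frames))
  arr <- aperm(arr, c(3, 2, 1, 4))
  dim_out <- c(rows, cols,
               if (samples > 1 || frames > 1) samples else NULL,
               if (frames > 1) frames else NULL)
  array(arr, dim = dim_out)
}

#' Encode a pixel array into PixelData bytes
#'
#' Inverse of [dicom_pixel_array()] for the same native layout.
#' @keywords internal
dicom_encode_pixels <- function(arr, bits) {
  d <- dim(arr)
  if (length(d) == 2) d <- c(d, 1L, 1L)
  if (length(d) == 3) d <- c(d, 1L)
  arr <- array(arr, dim = d)
  v <- as.integer(aperm(arr, c(3, 2, 1, 4)))
  if (bits == 8) {
    b <- as.raw(v)
  } else if (bits == 16) {
    b <- do.call(c, list(writeBin(v %% 65536L - ifelse(v %% 65536L > 32767L,
                                                       65536L, 0L),
                                  raw(), size = 2, endian = "little")))
  } else stop("unsupported BitsAllocated: ", bits)
  if (length(b) %% 2 == 1) b <- c(b, as.raw(0))
  b
}
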