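# Siemens twix raw-data (.dat) header de-identification.
#
# A twix file embeds one or more ASCII protocol headers alongside binary
# k-space payload. The k-space is not viewable anatomy, so only the headers
# are scrubbed -- but every header must be scrubbed, including the large
# protocol text block: a tool that only cleans the compact metadata block
# leaves a full copy of the patient record behind, ready to be pasted back
# on the next save. Because the container stores absolute byte offsets,
# every replacement is length-preserving: numeric values become runs of
# '0', quoted text becomes runs of 'x', and the file size never changes.
#
# Layout handled (the dialect the fixture generator emits):
#   multi-measurement: uint32 0, uint32 n_meas (1..64), then per
#     measurement a 16-byte table entry (uint64 offset, uint64 length);
#     each measurement starts with uint32 n_blocks, then blocks of
#     [48-byte NUL-padded name][uint32 text_length][ASCII text], followed
#     by binary payload up to the measurement end.
#   single-measurement: uint32 header_length (> 0), then the same block
#     structure, payload to EOF.

u64_raw <- function(x) c(u32_raw(x %% 4294967296), u32_raw(x %/% 4294967296))

raw_u64 <- function(b) raw_u32(b[1:4]) + 4294967296 * raw_u32(b[5:8])

.twix_block_name_len <- 48L

#' Default twix scrub rules
#'
#' Key patterns matched exact-or-prefix (case-sensitive) against parameter
#' names in the protocol text. Shipped as data; extend by concatenating your
#' own [twix_rule()]s.
#'
#' @return list of `twix_rule` objects.
#' @export
default_twix_rules <- function() {
  keys <- c("PatientName", "tPatientName", "PatientID", "PatientBirthDay",
            "PatientBirthday", "PatientSex", "PatientAge", "PatientWeight",
            "PatientHeight", "PatientSize", "PatientPosition",
            "PatientAddress", "PatientComment", "ReferringPhysician",
            "tReferringPhysician", "PerfPhysician", "OperatorName",
            "InstitutionName", "tInstitutionName", "InstitutionAddress",
            "tInstitutionAddress", "DeviceSerialNumber")
  lapply(keys, twix_rule)
}

#' Create a twix scrub rule
#'
#' @param key_pattern parameter-name pattern; matches a name token if the
#'   token equals the pattern or starts with it (case-sensitive).
#' @return a `twix_rule` object.
#' @export
twix_rule <- function(key_pattern) {
  stopifnot(is.character(key_pattern), length(key_pattern) == 1,
            nzchar(key_pattern))
  structure(list(key_pattern = key_pattern), class = "twix_rule")
}

#' Locate the ASCII header spans inside a twix file
#'
#' @param raw_bytes the file content as a raw vector.
#' @return a `twix_file` list: `dialect` (`"multi"` or `"single"`) and
#'   `measurements`, each with `offset`, `length`, `header_spans` (name,
#'   byte_start, byte_length; 0-based offsets of the text payloads) and
#'   `payload_span` (`c(start, length)`, 0-based).
#' @export
locate_twix_headers <- function(raw_bytes) {
  n <- length(raw_bytes)
  if (n < 8) stop("not a twix file: expected multi-measurement table or ",
                  "single-measurement header-length prefix")
  first <- raw_u32(raw_bytes[1:4])
  if (first == 0) {
    n_meas <- raw_u32(raw_bytes[5:8])
    if (n_meas < 1 || n_meas > 64) {
      stop("not a twix file: measurement count ", n_meas,
           " outside 1..64 (expected dialects: multi-measurement, ",
           "single-measurement)")
    }
    meas <- vector("list", n_meas)
    pos <- 8L
    for (i in seq_len(n_meas)) {
      if (pos + 16 > n) stop("truncated twix measurement table")
      off <- raw_u64(raw_bytes[(pos + 1):(pos + 8)])
      len <- raw_u64(raw_bytes[(pos + 9):(pos + 16)])
      if (off + len > n) stop("twix measurement extends past end of file")
      meas[[i]] <- parse_twix_measurement(raw_bytes, off, len)
      pos <- pos + 16L
    }
    return(structure(list(dialect = "multi", measurements = meas),
                     class = "twix_file"))
  }
  # single-measurement: first uint32 is the total header length
  if (first <= 4 || first > n) {
    stop("not a twix file: header length prefix ", first,
         " implausible (expected dialects: multi-measurement, ",
         "single-measurement)")
  }
  m <- tryCatch(parse_twix_measurement(raw_bytes, 4, n - 4,
                                       expected_header_len = first - 4),
                error = function(e) {
    stop("not a twix file: ", conditionMessage(e),
         " (expected dialects: multi-measurement, single-measurement)")
  })
  structure(list(dialect = "single", measurements = list(m)),
            class = "twix_file")
}

parse_twix_measurement <- function(raw_bytes, off, len,
                                   expected_header_len = NULL) {
  end <- off + len
  pos <- off
  if (pos + 4 > end) stop("truncated measurement header")
  n_blocks <- raw_u32(raw_bytes[(pos + 1):(pos + 4)])
  if (n_blocks < 1 || n_blocks > 32) {
    stop("implausible header block count ", n_blocks)
  }
  pos <- pos + 4
  spans <- vector("list", n_blocks)
  for (i in seq_len(n_blocks)) {
    if (pos + .twix_block_name_len + 4 > end) stop("truncated header block")
    name_raw <- raw_bytes[(pos + 1):(pos + .twix_block_name_len)]
    name_raw <- name_raw[cumsum(name_raw == as.raw(0)) == 0]
    name <- rawToChar(name_raw)
    if (!grepl("^[ -~]*$", name)) stop("non-ASCII header block name")
    pos <- pos + .twix_block_name_len
    text_len <- raw_u32(raw_bytes[(pos + 1):(pos + 4)])
    pos <- pos + 4
    if (pos + text_len > end) stop("header text exceeds measurement")
    spans[[i]] <- list(name = name, byte_start = pos, byte_length = text_len)
    pos <- pos + text_len
  }
  if (!is.null(expected_header_len) &&
      (pos - off) != expected_header_len) {
    stop("header length prefix does not match block structure")
  }
  list(offset = off, length = len, header_spans = spans,
       payload_span = c(pos, end - pos))
}

#' Scrub patient keys from twix protocol text
#'
#' Finds `name = value` assignments whose name token matches a rule
#' (exact-or-prefix on the full dotted token or its final component) and
#' replaces the value in place: quoted values are filled with `x`, unquoted
#' numeric values with `0`, each preserving character length exactly.
#'
#' @param text decoded protocol ASCII.
#' @param rules list of [twix_rule()]s; defaults to [default_twix_rules()].
#' @return list with `text` (same length as input) and `records`
#'   (data.frame: key, kind).
#' @export
scrub_twix_text <- function(text, rules = default_twix_rules()) {
  patterns <- vapply(rules, `[[`, "", "key_pattern")
  rx <- "([A-Za-z_][A-Za-z0-9_]*(?:[.\\[][A-Za-z0-9_\\]]*)*)([ \t]*=[ \t]*)(\"[^\"\n]*\"|[-+0-9][0-9.eE+-]*)"
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  records <- list()
  if (m[1] != -1) {
    starts <- as.integer(m)
    cap_start <- attr(m, "capture.start")
    cap_len <- attr(m, "capture.length")
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    for (i in seq_along(starts)) {
      key <- substr(text, cap_start[i, 1], cap_start[i, 1] + cap_len[i, 1] - 1)
      leaf <- sub(".*[.\\[]", "", gsub("\\]", "", key))
      hit <- any(vapply(patterns, function(p) {
        key == p || startsWith(key, p) || leaf == p || startsWith(leaf, p)
      }, logical(1)))
      if (!hit) next
      vs <- cap_start[i, 3]
      vl <- cap_len[i, 3]
      val <- substr(text, vs, vs + vl - 1)
      if (startsWith(val, "\"")) {
        if (vl > 2) chars[(vs + 1):(vs + vl - 2)] <- "x"
        kind <- "text"
      } else {
        chars[vs:(vs + vl - 1)] <- "0"
        kind <- "numeric"
      }
      records[[length(records) + 1]] <- list(key = key, kind = kind)
    }
    text <- paste(chars, collapse = "")
  }
  recdf <- if (length(records)) {
    do.call(rbind, lapply(records, as.data.frame, stringsAsFactors = FALSE))
  } else {
    data.frame(key = character(0), kind = character(0))
  }
  list(text = text, records = recdf)
}

#' De-identify a twix raw-data file
#'
#' Scrubs every ASCII header span of every measurement; all bytes outside
#' the header spans (k-space payload, tables, block names) are copied
#' verbatim, and the output file has exactly the input's size.
#'
#' @param in_path input `.dat` file.
#' @param out_path output path.
#' @param rules list of [twix_rule()]s.
#' @return a [report_entry()].
#' @export
deid_twix_file <- function(in_path, out_path, rules = default_twix_rules()) {
  res <- tryCatch({
    b <- readBin(in_path, "raw", n = file.info(in_path)$size)
    tw <- locate_twix_headers(b)
    all_records <- list()
    for (m in tw$measurements) {
      for (sp in m$header_spans) {
        if (sp$byte_length == 0) next
        span <- (sp$byte_start + 1):(sp$byte_start + sp$byte_length)
        txt <- rawToChar(b[span])
        sc <- scrub_twix_text(txt, rules)
        out_raw <- charToRaw(sc$text)
        stopifnot(length(out_raw) == sp$byte_length)
        b[span] <- out_raw
        if (nrow(sc$records) > 0) {
          sc$records$block <- sp$name
          all_records[[length(all_records) + 1]] <- sc$records
        }
      }
    }
    recdf <- if (length(all_records)) do.call(rbind, all_records) else
      data.frame(key = character(0), kind = character(0), block = character(0))
    recdf$action <- rep("FILL", nrow(recdf))
    dir.create(dirname(out_path), recursive = TRUE, showWarnings = FALSE)
    writeBin(b, out_path)
    report_entry(in_path, "twix", status = "ok", records = recdf)
  }, error = function(e) {
    if (file.exists(out_path)) unlink(out_path)
    report_entry(in_path, "twix", status = "failed",
                 error = conditionMessage(e))
  })
  res
}

#' Quick check whether a file looks like the supported twix layout
#' @keywords internal
is_twix_file <- function(path) {
  ok <- tryCatch({
    b <- readBin(path, "raw", n = file.info(path)$size)
    locate_twix_headers(b)
    TRUE
  }, error = function(e) FALSE)
  ok
}
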