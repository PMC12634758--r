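# Per-file de-identification reports.
#
# A report is a list of entries, one per processed file. Entries carry
# tags, actions and geometry only -- never removed values -- so a report
# can be archived without itself becoming PHI.

#' Create a report entry for one processed file
#'
#' @param path input file path.
#' @param format detected format label.
#' @param status `"ok"`, `"failed"` or `"skipped"`.
#' @param records data.frame of metadata modifications (may be `NULL`).
#' @param pixel_summary optional list summarising pixel-level cleaning.
#' @param error optional error message for failed/skipped files.
#' @return a `deid_report_entry` list.
#' @export
report_entry <- function(path, format, status = "ok", records = NULL,
                         pixel_summary = NULL, error = NULL) {
  structure(list(path = path, format = format, status = status,
                 n_modifications = if (is.null(records)) 0L else nrow(records),
                 records = records, pixel_summary = pixel_summary,
                 error = error),
            class = "deid_report_entry")
}

#' Write a de-identification report as JSON lines
#'
#' One JSON object per line, one line per file: stream-safe for large
#' batches.
#'
#' @param entries list of [report_entry()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(entries, path) {
  lines <- vapply(entries, function(e) {
    e <- unclass(e)
    e$records <- if (is.null(e$records)) NULL else e$records
    jsonlite::toJSON(e, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Summarise a report
#' @param entries list of [report_entry()] objects.
#' @return named counts of ok/failed/skipped entries.
#' @export
report_summary <- function(entries) {
  status <- vapply(entries, `[[`, "", "status")
  c(ok = sum(status == "ok"), failed = sum(status == "failed"),
    skipped = sum(status == "skipped"))
}
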