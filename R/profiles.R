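# Metadata de-identification rule engine.
#
# A profile is an ordered list of tag rules; the first rule whose selector
# matches an attribute wins, and a default action covers everything else.
# The engine is format-agnostic: it operates on ordered attribute sets (the
# same element lists the DICOM reader produces), so the DICOM and WSI
# pipelines share it.

.action_kinds <- c("REMOVE", "ZERO", "REPLACE_FIXED", "REMAP_UID",
                   "CLEAN_DATE", "KEEP")

# Date values are anchored, not shifted: de-identification has no key to
# recover a shift, so a fixed anchor is both simpler and honest.
.clean_date_anchor <- "19000101"

#' Create a tag rule
#'
#' @param selector exact tag (`"0010,0010"` or `"00100010"`), dictionary
#'   keyword, glob pattern on either (`"Patient*"`), `"private:*"` for all
#'   odd-group (private) tags, or `"kind:<k>"` to select by value kind
#'   (`uid`, `date`, `time`, `text`, `number`, `binary`, `sequence`).
#' @param action one of `REMOVE`, `ZERO`, `REPLACE_FIXED`, `REMAP_UID`,
#'   `CLEAN_DATE`, `KEEP`.
#' @param replacement fixed replacement value; required for `REPLACE_FIXED`.
#' @return a `tag_rule` object.
#' @export
tag_rule <- function(selector, action, replacement = NULL) {
  if (!is.character(selector) || length(selector) != 1 || !nzchar(selector)) {
    stop("selector must be a non-empty string")
  }
  if (!action %in% .action_kinds) {
    stop("unknown action '", action, "'; must be one of ",
         paste(.action_kinds, collapse = ", "))
  }
  if (action == "REPLACE_FIXED" && is.null(replacement)) {
    stop("REPLACE_FIXED requires a replacement value")
  }
  structure(list(selector = selector, action = action,
                 replacement = replacement),
            class = "tag_rule")
}

#' Create a de-identification profile
#'
#' @param name profile name (stamped into de-identified outputs).
#' @param rules ordered list of [tag_rule()]s; first match wins.
#' @param default_action action applied when no rule matches.
#' @param options character vector of extension option names already folded
#'   into the rules (informational).
#' @return a `deid_profile` object.
#' @export
deid_profile <- function(name, rules = list(), default_action = "KEEP",
                         options = character(0)) {
  if (!default_action %in% .action_kinds) {
    stop("unknown default_action '", default_action, "'")
  }
  for (r in rules) {
    if (!inherits(r, "tag_rule")) stop("rules must be tag_rule objects")
  }
  structure(list(name = name, rules = rules,
                 default_action = default_action, options = options),
            class = "deid_profile")
}

#' @export
print.deid_profile <- function(x, ...) {
  cat(sprintf("<deid_profile '%s': %d rules, default %s%s>\n", x$name,
              length(x$rules), x$default_action,
              if (length(x$options)) paste0(", options: ",
                                            paste(x$options, collapse = ", "))
              else ""))
  invisible(x)
}

# ---- built-in profiles ----

# Curated identifying-attribute list for the built-in basic profile. This is
# a pragmatic subset of the standard's confidentiality table, shipped as
# data and extensible through profile documents.
.basic_remove_keywords <- c(
  "PatientName", "PatientID", "OtherPatientIDs", "OtherPatientNames",
  "PatientBirthDate", "PatientSex", "PatientAge", "PatientSize",
  "PatientWeight", "PatientAddress", "MilitaryRank", "EthnicGroup",
  "Occupation", "AdditionalPatientHistory", "PatientComments",
  "ReferringPhysicianName", "PerformingPhysicianName", "OperatorsName",
  "InstitutionName", "InstitutionAddress", "InstitutionalDepartmentName",
  "StationName", "DeviceSerialNumber", "AccessionNumber", "StudyID",
  "StudyDescription", "ImageComments"
)

.basic_rules <- function() {
  rules <- list(
    # structural UIDs that must survive unmapped for the file to stay valid
    tag_rule("SOPClassUID", "KEEP"),
    tag_rule("ReferencedSOPClassUID", "KEEP"),
    tag_rule("TransferSyntaxUID", "KEEP")
  )
  for (kw in .basic_remove_keywords) {
    rules[[length(rules) + 1]] <- tag_rule(kw, "REMOVE")
  }
  c(rules, list(
    tag_rule("kind:uid", "REMAP_UID"),
    tag_rule("kind:date", "CLEAN_DATE"),
    tag_rule("kind:time", "ZERO"),
    tag_rule("private:*", "REMOVE")
  ))
}

# Extension overlays: rules prepended to the basic rules so they take
# precedence under first-match-wins.
.profile_extensions <- list(
  "retain-device-identity" = function() list(
    tag_rule("DeviceSerialNumber", "KEEP"),
    tag_rule("StationName", "KEEP"),
    tag_rule("Manufacturer", "KEEP"),
    tag_rule("ManufacturerModelName", "KEEP"),
    tag_rule("SoftwareVersions", "KEEP")
  ),
  "retain-patient-characteristics" = function() list(
    tag_rule("PatientSex", "KEEP"),
    tag_rule("PatientAge", "KEEP"),
    tag_rule("PatientSize", "KEEP"),
    tag_rule("PatientWeight", "KEEP"),
    tag_rule("EthnicGroup", "KEEP")
  ),
  "retain-longitudinal-dates" = function() list(
    tag_rule("kind:date", "KEEP"),
    tag_rule("kind:time", "KEEP")
  )
)

#' Names of built-in profiles and extension options
#' @return character vector of names accepted by [load_profile()].
#' @export
builtin_profiles <- function() {
  c("basic", paste0("basic+", names(.profile_extensions)))
}

#' Load a de-identification profile
#'
#' Accepts a built-in name (`"basic"`, optionally with `+option` suffixes,
#' e.g. `"basic+retain-patient-characteristics"`), a path to a YAML/JSON
#' profile document, or an already-parsed document list with fields `name`,
#' `default_action`, `rules` (each `{selector, action, replacement}`) and
#' optional `options`.
#'
#' @param source built-in name, file path, or document list.
#' @param options extra extension option names to fold in.
#' @return a [deid_profile()].
#' @export
load_profile <- function(source, options = character(0)) {
  if (inherits(source, "deid_profile")) {
    return(apply_options(source, options))
  }
  if (is.character(source) && length(source) == 1) {
    parts <- strsplit(source, "+", fixed = TRUE)[[1]]
    if (parts[1] == "basic") {
      prof <- deid_profile("basic", .basic_rules(), default_action = "KEEP")
      return(apply_options(prof, c(parts[-1], options)))
    }
    if (file.exists(source)) {
      doc <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
        jsonlite::read_json(source)
      } else {
        yaml::read_yaml(source)
      }
      return(apply_options(profile_from_document(doc), options))
    }
    stop("unknown profile '", source,
         "': not a built-in name and not an existing file")
  }
  if (is.list(source)) return(apply_options(profile_from_document(source), options))
  stop("cannot load profile from object of class ", class(source)[1])
}

apply_options <- function(prof, options) {
  for (opt in options) {
    ext <- .profile_extensions[[opt]]
    if (is.null(ext)) {
      stop("unknown profile option '", opt, "'; available: ",
           paste(names(.profile_extensions), collapse = ", "))
    }
    prof$rules <- c(ext(), prof$rules)
    prof$options <- union(prof$options, opt)
    prof$name <- paste0(prof$name, "+", opt)
  }
  prof
}

profile_from_document <- function(doc) {
  name <- if (!is.null(doc$name)) doc$name else "custom"
  default_action <- if (!is.null(doc$default_action)) doc$default_action else "KEEP"
  if (!default_action %in% .action_kinds) {
    stop("profile '", name, "': unknown default_action '", default_action, "'")
  }
  rules <- list()
  for (i in seq_along(doc$rules)) {
    r <- doc$rules[[i]]
    ok <- tryCatch(tag_rule(r$selector, r$action, r$replacement),
                   error = function(e) e)
    if (inherits(ok, "error")) {
      stop("profile '", name, "', rule ", i, ": ", conditionMessage(ok))
    }
    rules[[i]] <- ok
  }
  opts <- unlist(doc$options)
  prof <- deid_profile(name, rules, default_action)
  apply_options(prof, if (is.null(opts)) character(0) else opts)
}

# ---- attribute kinds and selector matching ----

#' Value kind of a DICOM VR
#' @keywords internal
kind_of_vr <- function(vr) {
  if (vr == "UI") return("uid")
  if (vr == "DA") return("date")
  if (vr %in% c("TM", "DT")) return("time")
  if (vr == "SQ") return("sequence")
  if (vr %in% c("OB", "OW", "OF", "UN")) return("binary")
  if (vr %in% c("US", "UL", "SS", "SL", "FL", "FD", "DS", "IS")) return("number")
  "text"
}

parse_tag_selector <- function(s) {
  s2 <- gsub("[(),]", "", s)
  if (grepl("^[0-9A-Fa-f]{8}$", s2)) {
    return(c(strtoi(substr(s2, 1, 4), 16L), strtoi(substr(s2, 5, 8), 16L)))
  }
  NULL
}

selector_matches <- function(selector, el) {
  kw <- dicom_keyword(el$group, el$element)
  if (selector == "private:*") return(el$group %% 2 == 1)
  if (startsWith(selector, "kind:")) {
    return(identical(sub("^kind:", "", selector), kind_of_vr(el$vr)))
  }
  tg <- parse_tag_selector(selector)
  if (!is.null(tg)) return(el$group == tg[1] && el$element == tg[2])
  if (grepl("[*?]", selector)) {
    rx <- utils::glob2rx(selector)
    return((!is.na(kw) && grepl(rx, kw)) ||
             grepl(rx, tag_string(el$group, el$element)) ||
             grepl(rx, sprintf("%04X,%04X", el$group, el$element)))
  }
  !is.na(kw) && selector == kw
}

#' Resolve the rule governing an attribute
#'
#' Walks the profile's rules in order and returns the first whose selector
#' matches; if none matches, returns a synthetic rule carrying the profile's
#' default action.
#'
#' @param profile a [deid_profile()].
#' @param tag a keyword string, a `"GGGG,EEEE"` tag string, or an element
#'   list (as inside a dataset).
#' @return the matching [tag_rule()].
#' @export
resolve_action <- function(profile, tag) {
  el <- as_element_stub(tag)
  for (r in profile$rules) {
    if (selector_matches(r$selector, el)) return(r)
  }
  tag_rule("*", profile$default_action,
           if (profile$default_action == "REPLACE_FIXED") "" else NULL)
}

as_element_stub <- function(tag) {
  if (is.list(tag) && !is.null(tag$group)) return(tag)
  if (is.character(tag) && length(tag) == 1) {
    tg <- parse_tag_selector(tag)
    if (!is.null(tg)) {
      kw <- dicom_keyword(tg[1], tg[2])
      ent <- if (!is.na(kw)) dicom_lookup(kw) else NULL
      vr <- if (!is.null(ent)) ent$vr else "UN"
      return(dicom_element(tg[1], tg[2], vr, NULL))
    }
    ent <- dicom_lookup(tag)
    if (!is.null(ent)) return(dicom_element(ent$group, ent$element, ent$vr, NULL))
    stop("tag '", tag, "' is neither a known keyword nor a GGGG,EEEE tag")
  }
  stop("tag must be a keyword string, tag string, or element")
}

# ---- UID remapping ----

#' Create a session-scoped UID map
#'
#' Generated UIDs are `<root_prefix><counter>`: valid dotted-numeric strings,
#' unique within the map, and stable for repeated queries of the same
#' original UID. UIDs already issued by this map (recognisable by the root
#' prefix) are returned unchanged, which makes profile application
#' idempotent.
#'
#' @param root_prefix dotted-numeric UID root ending in `.`.
#' @return a `uid_map` object (mutable; environment-backed).
#' @export
uid_map <- function(root_prefix = "1.2.826.0.1.3680043.10.1405.2.") {
  if (!grepl("^[0-9]+(\\.[0-9]+)*\\.$", root_prefix)) {
    stop("root_prefix must be dotted-numeric ending in '.'")
  }
  env <- new.env(parent = emptyenv())
  env$root_prefix <- root_prefix
  env$entries <- new.env(parent = emptyenv())
  env$counter <- 0L
  class(env) <- "uid_map"
  env
}

#' Remap a UID consistently within a session
#'
#' @param map a [uid_map()].
#' @param uid original dotted-numeric UID.
#' @return the replacement UID (stable for repeated calls with the same
#'   input; never equal to a fresh input; at most 64 characters).
#' @export
remap_uid <- function(map, uid) {
  if (!inherits(map, "uid_map")) stop("map must be a uid_map")
  if (!is.character(uid) || length(uid) != 1 ||
      !grepl("^[0-9]+(\\.[0-9]+)*$", uid)) {
    stop("uid must be a dotted-numeric string, got: ",
         deparse(substitute(uid)))
  }
  if (startsWith(uid, map$root_prefix)) return(uid)  # already remapped
  key <- paste0("u", uid)
  hit <- get0(key, envir = map$entries)
  if (!is.null(hit)) return(hit)
  map$counter <- map$counter + 1L
  new <- paste0(map$root_prefix, map$counter)
  stopifnot(nchar(new) <= 64)
  assign(key, new, envir = map$entries)
  new
}

#' Entries of a UID map as a data frame
#' @param map a [uid_map()].
#' @return data.frame with columns `original`, `replacement`.
#' @export
uid_map_entries <- function(map) {
  keys <- ls(map$entries)
  data.frame(original = substring(keys, 2),
             replacement = vapply(keys, get, "", envir = map$entries),
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- applying a profile to an attribute set ----

zero_value <- function(el) {
  kind <- kind_of_vr(el$vr)
  el$value <- switch(kind,
    number = if (el$vr %in% c("DS", "IS")) "0" else 0L,
    binary = raw(0),
    sequence = list(),
    ""  # text, date, time, uid
  )
  el
}

#' Apply a de-identification profile to an attribute set
#'
#' Walks the attribute set (a dataset as produced by [read_dicom()] or
#' [dicom_dataset()]), resolves the governing rule for each element, applies
#' the action, and recurses into sequences. The modification report records
#' tag, keyword, action and value kind -- never the removed values, so the
#' report itself cannot leak what it scrubbed.
#'
#' @param attrs ordered attribute set.
#' @param profile a [deid_profile()].
#' @param map a [uid_map()] shared across all files of a session.
#' @return list with `attrs` (scrubbed set) and `records` (data.frame of
#'   modifications: tag, keyword, action, kind).
#' @export
apply_profile <- function(attrs, profile, map = uid_map()) {
  res <- apply_profile_ds(attrs, profile, map, depth = 0L)
  rec <- res$records
  records <- if (length(rec) == 0) {
    data.frame(tag = character(0), keyword = character(0),
               action = character(0), kind = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(rec, as.data.frame, stringsAsFactors = FALSE))
  }
  list(attrs = res$ds, records = records)
}

apply_profile_ds <- function(ds, profile, map, depth) {
  out <- list()
  records <- list()
  note <- function(el, action) {
    records[[length(records) + 1]] <<- list(
      tag = sprintf("%04X,%04X", el$group, el$element),
      keyword = {
        kw <- dicom_keyword(el$group, el$element)
        if (is.na(kw)) "" else kw
      },
      action = action,
      kind = kind_of_vr(el$vr))
  }
  for (nm in names(ds)) {
    el <- ds[[nm]]
    rule <- resolve_action(profile, el)
    action <- rule$action
    if (action == "KEEP" && el$vr == "SQ") {
      # recurse anyway: nested items may hold covered attributes
      sub <- lapply(el$value, apply_profile_ds, profile = profile,
                    map = map, depth = depth + 1L)
      el$value <- lapply(sub, `[[`, "ds")
      for (s in sub) records <- c(records, s$records)
      out[[nm]] <- el
      next
    }
    switch(action,
      KEEP = { out[[nm]] <- el },
      REMOVE = { note(el, "REMOVE") },
      ZERO = { note(el, "ZERO"); out[[nm]] <- zero_value(el) },
      REPLACE_FIXED = {
        note(el, "REPLACE_FIXED")
        el$value <- rule$replacement
        out[[nm]] <- el
      },
      CLEAN_DATE = {
        note(el, "CLEAN_DATE")
        el$value <- rep(.clean_date_anchor, max(1L, length(el$value)))
        out[[nm]] <- el
      },
      REMAP_UID = {
        old <- el$value
        el$value <- vapply(old, function(u) remap_uid(map, u), "")
        if (!identical(unname(el$value), unname(old))) note(el, "REMAP_UID")
        out[[nm]] <- el
      }
    )
  }
  list(ds = out, records = records)
}
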