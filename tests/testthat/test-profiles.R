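test_that("built-in profiles load and bad rule documents are rejected", {
  p <- load_profile("basic")
  expect_s3_class(p, "deid_profile")
  expect_identical(p$default_action, "KEEP")
  # identifying tags resolve to REMOVE, technical tags fall through to KEEP
  expect_identical(resolve_action(p, "PatientName")$action, "REMOVE")
  expect_identical(resolve_action(p, "Modality")$action, "KEEP")
  expect_identical(resolve_action(p, "Rows")$action, "KEEP")

  # identity profile: no rules, default KEEP, changes nothing
  ident <- load_profile(list(name = "identity", default_action = "KEEP",
                             rules = list()))
  ds <- dicom_dataset(PatientName = "Doe^Jane", Modality = "MR")
  out <- apply_profile(ds, ident, uid_map())
  expect_identical(out$attrs, ds)
  expect_identical(nrow(out$records), 0L)

  # unknown action name is rejected with the rule index
  expect_error(load_profile(list(name = "bad", rules = list(
    list(selector = "PatientName", action = "shred")))),
    "rule 1.*shred|shred.*rule 1")

  # REPLACE_FIXED without replacement is invalid
  expect_error(tag_rule("PatientName", "REPLACE_FIXED"), "replacement")

  # profile documents round-trip through YAML
  doc <- list(name = "site", default_action = "KEEP",
              rules = list(list(selector = "PatientName",
                                action = "REPLACE_FIXED",
                                replacement = "ANON")))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, path)
  p2 <- load_profile(path)
  expect_identical(resolve_action(p2, "PatientName")$replacement, "ANON")

  expect_error(load_profile("no-such-profile"), "unknown profile")
})

test_that("extension options overlay the basic profile with precedence", {
  p <- load_profile("basic+retain-patient-characteristics")
  expect_identical(resolve_action(p, "PatientSex")$action, "KEEP")
  expect_identical(resolve_action(p, "PatientName")$action, "REMOVE")
  pd <- load_profile("basic", options = "retain-longitudinal-dates")
  expect_identical(resolve_action(pd, "StudyDate")$action, "KEEP")
  expect_identical(resolve_action(load_profile("basic"), "StudyDate")$action,
                   "CLEAN_DATE")
  expect_error(load_profile("basic", options = "retain-everything"),
               "unknown profile option")
})

test_that("wildcard and private selectors match, first match wins", {
  p <- deid_profile("t", list(tag_rule("private:*", "REMOVE"),
                              tag_rule("Patient*", "ZERO"),
                              tag_rule("PatientName", "KEEP")),
                    default_action = "KEEP")
  # any odd-group tag resolves to the private rule
  set.seed(42)
  for (i in 1:20) {
    g <- sample(seq(9, 0x00FF, by = 2), 1)
    e <- sample(0:0xFFFF, 1)
    el <- imdeid:::dicom_element(g, e, "LO", "x")
    expect_identical(resolve_action(p, el)$action, "REMOVE")
  }
  # glob beats the later exact rule (first match wins)
  expect_identical(resolve_action(p, "PatientName")$action, "ZERO")
  # fall-through synthesizes the default action
  expect_identical(resolve_action(p, "StudyDate")$action, "KEEP")
  # tag-string selectors
  p2 <- deid_profile("t2", list(tag_rule("0010,0010", "REMOVE")), "KEEP")
  expect_identical(resolve_action(p2, "PatientName")$action, "REMOVE")
})

test_that("uid remapping is consistent, injective, and bounded", {
  m <- uid_map()
  a1 <- remap_uid(m, "1.2.3.4")
  a2 <- remap_uid(m, "1.2.3.4")
  expect_identical(a1, a2)
  expect_false(a1 == "1.2.3.4")
  b <- remap_uid(m, "1.2.3.5")
  expect_false(a1 == b)
  expect_error(remap_uid(m, "not-a-uid"), "dotted-numeric")

  # collision sweep over 1000 random uids
  set.seed(7)
  uids <- unique(replicate(1000, paste(sample(0:999, 6, replace = TRUE),
                                       collapse = ".")))
  outs <- vapply(uids, function(u) remap_uid(m, u), "")
  expect_identical(anyDuplicated(outs), 0L)
  expect_true(all(nchar(outs) <= 64))
  expect_true(all(startsWith(outs, m$root_prefix)))
  expect_identical(nrow(uid_map_entries(m)), length(uids) + 2L)
})

test_that("apply_profile eradicates planted values at any depth", {
  sent <- c(name = "QX7PLMWR92AB", nested = "KJ3ZT8VYQ4CD",
            priv = "WM5NR2XKB7EF")
  ds <- dicom_dataset(
    PatientName = sent[["name"]],
    Modality = "MR", StudyDate = "20230405",
    StudyInstanceUID = "1.2.3", SOPClassUID = "1.2.840.10008.5.1.4.1.1.4",
    SOPInstanceUID = "1.2.3.9",
    ReferencedStudySequence = list(dicom_dataset(
      ReferencedSOPInstanceUID = "1.2.3",
      ReferencedStudySequence = list(dicom_dataset(
        PatientID = sent[["nested"]])))))
  ds[["00091001"]] <- imdeid:::dicom_element(9L, 0x1001L, "LO", sent[["priv"]])
  m <- uid_map()
  out <- apply_profile(ds, load_profile("basic"), m)
  blob <- imdeid:::encode_dataset(out$attrs)
  for (s in sent) {
    expect_identical(length(grepRaw(s, blob, fixed = TRUE, all = TRUE)), 0L)
  }

  # report records actions but never values
  expect_true(all(c("tag", "keyword", "action", "kind") %in%
                    names(out$records)))
  expect_false(any(vapply(sent, function(s)
    any(grepl(s, unlist(out$records), fixed = TRUE)), logical(1))))
  expect_true(nrow(out$records) >= 3)

  # idempotence under the same map
  again <- apply_profile(out$attrs, load_profile("basic"), m)
  expect_identical(again$attrs, out$attrs)

  # KEEP attributes byte-identical
  expect_identical(out$attrs[["00080060"]], ds[["00080060"]])

  # uid referential integrity: study uid and its reference share the remap
  su <- dicom_get(out$attrs, "StudyInstanceUID")
  sq <- dicom_get(out$attrs, "ReferencedStudySequence")
  expect_identical(dicom_get(sq[[1]], "ReferencedSOPInstanceUID"), su)

  # date policy: fixed anchor
  expect_identical(dicom_get(out$attrs, "StudyDate"), "19000101")

  # empty set maps to empty set with empty report
  empty <- apply_profile(list(), load_profile("basic"), uid_map())
  expect_identical(length(empty$attrs), 0L)
  expect_identical(nrow(empty$records), 0L)
})

test_that("ZERO action empties by kind and REPLACE_FIXED substitutes", {
  p <- deid_profile("z", list(tag_rule("PatientWeight", "ZERO"),
                              tag_rule("PatientName", "ZERO"),
                              tag_rule("PatientID", "REPLACE_FIXED", "ANON")),
                    "KEEP")
  ds <- dicom_dataset(PatientName = "Doe", PatientID = "123",
                      PatientWeight = "81.5")
  out <- apply_profile(ds, p, uid_map())$attrs
  expect_identical(dicom_get(out, "PatientName"), "")
  expect_identical(dicom_get(out, "PatientWeight"), "0")
  expect_identical(dicom_get(out, "PatientID"), "ANON")
})
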