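test_that("locate_headers finds every planted span in both dialects", {
  p <- tempfile(fileext = ".dat")
  man <- make_twix(p, n_measurements = 2, seed = 41)
  tw <- locate_twix_headers(readBin(p, "raw", file.info(p)$size))
  expect_identical(tw$dialect, "multi")
  expect_identical(length(tw$measurements), 2L)
  loc <- do.call(rbind, lapply(seq_along(tw$measurements), function(m) {
    do.call(rbind, lapply(tw$measurements[[m]]$header_spans, function(s) {
      data.frame(measurement = m, name = s$name,
                 byte_start = as.numeric(s$byte_start),
                 byte_length = as.numeric(s$byte_length),
                 stringsAsFactors = FALSE)
    }))
  }))
  expect_equal(loc, man$spans, ignore_attr = TRUE)
  expect_true(all(vapply(tw$measurements,
                         function(m) length(m$header_spans) >= 1, logical(1))))

  ps <- tempfile(fileext = ".dat")
  mans <- make_twix(ps, seed = 42, dialect = "single")
  tws <- locate_twix_headers(readBin(ps, "raw", file.info(ps)$size))
  expect_identical(tws$dialect, "single")
  expect_identical(length(tws$measurements), 1L)

  # random bytes are rejected with the dialects named
  expect_error(locate_twix_headers(as.raw(c(9, 7, 255, 255, 1:100))),
               "multi-measurement")
})

test_that("scrub_twix_text replaces values length-preservingly by syntax", {
  r <- scrub_twix_text('tPatientName = "MUSTERMANN"')
  expect_identical(r$text, 'tPatientName = "xxxxxxxxxx"')
  r2 <- scrub_twix_text("PatientID = 12345678")
  expect_identical(r2$text, "PatientID = 00000000")
  # quoted numerics are x-filled, unquoted zero-filled: decided by syntax
  r3 <- scrub_twix_text('PatientBirthDay = "19731021"')
  expect_identical(r3$text, 'PatientBirthDay = "xxxxxxxx"')
  # dotted ASCCONV names match on their final component
  r4 <- scrub_twix_text('sPatientInfo.tPatientName = "ABC"')
  expect_identical(r4$text, 'sPatientInfo.tPatientName = "xxx"')
  # untouched: non-patient keys and text without assignments
  clean <- "alTR[0] = 8600\ntProtocolName = \"t1_localizer\"\n"
  expect_identical(scrub_twix_text(clean)$text, clean)
  expect_identical(scrub_twix_text("no keys here")$text, "no keys here")
  # length conservation in general
  mixed <- paste0('tPatientName = "AB CD"\nPatientWeight = 78.5\n',
                  'sSliceArray.asSlice[0].dThickness = 5.0\n')
  out <- scrub_twix_text(mixed)
  expect_identical(nchar(out$text), nchar(mixed))
})

test_that("deid_twix_file conserves structure and eradicates sentinels", {
  p <- tempfile(fileext = ".dat")
  man <- make_twix(p, n_measurements = 3, seed = 17)
  out <- tempfile(fileext = ".dat")
  entry <- deid_twix_file(p, out)
  expect_identical(entry$status, "ok")

  b0 <- readBin(p, "raw", file.info(p)$size)
  b1 <- readBin(out, "raw", file.info(out)$size)
  expect_identical(length(b1), length(b0))

  # sentinel absent from the entire output, including both header blocks
  for (s in man$sentinels$value) {
    expect_identical(length(grepRaw(s, b1, fixed = TRUE, all = TRUE)), 0L)
  }
  # payload spans byte-identical
  for (i in seq_len(nrow(man$payload_spans))) {
    sp <- man$payload_spans[i, ]
    idx <- (sp$byte_start + 1):(sp$byte_start + sp$byte_length)
    expect_identical(b1[idx], b0[idx])
  }
  # bytes outside header spans identical
  hdr_idx <- unlist(lapply(seq_len(nrow(man$spans)), function(i) {
    (man$spans$byte_start[i] + 1):(man$spans$byte_start[i] +
                                     man$spans$byte_length[i])
  }))
  outside <- setdiff(seq_along(b0), hdr_idx)
  expect_identical(b1[outside], b0[outside])

  # idempotence: scrubbing twice equals scrubbing once
  out2 <- tempfile(fileext = ".dat")
  deid_twix_file(out, out2)
  expect_identical(readBin(out2, "raw", file.info(out2)$size), b1)
})

test_that("files without PHI keys pass through bit-identically", {
  p <- tempfile(fileext = ".dat")
  # build a twix file then pre-scrub it; scrubbing a scrubbed file is identity
  make_twix(p, n_measurements = 1, seed = 29)
  clean <- tempfile(fileext = ".dat")
  deid_twix_file(p, clean)
  out <- tempfile(fileext = ".dat")
  deid_twix_file(clean, out)
  expect_identical(readBin(out, "raw", file.info(out)$size),
                   readBin(clean, "raw", file.info(clean)$size))
})

test_that("output size equals input size over many random fixtures", {
  for (seed in 1:15) {
    p <- tempfile(fileext = ".dat")
    man <- make_twix(p, n_measurements = 1 + seed %% 3, seed = seed,
                     dialect = if (seed %% 4 == 0) "single" else "multi")
    out <- tempfile(fileext = ".dat")
    entry <- deid_twix_file(p, out)
    expect_identical(entry$status, "ok")
    expect_identical(file.info(out)$size, file.info(p)$size)
    unlink(c(p, out))
  }
})

test_that("failed twix processing leaves no partial output", {
  p <- tempfile(fileext = ".dat")
  writeBin(as.raw(c(9, 9, 9, 9, 1:50)), p)
  out <- tempfile(fileext = ".dat")
  entry <- deid_twix_file(p, out)
  expect_identical(entry$status, "failed")
  expect_false(file.exists(out))
})
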