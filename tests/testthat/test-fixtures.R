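test_that("generators are pure functions of parameters and seed", {
  d1 <- tmp_dir(); d2 <- tmp_dir()
  m1 <- make_dicom_series(d1, 2, seed = 7)
  m2 <- make_dicom_series(d2, 2, seed = 7)
  for (i in 1:2) {
    expect_identical(readBin(m1$files[i], "raw", file.info(m1$files[i])$size),
                     readBin(m2$files[i], "raw", file.info(m2$files[i])$size))
  }
  m3 <- make_dicom_series(tmp_dir(), 2, seed = 8)
  expect_false(identical(m1$sentinels$value, m3$sentinels$value))

  t1 <- tempfile(); t2 <- tempfile()
  make_twix(t1, 2, seed = 3); make_twix(t2, 2, seed = 3)
  expect_identical(readBin(t1, "raw", file.info(t1)$size),
                   readBin(t2, "raw", file.info(t2)$size))

  fx1 <- make_text_image(seed = 5)
  fx2 <- make_text_image(seed = 5)
  expect_identical(fx1$image, fx2$image)
  expect_identical(fx1$manifest, fx2$manifest)

  p1 <- make_head_phantom(seed = 21)
  p2 <- make_head_phantom(seed = 21)
  expect_identical(p1$volume$voxels, p2$volume$voxels)
})

test_that("dicom series manifest accounts for all planted sentinels", {
  d <- tmp_dir()
  man <- make_dicom_series(d, 3, seed = 55)
  expect_identical(length(man$files), 3L)
  # every manifest sentinel is actually present in the input bytes
  for (s in man$sentinels$value) {
    expect_gt(count_bytes_in_file(man$files[1], s), 0)
  }
  # instances share study/series uids and parse back
  for (f in man$files) {
    ds <- read_dicom(f)$attrs
    expect_identical(dicom_get(ds, "StudyInstanceUID"), man$uids$study)
    expect_identical(dicom_get(ds, "SeriesInstanceUID"), man$uids$series)
  }
})

test_that("twix manifest spans tile the header region and cover all keys", {
  p <- tempfile()
  man <- make_twix(p, 2, seed = 9)
  expect_identical(file.info(p)$size, as.numeric(man$file_length))
  b <- readBin(p, "raw", man$file_length)
  # every sentinel occurs inside a recorded header span (twice per file:
  # once per header block), never outside
  for (i in seq_len(nrow(man$sentinels))) {
    val <- man$sentinels$value[i]
    hits <- grepRaw(val, b, fixed = TRUE, all = TRUE)
    expect_gt(length(hits), 0)
    for (h in hits) {
      inside <- any(h > man$spans$byte_start &
                      h <= man$spans$byte_start + man$spans$byte_length)
      expect_true(inside)
    }
  }
  # span arithmetic: header spans + payloads stay within the file
  expect_true(all(man$spans$byte_start + man$spans$byte_length <=
                    man$file_length))
  expect_true(all(man$payload_spans$byte_start +
                    man$payload_spans$byte_length <= man$file_length))
})

test_that("wsi study fixture matches its manifest", {
  d <- tmp_dir()
  man <- make_wsi_study(d, levels = 2, seed = 15)
  expect_identical(length(man$files$pyramid), 2L)
  expect_identical(man$roles, c("VOLUME", "VOLUME", "OVERVIEW", "LABEL"))
  # label carries non-zero "text" pixels to blank
  lab <- dicom_pixel_array(read_dicom(man$files$label)$attrs)
  expect_gt(sum(lab == 250), 0)
  # recorded checksums match the files
  for (l in 1:2) {
    arr <- dicom_pixel_array(read_dicom(man$files$pyramid[l])$attrs)
    expect_identical(sum(arr), as.integer(man$pixel_checksums[l]))
  }
})

test_that("text-image fixture honors placements and stays in bounds", {
  fx <- make_text_image(width = 90, height = 70,
                        placements = c("border", "center", "border"), seed = 2)
  man <- fx$manifest
  expect_identical(nrow(man), 3L)
  expect_true(all(man$x >= 0 & man$x + man$w <= 90))
  expect_true(all(man$y >= 0 & man$y + man$h <= 70))
  ctr <- man[man$placement == "center", ]
  # center box overlaps the central rectangle of the default detector
  rect <- imdeid:::central_rectangle(fx$image, 0.5)
  expect_true(ctr$x >= rect$x && ctr$x + ctr$w <= rect$x + rect$w)
  # glyph blocks are rendered at the manifest positions
  for (i in seq_len(nrow(man))) {
    block <- fx$image[(man$y[i] + 1):(man$y[i] + man$h[i]),
                      (man$x[i] + 1):(man$x[i] + man$w[i])]
    expect_true(all(block == 0.55))
  }
})

test_that("head phantom mask sits inside the head and face adds voxels", {
  ph <- make_head_phantom(with_face = TRUE, seed = 6)
  ph0 <- make_head_phantom(with_face = FALSE, seed = 6)
  head_support <- ph$volume$voxels > 0
  expect_true(all(head_support[ph$mask]))          # mask subset of support
  expect_gt(ph$n_face_voxels, 0)
  expect_identical(ph0$n_face_voxels, 0L)
  expect_identical(sum(ph$volume$voxels > 0) - sum(ph0$volume$voxels > 0),
                   ph$n_face_voxels)
  # NIfTI round trip preserves voxels and orientation
  p <- tempfile(fileext = ".nii.gz")
  ph2 <- make_head_phantom(with_face = TRUE, orientation = "LPS", seed = 6,
                           path = p)
  img <- RNifti::readNifti(p)
  expect_equal(as.vector(img[]), as.vector(ph2$volume$voxels),
               tolerance = 1e-6)
  expect_identical(orientation_codes(RNifti::xform(img)), c("L", "P", "S"))
})
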