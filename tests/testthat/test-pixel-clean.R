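test_that("reorient_to_ras preserves world coordinates and voxel values", {
  set.seed(101)
  # a mix of orientations, including oblique-free permutations with flips
  for (orient in c("LPS", "PIR", "ASL", "RAS", "IPL")) {
    ph <- make_head_phantom(with_face = FALSE, orientation = orient,
                            seed = 7)
    vol <- ph$volume
    ras <- reorient_to_ras(vol)
    expect_identical(orientation_codes(ras$affine), c("R", "A", "S"))
    d <- dim(vol$voxels)
    inv <- solve(ras$affine)
    for (k in 1:20) {
      ijk <- vapply(d, function(n) sample(0:(n - 1), 1), numeric(1))
      w <- imdeid:::voxel_to_world(vol, ijk)
      ijk2 <- round((inv %*% c(w, 1))[1:3])
      expect_equal(ras$voxels[ijk2[1] + 1, ijk2[2] + 1, ijk2[3] + 1],
                   vol$voxels[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1])
    }
    # multiset of voxel values exactly preserved
    expect_identical(sort(as.vector(ras$voxels)),
                     sort(as.vector(vol$voxels)))
    # idempotence
    again <- reorient_to_ras(ras)
    expect_identical(again$voxels, ras$voxels)
    expect_equal(again$affine, ras$affine)
  }
  expect_error(reorient_to_ras(image_volume(array(0, c(2, 2, 2)),
                                            matrix(0, 4, 4))), "singular")
})

test_that("prepare_model_input standardizes to the target shape", {
  set.seed(5)
  vol <- image_volume(array(stats::runif(32 * 100 * 90, 10, 500),
                            dim = c(32, 100, 90)))
  out <- prepare_model_input(vol)
  expect_identical(dim(out), c(64L, 224L, 224L))
  expect_lt(abs(mean(out)), 1e-6)
  expect_lt(abs(sqrt(mean((out - mean(out))^2)) - 1), 1e-3)

  # constant volumes yield zeros, never NaN
  const <- prepare_model_input(image_volume(array(7, c(8, 9, 10))),
                               c(4, 4, 4))
  expect_true(all(const == 0))

  # resizing to the native shape is exact
  a <- array(stats::rnorm(6 * 7 * 8), dim = c(6, 7, 8))
  expect_identical(max(abs(resize_trilinear(a, c(6, 7, 8)) - a)), 0)

  # interpolation is linear: a linear ramp resamples exactly
  ramp <- array(rep(seq(0, 1, length.out = 21), each = 1), dim = c(21, 1, 1))
  up <- resize_trilinear(ramp, c(41, 1, 1))
  expect_equal(as.vector(up), seq(0, 1, length.out = 41), tolerance = 1e-12)
})

test_that("apply_mask satisfies the masked-sum identity exactly", {
  set.seed(9)
  a <- array(stats::runif(10 * 11 * 12), dim = c(10, 11, 12))
  m <- array(stats::runif(10 * 11 * 12) > 0.4, dim = c(10, 11, 12))
  out <- apply_mask(a, m)
  expect_identical(sum(out), sum(a[m]))
  expect_identical(out[m], a[m])          # true voxels untouched
  expect_true(all(out[!m] == 0))
  expect_identical(apply_mask(a, array(TRUE, dim(a))), a)
  expect_true(all(apply_mask(a, array(FALSE, dim(a))) == 0))
  # a mask on a coarser grid is resampled by nearest neighbour
  m2 <- array(TRUE, dim = c(5, 11, 12))
  expect_identical(apply_mask(a, m2), a)
  # image_volume in, image_volume out, affine carried
  vol <- image_volume(a)
  mv <- apply_mask(vol, m)
  expect_s3_class(mv, "image_volume")
  expect_identical(mv$affine, vol$affine)
})

test_that("two-pass detection finds border text in pass 1 and center text
          only after the rectangle is removed", {
  fx <- make_text_image(seed = 3)
  man <- fx$manifest
  ocr <- stub_ocr_engine(man)
  center <- man[man$placement == "center", ]
  border <- man[man$placement == "border", ]

  # single pass on the rectangle image: border boxes only
  rect <- imdeid:::central_rectangle(fx$image, 0.5)
  pass1_img <- imdeid:::fill_boxes(fx$image, as.data.frame(rect), 1)
  p1 <- ocr$detect(pass1_img)
  expect_identical(sort(p1$text), sort(border$text))
  expect_false(center$text %in% p1$text)

  # the two-pass union recovers the center box too
  boxes <- detect_text_two_pass(fx$image, ocr)
  expect_setequal(boxes$text, man$text)

  # blank image: nothing detected
  blank <- matrix(0, 50, 60)
  expect_identical(nrow(detect_text_two_pass(blank, stub_ocr_engine(NULL))),
                   0L)

  # two-pass result is a superset of a plain single pass
  single <- ocr$detect(fx$image)
  expect_true(all(single$text %in% boxes$text))

  # a broken engine is reported by name
  bad <- list(name = "brokenocr", detect = function(img) stop("boom"))
  expect_error(detect_text_two_pass(fx$image, bad), "brokenocr")
})

test_that("remove_text fills exactly the detected boxes", {
  fx <- make_text_image(seed = 8)
  man <- fx$manifest
  res <- remove_text(fx$image, stub_ocr_engine(man))
  # every planted box fully covered
  sc <- score_text_removal(list(res$image), list(man))
  expect_identical(sc$score, 1)
  # pixels outside all boxes bit-identical
  inside <- matrix(FALSE, nrow(fx$image), ncol(fx$image))
  for (i in seq_len(nrow(man))) {
    inside[(man$y[i] + 1):(man$y[i] + man$h[i]),
           (man$x[i] + 1):(man$x[i] + man$w[i])] <- TRUE
  }
  expect_identical(res$image[!inside], fx$image[!inside])
  # report carries geometry and confidence but no text content
  expect_named(res$report, c("x", "y", "w", "h", "confidence"))
  # textless image is returned unchanged
  quiet <- matrix(stats::runif(300, 0, 0.2), 15, 20)
  res2 <- remove_text(quiet, stub_ocr_engine(NULL))
  expect_identical(res2$image, quiet)

  # low-confidence and letter-free boxes are not filled
  man2 <- man
  man2$confidence <- 0.1
  res3 <- remove_text(fx$image, stub_ocr_engine(man2))
  expect_identical(res3$image, fx$image)
  man3 <- man
  man3$text <- "  ..  "
  res4 <- remove_text(fx$image, stub_ocr_engine(man3))
  expect_identical(res4$image, fx$image)
})

test_that("batch de-identification fraction matches the manifest oracle", {
  imgs <- list(); mans <- list()
  for (seed in 1:6) {
    fx <- make_text_image(seed = seed)
    mans[[seed]] <- fx$manifest
    if (seed <= 4) {
      imgs[[seed]] <- remove_text(fx$image, stub_ocr_engine(fx$manifest))$image
    } else {
      # leave one box uncovered: the image must not count as de-identified
      partial <- fx$manifest[-1, ]
      imgs[[seed]] <- imdeid:::fill_boxes(fx$image, partial, 1)
    }
  }
  sc <- score_text_removal(imgs, mans)
  expect_identical(sc$score, 4 / 6)
  expect_identical(sc$per_image, c(rep(TRUE, 4), FALSE, FALSE))
})
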