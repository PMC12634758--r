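# Pixel-level de-identification: volume reorientation and preprocessing,
# binary-mask application (the consumer side of skull-strip / deface
# segmentation), and two-pass OCR burned-in text removal.

#' Construct an image volume
#'
#' @param voxels 3D numeric array.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices, mm).
#' @return an `image_volume` list.
#' @export
image_volume <- function(voxels, affine = diag(4)) {
  stopifnot(length(dim(voxels)) == 3, all(dim(affine) == c(4, 4)))
  structure(list(voxels = voxels, affine = affine), class = "image_volume")
}

#' Axis codes of a volume's orientation (nearest-axis convention)
#'
#' @param affine 4x4 affine.
#' @return three characters from R/L, A/P, S/I: the world direction each
#'   voxel axis points towards.
#' @export
orientation_codes <- function(affine) {
  R <- affine[1:3, 1:3]
  codes <- character(3)
  pos <- c("R", "A", "S"); neg <- c("L", "P", "I")
  used <- integer(0)
  for (ax in 1:3) {
    col <- R[, ax]
    ord <- order(abs(col), decreasing = TRUE)
    w <- setdiff(ord, used)[1]
    used <- c(used, w)
    codes[ax] <- if (col[w] >= 0) pos[w] else neg[w]
  }
  codes
}

#' Reorient a volume to RAS
#'
#' Permutes and flips the voxel array so the first axis points Right, the
#' second Anterior, the third Superior, and updates the affine so every
#' voxel keeps its world coordinate.
#'
#' @param vol an [image_volume()].
#' @return the reoriented [image_volume()].
#' @export
reorient_to_ras <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  if (abs(det(vol$affine[1:3, 1:3])) < 1e-12) {
    stop("singular affine: orientation undefined")
  }
  codes <- orientation_codes(vol$affine)
  world_axis <- match(codes, c("R", "A", "S"))
  world_axis[is.na(world_axis)] <- match(codes[is.na(world_axis)],
                                         c("L", "P", "I"))
  flip <- codes %in% c("L", "P", "I")
  perm <- order(world_axis)          # voxel axes in world order R,A,S
  d <- dim(vol$voxels)
  v <- vol$voxels
  idx <- lapply(1:3, function(ax) {
    if (flip[ax]) rev(seq_len(d[ax])) else seq_len(d[ax])
  })
  v <- v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  v <- aperm(v, perm)
  # transform composing flip then permutation, on 0-based voxel indices
  A <- vol$affine
  Tm <- diag(4)
  for (new_ax in 1:3) {
    old_ax <- perm[new_ax]
    Tm[old_ax, ] <- 0
    if (flip[old_ax]) {
      Tm[old_ax, new_ax] <- -1
      Tm[old_ax, 4] <- d[old_ax] - 1
    } else {
      Tm[old_ax, new_ax] <- 1
    }
  }
  image_volume(v, A %*% Tm)
}

#' World coordinate of a (0-based) voxel index
#' @keywords internal
voxel_to_world <- function(vol, ijk) {
  as.numeric(vol$affine %*% c(as.numeric(ijk), 1))[1:3]
}

# Separable linear resize (equivalent to trilinear interpolation), with
# endpoint-aligned sampling so resizing to the same length is exact.
resize_axis <- function(arr, axis, target) {
  d <- dim(arr)
  n <- d[axis]
  if (n == target) return(arr)
  if (n == 1) {
    idx <- rep(1L, target)
    return(index_axis(arr, axis, idx))
  }
  pos <- if (target == 1) (n - 1) / 2 else (seq_len(target) - 1) * (n - 1) / (target - 1)
  lo <- pmin(floor(pos) + 1, n)
  hi <- pmin(lo + 1, n)
  w <- pos - (lo - 1)
  a_lo <- index_axis(arr, axis, lo)
  a_hi <- index_axis(arr, axis, hi)
  # broadcast the per-slice weights along the resized axis
  dd <- dim(a_lo)
  wfull <- aperm(array(w, dim = c(dd[axis], dd[-axis])),
                 order(c(axis, seq_len(3)[-axis])))
  a_lo * (1 - wfull) + a_hi * wfull
}

index_axis <- function(arr, axis, idx) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

#' Resize a 3D array with trilinear interpolation
#'
#' @param arr 3D numeric array.
#' @param target_shape integer vector of length 3.
#' @return resized array. Resizing to the input shape is the identity.
#' @export
resize_trilinear <- function(arr, target_shape) {
  stopifnot(length(dim(arr)) == 3, length(target_shape) == 3)
  for (ax in 1:3) arr <- resize_axis(arr, ax, target_shape[ax])
  arr
}

#' Prepare a volume as normalized model input
#'
#' Min-max normalizes intensities to `[0, 1]`, resizes to the target shape
#' with trilinear interpolation, then standardizes to zero mean and unit
#' standard deviation. Constant-intensity volumes yield all zeros.
#'
#' @param vol an [image_volume()] (expected already reoriented to RAS).
#' @param target_shape output dimensions; default `c(64, 224, 224)`.
#' @return numeric array of the target shape.
#' @export
prepare_model_input <- function(vol, target_shape = c(64L, 224L, 224L)) {
  v <- if (inherits(vol, "image_volume")) vol$voxels else vol
  stopifnot(length(dim(v)) == 3)
  rng <- range(v)
  if (rng[2] > rng[1]) {
    v <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    return(array(0, dim = target_shape))
  }
  v <- resize_trilinear(v, target_shape)
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) return(array(0, dim = target_shape))
  (v - mu) / sdv
}

#' Apply a binary mask to a volume
#'
#' Voxels outside the mask become 0; voxels inside are copied untouched.
#' A mask on a different grid is resampled to the volume's shape by
#' nearest neighbour.
#'
#' @param vol an [image_volume()] or 3D array.
#' @param mask logical/0-1 3D array (a brain or face-complement mask).
#' @return same type as `vol`, masked.
#' @export
apply_mask <- function(vol, mask) {
  v <- if (inherits(vol, "image_volume")) vol$voxels else vol
  m <- if (inherits(mask, "image_volume")) mask$voxels else mask
  stopifnot(length(dim(v)) == 3, length(dim(m)) == 3)
  if (!identical(dim(m), dim(v))) m <- resize_nearest(m, dim(v))
  out <- v
  out[!as.logical(m)] <- 0
  if (inherits(vol, "image_volume")) image_volume(out, vol$affine) else out
}

resize_nearest <- function(arr, target_shape) {
  d <- dim(arr)
  idx <- lapply(1:3, function(ax) {
    if (d[ax] == target_shape[ax]) return(seq_len(d[ax]))
    pmin(pmax(round(((seq_len(target_shape[ax]) - 0.5) * d[ax]) /
                      target_shape[ax] + 0.5), 1), d[ax])
  })
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# ---- burned-in text removal ----

norm_boxes <- function(boxes) {
  need <- c("x", "y", "w", "h", "text", "confidence")
  if (is.null(boxes) || NROW(boxes) == 0) {
    return(data.frame(x = integer(0), y = integer(0), w = integer(0),
                      h = integer(0), text = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE))
  }
  stopifnot(all(need %in% names(boxes)))
  boxes[need]
}

letter_boxes <- function(boxes, min_confidence) {
  boxes <- norm_boxes(boxes)
  txt <- trimws(boxes$text)
  keep <- nzchar(txt) & grepl("[[:alnum:]]", txt) &
    boxes$confidence >= min_confidence
  boxes[keep, , drop = FALSE]
}

fill_boxes <- function(image, boxes, fill_value) {
  for (i in seq_len(NROW(boxes))) {
    xs <- (boxes$x[i] + 1):(boxes$x[i] + boxes$w[i])
    ys <- (boxes$y[i] + 1):(boxes$y[i] + boxes$h[i])
    xs <- xs[xs >= 1 & xs <= ncol(image)]
    ys <- ys[ys >= 1 & ys <= nrow(image)]
    image[ys, xs] <- fill_value
  }
  image
}

central_rectangle <- function(image, rect_fraction) {
  h <- nrow(image); w <- ncol(image)
  rh <- max(1L, floor(h * rect_fraction))
  rw <- max(1L, floor(w * rect_fraction))
  y0 <- floor((h - rh) / 2)
  x0 <- floor((w - rw) / 2)
  list(x = x0, y = y0, w = rw, h = rh)
}

#' Two-pass burned-in text detection
#'
#' Pass 1 runs the OCR engine on a copy of the image with a white rectangle
#' over its centre, steering detection to the border region where scans
#' carry most of their annotations. Pass 2 removes the rectangle, fills the
#' pass-1 boxes, and runs the engine again so text in the image centre --
#' occluded during pass 1 -- is found as well. Returns the union of
#' letter-containing boxes from both passes.
#'
#' @param image 2D numeric matrix in `[0, 1]` (rows = y, cols = x).
#' @param ocr an OCR engine: a list with a `detect(image)` function
#'   returning a data.frame `x, y, w, h, text, confidence` (0-based,
#'   top-left origin, half-open boxes). See [stub_ocr_engine()].
#' @param rect_fraction fraction of each dimension the central rectangle
#'   covers; default 0.5.
#' @param min_confidence minimum detector confidence for a box to count;
#'   default 0.3.
#' @param passes number of detection passes; default 2.
#' @return data.frame of boxes (x, y, w, h, text, confidence).
#' @export
detect_text_two_pass <- function(image, ocr, rect_fraction = 0.5,
                                 min_confidence = 0.3, passes = 2L) {
  stopifnot(is.matrix(image), passes >= 1)
  if (is.null(ocr$detect) || !is.function(ocr$detect)) {
    stop("ocr adapter has no detect() function")
  }
  run_ocr <- function(img) {
    res <- tryCatch(ocr$detect(img), error = function(e) {
      stop("OCR engine '", ocr$name %||% "unnamed", "' failed: ",
           conditionMessage(e))
    })
    letter_boxes(res, min_confidence)
  }
  rect <- central_rectangle(image, rect_fraction)
  pass1_img <- fill_boxes(image, as.data.frame(rect), 1)
  found <- run_ocr(pass1_img)
  for (p in seq_len(passes - 1L)) {
    work <- fill_boxes(image, found, 1)  # rectangle removed, prior boxes filled
    extra <- run_ocr(work)
    if (NROW(extra) > 0) {
      key <- function(b) paste(b$x, b$y, b$w, b$h)
      extra <- extra[!key(extra) %in% key(found), , drop = FALSE]
      found <- rbind(found, extra)
    }
  }
  rownames(found) <- NULL
  found
}

#' Remove burned-in text from an image
#'
#' Runs [detect_text_two_pass()] and fills every returned box. Pixels
#' outside the boxes are copied exactly. The report lists box geometry and
#' confidence, never the detected text content.
#'
#' @inheritParams detect_text_two_pass
#' @param fill_value fill for detected boxes: `"white"` (image maximum of
#'   the value range, i.e. 1), `"black"` (0), or a number.
#' @return list with `image` (cleaned matrix) and `report` (data.frame of
#'   box geometry: x, y, w, h, confidence).
#' @export
remove_text <- function(image, ocr, rect_fraction = 0.5, fill_value = "white",
                        min_confidence = 0.3, passes = 2L) {
  fill <- if (identical(fill_value, "white")) 1
          else if (identical(fill_value, "black")) 0
          else as.numeric(fill_value)
  boxes <- detect_text_two_pass(image, ocr, rect_fraction = rect_fraction,
                                min_confidence = min_confidence,
                                passes = passes)
  out <- fill_boxes(image, boxes, fill)
  report <- boxes[c("x", "y", "w", "h", "confidence")]
  rownames(report) <- NULL
  list(image = out, report = report)
}

#' Batch text-removal score
#'
#' An image counts as de-identified only if every planted text box is fully
#' covered by the fill value; the score is the fraction of images meeting
#' that all-or-nothing criterion.
#'
#' @param images list of cleaned image matrices.
#' @param manifests list of box data.frames (x, y, w, h) of the text
#'   originally present in each image.
#' @param fill_value the fill used during cleaning (default 1).
#' @return list with `score` (fraction in `[0, 1]`), and `per_image`
#'   logical vector.
#' @export
score_text_removal <- function(images, manifests, fill_value = 1) {
  stopifnot(length(images) == length(manifests))
  per <- mapply(function(img, boxes) {
    boxes <- as.data.frame(boxes)
    for (i in seq_len(NROW(boxes))) {
      xs <- (boxes$x[i] + 1):(boxes$x[i] + boxes$w[i])
      ys <- (boxes$y[i] + 1):(boxes$y[i] + boxes$h[i])
      if (!all(img[ys, xs] == fill_value)) return(FALSE)
    }
    TRUE
  }, images, manifests)
  list(score = mean(per), per_image = as.logical(per))
}

#' Stub OCR engine driven by a fixture manifest
#'
#' Deterministic test double for a real OCR binary: it "detects" a manifest
#' box only while less than half of the box's area sits at the white/fill
#' level, which reproduces how a real engine stops seeing text once it is
#' occluded by the central rectangle or already filled.
#'
#' @param manifest data.frame of boxes (x, y, w, h, text, confidence).
#' @param white_value pixel level counted as occluding; default 1.
#' @return an OCR engine adapter (list with `name` and `detect`).
#' @export
stub_ocr_engine <- function(manifest, white_value = 1) {
  manifest <- norm_boxes(manifest)
  list(
    name = "stub",
    detect = function(image) {
      vis <- vapply(seq_len(NROW(manifest)), function(i) {
        xs <- (manifest$x[i] + 1):(manifest$x[i] + manifest$w[i])
        ys <- (manifest$y[i] + 1):(manifest$y[i] + manifest$h[i])
        mean(image[ys, xs] == white_value) < 0.5
      }, logical(1))
      manifest[vis, , drop = FALSE]
    }
  )
}
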