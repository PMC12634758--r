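# Defacing-score evaluation.
#
# A defaced head scan passes only if a face detector no longer finds a face
# in a frontal rendering of the volume. The rendering here is a
# deterministic maximum-intensity projection along the anterior axis of the
# RAS-reoriented volume -- an approximation of an interactive volumetric
# viewer's front-facing screenshot that can run unattended. The detector is
# a pluggable adapter so screenshots from any renderer, or any face
# detection library, can be scored with the same arithmetic.

#' Render a frontal view of a volume
#'
#' Reorients to RAS and takes the maximum-intensity projection along the
#' anterior axis. Rows run superior-to-inferior (top of the head at the top
#' of the image), columns along the right axis; intensities are min-max
#' scaled to 0..255.
#'
#' @param vol an [image_volume()].
#' @return integer matrix (superior-axis rows x right-axis cols) in 0..255.
#' @export
frontal_render <- function(vol) {
  if (!inherits(vol, "image_volume")) vol <- image_volume(vol)
  if (length(vol$voxels) == 0) stop("empty volume")
  ras <- reorient_to_ras(vol)
  mip <- apply(ras$voxels, c(1, 3), max)   # project over anterior axis
  img <- t(mip)                            # rows = superior axis
  img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  rng <- range(img)
  if (rng[2] > rng[1]) {
    img <- (img - rng[1]) / (rng[2] - rng[1])
  } else {
    img <- img * 0
  }
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}

#' Mock face detector
#'
#' Deterministic detector for tests and pipelines without a face-detection
#' dependency: reports one face whenever the rendered image contains any
#' pixel at or above `threshold` (an undefaced phantom projects bright
#' face-region pixels; a fully defaced or empty render does not).
#'
#' @param threshold 0..255 intensity above which a render counts as a face.
#' @return a detector adapter (list with `name` and `detect(image) -> count`).
#' @export
mock_face_detector <- function(threshold = 1) {
  list(name = "mock",
       detect = function(image) as.integer(any(image >= threshold)))
}

#' Defacing score of a batch of volumes
#'
#' Each volume is rendered frontally and passed to the detector; a scan
#' counts as still-detected if the detector reports at least one face. The
#' score is `100 * (n_total - n_detected) / n_total`: the percentage of
#' scans the detector can no longer classify as faces.
#'
#' @param volumes list of [image_volume()]s (or 3D arrays).
#' @param detector detector adapter with `detect(image) -> count`.
#' @return a `deface_score_result`: `n_total`, `n_detected`, `score`
#'   (percent), `per_scan` data.frame (detected, faces, error).
#' @export
defacing_score <- function(volumes, detector = mock_face_detector()) {
  stopifnot(length(volumes) >= 1)
  if (is.null(detector$detect) || !is.function(detector$detect)) {
    stop("detector adapter has no detect() function")
  }
  outcomes <- lapply(volumes, function(v) {
    tryCatch({
      n <- detector$detect(frontal_render(v))
      list(faces = as.integer(n), detected = n >= 1, error = NA_character_)
    }, error = function(e) {
      list(faces = NA_integer_, detected = NA, error = conditionMessage(e))
    })
  })
  per <- do.call(rbind, lapply(outcomes, as.data.frame,
                               stringsAsFactors = FALSE))
  errored <- !is.na(per$error)
  if (any(errored)) {
    warning(sum(errored), " scan(s) errored and were excluded from the score")
  }
  n_total <- sum(!errored)
  n_detected <- sum(per$detected[!errored])
  score <- if (n_total > 0) 100 * (n_total - n_detected) / n_total else NA_real_
  structure(list(n_total = n_total, n_detected = n_detected, score = score,
                 per_scan = per),
            class = "deface_score_result")
}

#' @export
print.deface_score_result <- function(x, ...) {
  cat(sprintf("Defacing score: %.2f%% (%d of %d scans no longer detected)\n",
              x$score, x$n_total - x$n_detected, x$n_total))
  invisible(x)
}
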