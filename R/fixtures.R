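# Synthetic fixture generators.
#
# Every generator is a pure function of (parameters, seed) and returns a
# manifest that fully accounts for the PHI it planted, so eradication tests
# can byte-grep outputs against the manifest with no ambiguity. Sentinels
# are high-entropy random alphanumerics (text) or long random digit runs
# (numeric), which makes accidental matches in unrelated bytes practically
# impossible. The generators emulate structure, not anatomy or scanner
# physics: geometric phantoms, noise backgrounds, solid glyph blocks.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random high-entropy sentinel string
#' @param n_chars sentinel length; default 12.
#' @return character scalar of alphanumerics (always starts with a letter).
#' @export
random_sentinel <- function(n_chars = 12) {
  pool <- c(LETTERS, 0:9)
  paste(c(sample(LETTERS, 1), sample(pool, n_chars - 1, replace = TRUE)),
        collapse = "")
}

random_digits <- function(n = 12) {
  paste(c(sample(1:9, 1), sample(0:9, n - 1, replace = TRUE)), collapse = "")
}

random_uid <- function(root = "1.2.840.99999.") {
  paste0(root, paste(sample(1e4:(1e5 - 1), 3), collapse = "."))
}

#' Generate a synthetic DICOM MR series with planted PHI
#'
#' Writes `n_instances` Part 10 files sharing Study/Series UIDs, with
#' sentinel values on identity attributes, inside a doubly nested sequence,
#' and on a private tag.
#'
#' @param out_dir output directory (created).
#' @param n_instances number of instances; default 3.
#' @param seed RNG seed.
#' @return manifest list: `files`, `sentinels` (data.frame tag/keyword/value),
#'   `uids` (study/series/sop), `pixel_checksums`.
#' @export
make_dicom_series <- function(out_dir, n_instances = 3, seed = 1) {
  stopifnot(n_instances >= 1)
  with_seed(seed, {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    study_uid <- random_uid()
    series_uid <- random_uid()
    frame_uid <- random_uid()
    sent <- list(
      PatientName = paste0(random_sentinel(), "^", random_sentinel()),
      PatientID = random_sentinel(),
      OtherPatientIDs = random_sentinel(),
      InstitutionName = random_sentinel(),
      ReferringPhysicianName = random_sentinel(),
      PatientComments = random_sentinel(),
      AccessionNumber = random_sentinel(10),
      StudyDescription = random_sentinel()
    )
    nested_id <- random_sentinel()
    private_val <- random_sentinel()
    files <- character(n_instances)
    sop_uids <- character(n_instances)
    checksums <- numeric(n_instances)
    for (i in seq_len(n_instances)) {
      sop_uids[i] <- random_uid()
      px_vals <- array(sample(0:4095, 32 * 32, replace = TRUE), dim = c(32, 32))
      checksums[i] <- sum(px_vals)
      ds <- dicom_dataset(
        SOPClassUID = .uid_mr_image_storage,
        SOPInstanceUID = sop_uids[i],
        StudyInstanceUID = study_uid,
        SeriesInstanceUID = series_uid,
        FrameOfReferenceUID = frame_uid,
        Modality = "MR",
        StudyDate = "20240517", SeriesDate = "20240517",
        StudyTime = "101500", PatientBirthDate = "19651203",
        PatientSex = "M", PatientAge = "058Y", PatientWeight = "81.5",
        StudyID = "ST001", SeriesNumber = as.character(1L),
        InstanceNumber = as.character(i),
        Manufacturer = "SyntheticScanner", ProtocolName = "t1_mprage",
        Rows = 32L, Columns = 32L, BitsAllocated = 16L, BitsStored = 12L,
        HighBit = 11L, PixelRepresentation = 0L, SamplesPerPixel = 1L,
        PhotometricInterpretation = "MONOCHROME2",
        ReferencedStudySequence = list(dicom_dataset(
          ReferencedSOPClassUID = .uid_mr_image_storage,
          ReferencedSOPInstanceUID = study_uid,
          ReferencedStudySequence = list(dicom_dataset(
            PatientID = nested_id)))),
        PixelData = dicom_encode_pixels(px_vals, 16L))
      for (kw in names(sent)) ds <- dicom_set(ds, kw, sent[[kw]])
      # private creator block with a sentinel payload
      ds[["00090010"]] <- dicom_element(0x0009L, 0x0010L, "LO", "SYNTH_PRIV")
      ds[["00091001"]] <- dicom_element(0x0009L, 0x1001L, "LO", private_val)
      ds <- dicom_sort(ds)
      files[i] <- file.path(out_dir, sprintf("mr_%03d.dcm", i))
      write_dicom(ds, files[i])
    }
    sentdf <- data.frame(
      tag = c(names(sent), "nested PatientID", "0009,1001"),
      value = c(unlist(sent), nested_id, private_val),
      stringsAsFactors = FALSE, row.names = NULL)
    list(files = files,
         sentinels = sentdf,
         uids = list(study = study_uid, series = series_uid,
                     frame = frame_uid, sop = sop_uids),
         pixel_checksums = checksums)
  })
}

#' Generate a synthetic NIfTI volume with PHI in its text fields
#'
#' @param path output `.nii` or `.nii.gz` path.
#' @param seed RNG seed.
#' @param with_extension also attach a header extension carrying a sentinel.
#' @return manifest list: `path`, `sentinels` (descrip/intent_name values),
#'   `dim`.
#' @export
make_nifti_with_phi <- function(path, seed = 1, with_extension = FALSE) {
  with_seed(seed, {
    arr <- array(stats::rnorm(16 * 18 * 14), dim = c(16, 18, 14))
    descrip_sent <- paste0(random_sentinel(), " ", random_digits(8))
    intent_sent <- random_sentinel(12)
    img <- RNifti::asNifti(arr)
    img$descrip <- descrip_sent
    img$intent_name <- intent_sent
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    RNifti::writeNifti(img, path)
    if (with_extension) {
      attach_nifti_extension(path, charToRaw(paste0("PHI:", descrip_sent)))
    }
    list(path = path,
         sentinels = c(descrip = descrip_sent, intent_name = intent_sent),
         dim = dim(arr))
  })
}

# Append a NIfTI-1 header extension block (ecode 0 = unknown), shifting the
# voxel payload; used to exercise the extension-stripping path.
attach_nifti_extension <- function(path, payload) {
  f <- read_file_bytes(path)
  b <- f$bytes
  endian <- nifti_endian(b)
  esize <- 8 + length(payload)
  esize <- esize + (16 - esize %% 16) %% 16    # extensions are 16-byte padded
  ext <- c(writeBin(as.integer(esize), raw(), size = 4, endian = endian),
           writeBin(0L, raw(), size = 4, endian = endian),
           payload, raw(esize - 8 - length(payload)))
  vox_offset <- readBin(b[109:112], "numeric", size = 4, endian = endian)
  payload_bytes <- b[(vox_offset + 1):length(b)]
  out <- c(b[1:348], as.raw(c(1, 0, 0, 0)), ext, payload_bytes)
  out[109:112] <- writeBin(352 + esize, raw(), size = 4, endian = endian)
  write_file_bytes(out, path, f$gz)
  invisible(path)
}

# ---- twix ----

twix_hdr_text <- function(sent) {
  paste0(
    "<XProtocol>\n",
    "PatientName = \"", sent$name, "\"\n",
    "PatientID = ", sent$id, "\n",
    "PatientBirthDay = ", sent$birthday, "\n",
    "PatientSex = 1\n",
    "InstitutionName = \"", sent$institution, "\"\n",
    "FrameOfReference = \"1.3.12.2.1107.5.2\"\n")
}

twix_hdr_string_text <- function(sent) {
  paste0(
    "### ASCCONV BEGIN ###\n",
    "ulVersion = 51130001\n",
    "tSequenceFileName = \"%SiemensSeq%\\gre\"\n",
    "tProtocolName = \"t1_localizer\"\n",
    "tPatientName = \"", sent$name, "\"\n",
    "PatientID = ", sent$id, "\n",
    "PatientBirthDay = ", sent$birthday, "\n",
    "flPatientAge = 47.25\n",
    "flUsedPatientWeight = 78.5\n",
    "lPatientSex = 2\n",
    "sPatientInfo.tInstitutionName = \"", sent$institution, "\"\n",
    "sSliceArray.asSlice[0].dThickness = 5.0\n",
    "sSliceArray.asSlice[0].dReadoutFOV = 260.0\n",
    "alTR[0] = 8600\n",
    "alTE[0] = 2460\n",
    "### ASCCONV END ###\n")
}

#' Generate a synthetic twix raw-data file with planted PHI
#'
#' Emits the simplified but structurally faithful layout the locator
#' parses: a multi-measurement offset/length table (or a single-measurement
#' header-length prefix), named header blocks with length prefixes, and a
#' binary k-space-like payload. The same sentinels are planted in both the
#' compact metadata block and the large protocol text block of every
#' measurement.
#'
#' @param path output `.dat` path.
#' @param n_measurements number of measurements (multi dialect); default 2.
#' @param seed RNG seed.
#' @param dialect `"multi"` or `"single"` (single forces one measurement).
#' @return manifest list: `path`, `sentinels` (data.frame key/value/kind),
#'   `spans` (data.frame measurement/name/byte_start/byte_length),
#'   `payload_spans`, `file_length`.
#' @export
make_twix <- function(path, n_measurements = 2, seed = 1,
                      dialect = c("multi", "single")) {
  dialect <- match.arg(dialect)
  if (dialect == "single") n_measurements <- 1L
  stopifnot(n_measurements >= 1, n_measurements <= 64)
  with_seed(seed, {
    sent <- list(name = random_sentinel(), id = random_digits(),
                 birthday = random_digits(8),
                 institution = random_sentinel())
    meas_raw <- vector("list", n_measurements)
    spans_rel <- vector("list", n_measurements)
    payload_rel <- vector("list", n_measurements)
    for (m in seq_len(n_measurements)) {
      blocks <- list(list(name = "hdr", text = twix_hdr_text(sent)),
                     list(name = "hdr string",
                          text = twix_hdr_string_text(sent)))
      body <- u32_raw(length(blocks))
      rel <- list()
      for (bl in blocks) {
        name_raw <- charToRaw(bl$name)
        name_field <- c(name_raw, raw(.twix_block_name_len - length(name_raw)))
        text_raw <- charToRaw(bl$text)
        rel[[length(rel) + 1]] <- list(name = bl$name,
                                       byte_start = length(body) +
                                         .twix_block_name_len + 4,
                                       byte_length = length(text_raw))
        body <- c(body, name_field, u32_raw(length(text_raw)), text_raw)
      }
      payload <- as.raw(sample(0:255, 256 + 64 * m, replace = TRUE))
      payload_rel[[m]] <- c(length(body), length(payload))
      meas_raw[[m]] <- c(body, payload)
      spans_rel[[m]] <- rel
    }
    if (dialect == "multi") {
      table_len <- 8 + 16 * n_measurements
      offsets <- cumsum(c(table_len,
                          head(vapply(meas_raw, length, 0), -1)))
      header <- c(u32_raw(0), u32_raw(n_measurements))
      for (m in seq_len(n_measurements)) {
        header <- c(header, u64_raw(offsets[m]),
                    u64_raw(length(meas_raw[[m]])))
      }
      out <- c(header, do.call(c, meas_raw))
      base <- offsets
    } else {
      hdr_len <- 4 + payload_rel[[1]][1]
      out <- c(u32_raw(hdr_len), meas_raw[[1]])
      base <- 4
    }
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writeBin(out, path)
    spans <- do.call(rbind, lapply(seq_len(n_measurements), function(m) {
      do.call(rbind, lapply(spans_rel[[m]], function(sp) {
        data.frame(measurement = m, name = sp$name,
                   byte_start = base[m] + sp$byte_start,
                   byte_length = sp$byte_length, stringsAsFactors = FALSE)
      }))
    }))
    payload_spans <- do.call(rbind, lapply(seq_len(n_measurements),
      function(m) data.frame(measurement = m,
                             byte_start = base[m] + payload_rel[[m]][1],
                             byte_length = payload_rel[[m]][2])))
    sentdf <- data.frame(
      key = c("PatientName/tPatientName", "PatientID", "PatientBirthDay",
              "InstitutionName"),
      value = c(sent$name, sent$id, sent$birthday, sent$institution),
      kind = c("text", "numeric", "numeric", "text"),
      stringsAsFactors = FALSE)
    list(path = path, dialect = dialect, sentinels = sentdf, spans = spans,
         payload_spans = payload_spans, file_length = length(out))
  })
}

# ---- WSI ----

rgb_noise <- function(rows, cols) {
  array(sample(20:120, rows * cols * 3, replace = TRUE),
        dim = c(rows, cols, 3))
}

#' Generate a synthetic DICOM-WSI study
#'
#' Pyramid levels plus an overview image (with a bright label-like region on
#' its left side) and a label image with bright handwriting-like pixels, all
#' sharing a StudyInstanceUID and carrying PHI sentinels in their metadata.
#'
#' @param out_dir output directory.
#' @param levels number of pyramid zoom levels; default 3.
#' @param converted flag recorded in the manifest (converted studies drop
#'   the label during de-identification).
#' @param seed RNG seed.
#' @return manifest list: `files` (named: pyramid/overview/label), `roles`,
#'   `sentinels`, `uids`, `pixel_checksums` (per pyramid file),
#'   `overview_dim`, `converted`.
#' @export
make_wsi_study <- function(out_dir, levels = 3, converted = FALSE, seed = 1) {
  stopifnot(levels >= 1)
  with_seed(seed, {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    study_uid <- random_uid()
    series_uid <- random_uid()
    sent <- list(PatientName = random_sentinel(),
                 PatientID = random_sentinel(),
                 InstitutionName = random_sentinel())
    base_ds <- function(sop_uid, image_type, arr) {
      ds <- dicom_dataset(
        SOPClassUID = .uid_vl_wsi_storage,
        SOPInstanceUID = sop_uid,
        StudyInstanceUID = study_uid,
        SeriesInstanceUID = series_uid,
        Modality = "SM",
        ImageType = image_type,
        StudyDate = "20240102", StudyTime = "090000",
        Rows = dim(arr)[1], Columns = dim(arr)[2],
        SamplesPerPixel = 3L, PlanarConfiguration = 0L,
        BitsAllocated = 8L, BitsStored = 8L, HighBit = 7L,
        PixelRepresentation = 0L,
        PhotometricInterpretation = "RGB",
        PixelData = dicom_encode_pixels(arr, 8L))
      for (kw in names(sent)) ds <- dicom_set(ds, kw, sent[[kw]])
      ds
    }
    files <- list(pyramid = character(levels))
    checks <- numeric(levels)
    size <- 64L
    for (l in seq_len(levels)) {
      arr <- rgb_noise(size, size)
      checks[l] <- sum(arr)
      p <- file.path(out_dir, sprintf("pyramid_%d.dcm", l))
      write_dicom(base_ds(random_uid(),
                          c("ORIGINAL", "PRIMARY", "VOLUME", "NONE"), arr), p)
      files$pyramid[l] <- p
      size <- max(8L, size %/% 2L)
    }
    ov <- rgb_noise(48L, 80L)
    ov[10:40, 4:28, ] <- 235L        # label sticker on the left side
    files$overview <- file.path(out_dir, "overview.dcm")
    write_dicom(base_ds(random_uid(),
                        c("ORIGINAL", "PRIMARY", "OVERVIEW", "NONE"), ov),
                files$overview)
    lab <- rgb_noise(48L, 48L)
    lab[seq(6, 42, by = 6), 6:42, ] <- 250L   # handwriting-like strokes
    files$label <- file.path(out_dir, "label.dcm")
    write_dicom(base_ds(random_uid(),
                        c("ORIGINAL", "PRIMARY", "LABEL", "NONE"), lab),
                files$label)
    sentdf <- data.frame(tag = names(sent), value = unlist(sent),
                         stringsAsFactors = FALSE, row.names = NULL)
    list(files = files,
         roles = c(rep("VOLUME", levels), "OVERVIEW", "LABEL"),
         sentinels = sentdf,
         uids = list(study = study_uid, series = series_uid),
         pixel_checksums = checks,
         overview_dim = dim(ov),
         converted = converted)
  })
}

# ---- 2D text images ----

#' Generate a 2D image with burned-in text blocks
#'
#' Renders each "text" as a solid glyph block on a noisy background and
#' returns the box manifest the stub OCR engine consumes. Placements:
#' `"border"` boxes sit in the outer margin, `"center"` boxes near the
#' image centre (under the central rectangle of the two-pass detector).
#'
#' @param width,height image size in pixels.
#' @param placements character vector of `"border"` / `"center"`, one per
#'   planted text; default two border and one center.
#' @param seed RNG seed.
#' @return list: `image` (matrix in `[0,1]`), `manifest` (data.frame x, y,
#'   w, h, text, confidence, placement).
#' @export
make_text_image <- function(width = 120, height = 100,
                            placements = c("border", "border", "center"),
                            seed = 1) {
  with_seed(seed, {
    img <- matrix(stats::runif(height * width, 0, 0.2), height, width)
    boxes <- list()
    border_slots <- list(
      c(2, 2), c(width - 34, 2), c(2, height - 14), c(width - 34, height - 14))
    slot_i <- 0
    for (pl in placements) {
      txt <- random_sentinel(8)
      w <- 4 * nchar(txt)
      h <- 10L
      if (pl == "border") {
        slot_i <- slot_i %% length(border_slots) + 1
        at <- border_slots[[slot_i]]
        x <- at[1]; y <- at[2]
      } else {
        x <- floor(width / 2 - w / 2) + sample(-3:3, 1)
        y <- floor(height / 2 - h / 2) + sample(-3:3, 1)
      }
      img[(y + 1):(y + h), (x + 1):(x + w)] <- 0.55
      boxes[[length(boxes) + 1]] <- data.frame(
        x = x, y = y, w = w, h = h, text = txt, confidence = 0.9,
        placement = pl, stringsAsFactors = FALSE)
    }
    manifest <- if (length(boxes)) do.call(rbind, boxes) else
      data.frame(x = integer(0), y = integer(0), w = integer(0),
                 h = integer(0), text = character(0),
                 confidence = numeric(0), placement = character(0))
    list(image = img, manifest = manifest)
  })
}

# ---- head phantom ----

#' Generate a geometric head phantom volume and brain mask
#'
#' An ellipsoidal "head" with a brighter inner "brain" ellipsoid, optionally
#' an anterior protrusion standing in for facial features. Geometry is
#' defined in world millimetres, so any requested orientation yields the
#' same anatomy.
#'
#' @param with_face add anterior face voxels.
#' @param orientation three axis codes, e.g. `"RAS"`, `"LPS"`, `"PIR"`.
#' @param seed RNG seed.
#' @param shape voxel grid size; default `c(32, 36, 34)`.
#' @param path optional `.nii`/`.nii.gz` path to also write the volume.
#' @return list: `volume` ([image_volume()]), `mask` (logical array),
#'   `n_face_voxels`, `path` (or `NULL`).
#' @export
make_head_phantom <- function(with_face = TRUE, orientation = "RAS",
                              seed = 1, shape = c(32L, 36L, 34L),
                              path = NULL) {
  codes <- strsplit(toupper(orientation), "")[[1]]
  stopifnot(length(codes) == 3)
  world_axis <- match(codes, c("R", "A", "S"))
  neg <- is.na(world_axis)
  world_axis[neg] <- match(codes[neg], c("L", "P", "I"))
  if (any(is.na(world_axis)) || length(unique(world_axis)) != 3) {
    stop("orientation must use one code per axis from R/L, A/P, S/I")
  }
  sign <- ifelse(neg, -1, 1)
  spacing <- 2
  R <- matrix(0, 3, 3)
  for (ax in 1:3) R[world_axis[ax], ax] <- sign[ax] * spacing
  centre_index <- (shape - 1) / 2
  trans <- -as.numeric(R %*% centre_index)
  affine <- rbind(cbind(R, trans), c(0, 0, 0, 1))
  with_seed(seed, {
    idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                                 k = 0:(shape[3] - 1)))
    world <- t(R %*% t(idx)) + matrix(trans, nrow(idx), 3, byrow = TRUE)
    x <- world[, 1]; y <- world[, 2]; z <- world[, 3]
    head_r <- c(24, 27, 29)
    head_in <- (x / head_r[1])^2 + (y / head_r[2])^2 + (z / head_r[3])^2 <= 1
    brain_in <- (x / (0.7 * head_r[1]))^2 + (y / (0.7 * head_r[2]))^2 +
      ((z - 4) / (0.7 * head_r[3]))^2 <= 1
    face_in <- rep(FALSE, length(x))
    if (with_face) {
      # nose-like protrusion on the anterior surface, below mid-height
      face_in <- (x / 7)^2 + ((y - head_r[2]) / 9)^2 + ((z + 8) / 7)^2 <= 1
      face_in <- face_in & !head_in
    }
    vox <- numeric(length(x))
    vox[head_in] <- 100
    vox[brain_in] <- 130
    vox[face_in] <- 90
    vox <- vox + stats::runif(length(vox), 0, 1) * (vox > 0)
    v <- array(vox, dim = shape)
    mask <- array(brain_in, dim = shape)
    vol <- image_volume(v, affine)
    if (!is.null(path)) {
      img <- RNifti::asNifti(v)
      img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      RNifti::writeNifti(img, path)
    }
    list(volume = vol, mask = mask, n_face_voxels = sum(face_in),
         path = path)
  })
}
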