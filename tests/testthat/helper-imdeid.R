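# Shared test helpers.

# Number of byte-level occurrences of an ASCII sentinel in a file.
count_bytes_in_file <- function(path, needle) {
  n <- file.info(path)$size
  b <- readBin(path, "raw", n = n)
  as.numeric(length(grepRaw(needle, b, fixed = TRUE, all = TRUE)))
}

# Total sentinel hits across all files of a directory tree.
sentinel_hits <- function(dir, sentinels) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  sum(vapply(files, function(f) {
    sum(vapply(sentinels, function(s) count_bytes_in_file(f, s), numeric(1)))
  }, numeric(1)))
}

tmp_dir <- function() {
  d <- tempfile("imdeid-")
  dir.create(d)
  d
}

# Glyph-block image with planted boxes at explicit positions.
plant_boxes <- function(image, boxes, value = 0.55) {
  for (i in seq_len(nrow(boxes))) {
    image[(boxes$y[i] + 1):(boxes$y[i] + boxes$h[i]),
          (boxes$x[i] + 1):(boxes$x[i] + boxes$w[i])] <- value
  }
  image
}
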