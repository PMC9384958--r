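#' Load a strip image from disk
#'
#' Reads PNG, TIFF (8-bit) or PGM (P2/P5) images bit-exactly into a
#' [strip_image]. RGB images keep their three channels; alpha channels are
#' dropped. Bit depths above 8 bits per channel are rejected.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` or `.pgm` file.
#' @return A [strip_image] with integer counts in \[0, 255\].
#' @examples
#' cfg <- phantom_config(pixel_noise_sd = 0, strip_jitter_sd = 0)
#' f <- tempfile(fileext = ".png")
#' write_strip_png(render_strip(300, cfg)$image, f)
#' img <- load_image(f)
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop_lfa("lfaquant_io_error", "file not found: %s", path)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = read_png_counts(path),
    tif = ,
    tiff = read_tiff_counts(path),
    pgm = read_pgm(path),
    stop_lfa("lfaquant_format_error", "unsupported image format: .%s", ext)
  )
  strip_image(arr)
}

read_png_counts <- function(path) {
  raw <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) stop_lfa("lfaquant_io_error",
                                               "failed to read PNG %s: %s", path, conditionMessage(e)))
  info <- attr(raw, "info")
  if (!is.null(info$bit.depth) && info$bit.depth > 8) {
    stop_lfa("lfaquant_format_error", "bit depth %d > 8 not supported", info$bit.depth)
  }
  counts_from_unit(raw)
}

read_tiff_counts <- function(path) {
  raw <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e) stop_lfa("lfaquant_io_error",
                                               "failed to read TIFF %s: %s", path, conditionMessage(e)))
  bps <- attr(raw, "bits.per.sample")
  if (!is.null(bps) && any(bps > 8)) {
    stop_lfa("lfaquant_format_error", "bit depth %d > 8 not supported", max(bps))
  }
  counts_from_unit(raw)
}

# readers return values on [0,1]; recover 8-bit counts exactly
counts_from_unit <- function(raw) {
  arr <- array(round(raw * 255), dim = dim(raw))  # k/255 * 255 rounds back to k;
  # array() also drops the reader's metadata attributes
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] >= 3) arr <- arr[, , 1:3, drop = FALSE] else arr <- arr[, , 1]
    if (length(dim(arr)) == 3 && dim(arr)[3] == 1) arr <- arr[, , 1]
  }
  arr
}

# Minimal PGM reader: plain (P2) and binary (P5), maxval <= 255.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # read header tokens, skipping '#' comments
  buf <- character(0)
  while (length(tokens) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0 || nchar(ch) == 0) {
      stop_lfa("lfaquant_io_error", "truncated PGM header in %s", path)
    }
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch %in% c("\n", "\r")) break
      }
      next
    }
    if (grepl("^[ \t\r\n]$", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3]); maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5")) {
    stop_lfa("lfaquant_format_error", "not a PGM file (magic %s)", magic)
  }
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1 || h < 1) {
    stop_lfa("lfaquant_io_error", "bad PGM header in %s", path)
  }
  if (maxval > 255) {
    stop_lfa("lfaquant_format_error", "PGM maxval %d > 255 not supported", maxval)
  }
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = n))
  } else {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    vals <- suppressWarnings(as.integer(strsplit(trimws(txt), "[ \t\r\n]+")[[1]]))
  }
  if (length(vals) < n || anyNA(vals[seq_len(n)])) {
    stop_lfa("lfaquant_io_error", "truncated PGM pixel data in %s", path)
  }
  matrix(vals[seq_len(n)], nrow = h, ncol = w, byrow = TRUE)
}

#' Write a strip image as an 8-bit grayscale PNG
#'
#' @param img A [strip_image] (grayscale). Values are quantised half-up
#'   before writing.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strip_png <- function(img, path) {
  stopifnot(inherits(img, "strip_image"))
  if (img$channels != 1L) {
    stop_lfa("lfaquant_format_error", "write_strip_png expects a grayscale image")
  }
  px <- pmin(round_half_up(img$pixels), 255)
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Write a strip image as a plain-text PGM (P2)
#'
#' @param img A grayscale [strip_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strip_pgm <- function(img, path) {
  stopifnot(inherits(img, "strip_image"))
  if (img$channels != 1L) {
    stop_lfa("lfaquant_format_error", "write_strip_pgm expects a grayscale image")
  }
  px <- pmin(round_half_up(img$pixels), 255)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("P2", paste(img$width, img$height), "255"), con)
  apply(px, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
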