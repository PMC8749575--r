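#' Construct a RawImage
#'
#' @param pixels integer matrix (grey) or rows x cols x 3 array (RGB) of
#'   sample values.
#' @param bitDepth bits per sample, 8 (default) or 16.
#' @param sourceId free-text provenance.
#' @param plane scanning-plane label (`"L"`, `"T"`, `"O1"`, `"O2"`) or `NA`.
#' @return a [RawImage-class].
#' @export
RawImage <- function(pixels, bitDepth = 8L, sourceId = "", plane = NA_character_) {
  pixels <- as.array(pixels)
  channels <- if (length(dim(pixels)) == 3L) dim(pixels)[3] else 1L
  new("RawImage", pixels = pixels, channels = as.integer(channels),
      bitDepth = as.integer(bitDepth), sourceId = as.character(sourceId),
      plane = as.character(plane))
}

#' Construct a GreyImage
#'
#' @param pixels numeric matrix of whole numbers in `[0, 255]`.
#' @param normalized whether the byte-scale stretch has been applied.
#' @param plane scanning-plane label or `NA`.
#' @param sourceId free-text provenance.
#' @return a [GreyImage-class].
#' @export
GreyImage <- function(pixels, normalized = FALSE, plane = NA_character_,
                      sourceId = "") {
  storage.mode(pixels) <- "double"
  new("GreyImage", pixels = pixels, normalized = normalized,
      plane = as.character(plane), sourceId = as.character(sourceId))
}

## round-half-up; base round() is round-half-even, which would make the
## byte-scale examples grid-dependent
roundHalfUp <- function(x) floor(x + 0.5)

#' Parse a scanning-plane label from a file name
#'
#' Recognizes the case-insensitive suffixes `_L`, `_T`, `_O1`, `_O2`
#' immediately before the file extension, e.g. `bird07_O1.png` -> `"O1"`.
#'
#' @param path file name or path.
#' @return `"L"`, `"T"`, `"O1"`, `"O2"` or `NA_character_`.
#' @export
parsePlaneFromName <- function(path) {
  stem <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(stem, regexpr("_(l|t|o1|o2)$", stem, ignore.case = TRUE))
  if (length(m) == 0L) return(NA_character_)
  toupper(sub("^_", "", m))
}

#' Read an ultrasonogram from a standard image container
#'
#' Supported containers: PNG, TIFF, BMP (24-bit uncompressed), and
#' single-frame uncompressed DICOM (8- or 16-bit greyscale or 8-bit RGB).
#' DICOM `MONOCHROME1` images are inverted to the `MONOCHROME2` convention,
#' so larger sample values always mean brighter echoes.
#'
#' @param path path to the image file.
#' @param plane optional scanning-plane label; when `NULL` it is parsed from
#'   the file-name suffix (`_L`, `_T`, `_O1`, `_O2`; see
#'   [parsePlaneFromName()]).
#' @return a [RawImage-class].
#' @export
readUltrasound <- function(path, plane = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path)
  if (is.null(plane)) plane <- parsePlaneFromName(path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = readPngRaw(path),
    tif  = ,
    tiff = readTiffRaw(path),
    bmp  = readBmpRaw(path),
    dcm  = ,
    dicom = readDicomRaw(path),
    stop("unsupported image container '", ext, "' for file: ", path)
  )
  RawImage(img$pixels, bitDepth = img$bitDepth, sourceId = basename(path),
           plane = plane)
}

readPngRaw <- function(path) {
  arr <- tryCatch(png::readPNG(path, info = TRUE),
                  error = function(e) stop("unreadable PNG file: ", path,
                                           " (", conditionMessage(e), ")"))
  info <- attr(arr, "info")
  bits <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth else 8L
  bits <- max(8L, as.integer(bits))
  if (length(dim(arr)) == 3L && dim(arr)[3] == 4L)
    stop("4-channel (alpha) image not supported; remove the alpha channel: ",
         path)
  if (length(dim(arr)) == 3L && dim(arr)[3] == 2L)
    arr <- arr[, , 1, drop = TRUE]  # grey + alpha: alpha must be opaque-only
  px <- roundHalfUp(arr * (2^bits - 1))
  list(pixels = array(px, dim(px)), bitDepth = bits)
}

readTiffRaw <- function(path) {
  arr <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e) stop("unreadable TIFF file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (is.list(arr) && !is.array(arr))
    stop("multi-page TIFF not supported; extract a single page: ", path)
  bits <- attr(arr, "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  bits <- max(8L, as.integer(bits))
  if (length(dim(arr)) == 3L && dim(arr)[3] == 4L)
    stop("4-channel (alpha) image not supported; remove the alpha channel: ",
         path)
  px <- roundHalfUp(arr * (2^bits - 1))
  list(pixels = array(px, dim(px)), bitDepth = bits)
}

## Minimal reader for uncompressed 24-bit BMP (the common BITMAPINFOHEADER
## bottom-up layout with 4-byte row padding). No installed R package reads
## BMP, so the format is parsed directly.
readBmpRaw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  if (length(magic) < 2L || rawToChar(magic) != "BM")
    stop("unreadable BMP file (bad magic): ", path)
  readBin(con, "raw", 8L)                                  # size + reserved
  dataOffset <- readBin(con, "integer", 1L, 4L, endian = "little")
  headerSize <- readBin(con, "integer", 1L, 4L, endian = "little")
  if (headerSize < 40L) stop("unsupported BMP header in: ", path)
  width  <- readBin(con, "integer", 1L, 4L, endian = "little")
  height <- readBin(con, "integer", 1L, 4L, endian = "little")
  readBin(con, "integer", 1L, 2L, endian = "little")       # planes
  bpp <- readBin(con, "integer", 1L, 2L, endian = "little")
  compression <- readBin(con, "integer", 1L, 4L, endian = "little")
  if (bpp != 24L || compression != 0L)
    stop("only uncompressed 24-bit BMP supported: ", path)
  if (width < 1L || abs(height) < 1L)
    stop("unreadable BMP file (bad dimensions): ", path)
  seek(con, dataOffset)
  topDown <- height < 0L
  height <- abs(height)
  rowBytes <- ((width * 3L + 3L) %/% 4L) * 4L
  bytes <- readBin(con, "raw", rowBytes * height)
  if (length(bytes) < rowBytes * height)
    stop("unreadable BMP file (truncated pixel data): ", path)
  v <- as.integer(bytes)
  px <- array(0L, dim = c(height, width, 3L))
  for (r in seq_len(height)) {
    rowStart <- (r - 1L) * rowBytes
    idx <- rowStart + seq_len(width * 3L)
    row <- matrix(v[idx], nrow = 3L)                       # B, G, R triples
    outRow <- if (topDown) r else height - r + 1L
    px[outRow, , 1L] <- row[3L, ]
    px[outRow, , 2L] <- row[2L, ]
    px[outRow, , 3L] <- row[1L, ]
  }
  list(pixels = px, bitDepth = 8L)
}

## Minimal reader for single-frame uncompressed DICOM, explicit or implicit
## VR little endian. Parses only the tags needed for pixel access; no
## installed R package reads DICOM, so the elements are parsed directly.
readDicomRaw <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 132L || rawToChar(bytes[129:132]) != "DICM")
    stop("unreadable DICOM file (missing DICM magic): ", path)
  pos <- 133L
  tagU16 <- function(at) {
    as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
  }
  u32 <- function(at) {
    as.numeric(as.integer(bytes[at])) +
      256 * as.integer(bytes[at + 1L]) +
      65536 * as.integer(bytes[at + 2L]) +
      16777216 * as.integer(bytes[at + 3L])
  }
  longVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  elems <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- tagU16(pos); elem <- tagU16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit) {
      if (vr %in% longVRs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- tagU16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) {
      if (identical(vr, "SQ") || is.na(vr))
        stop("DICOM sequences with undefined length not supported: ", path)
      stop("undefined-length element not supported in: ", path)
    }
    valStart <- pos + hdr
    if (valStart + len - 1L > n)
      stop("unreadable DICOM file (truncated element): ", path)
    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% c("0028,0010", "0028,0011", "0028,0002", "0028,0100",
                   "0028,0103", "0028,0004", "0028,0008", "7fe0,0010"))
      elems[[key]] <- bytes[valStart:(valStart + len - 1L)]
    pos <- valStart + len
  }
  need <- function(key, what) {
    if (is.null(elems[[key]])) stop("DICOM file lacks ", what, ": ", path)
    elems[[key]]
  }
  us <- function(rawv) as.integer(rawv[1]) + 256L * as.integer(rawv[2])
  rows <- us(need("0028,0010", "Rows"))
  cols <- us(need("0028,0011", "Columns"))
  samples <- if (is.null(elems[["0028,0002"]])) 1L else us(elems[["0028,0002"]])
  bits <- if (is.null(elems[["0028,0100"]])) 8L else us(elems[["0028,0100"]])
  photometric <- if (is.null(elems[["0028,0004"]])) "MONOCHROME2" else
    trimws(rawToChar(elems[["0028,0004"]]))
  if (!is.null(elems[["0028,0008"]])) {
    nframes <- suppressWarnings(as.integer(trimws(rawToChar(elems[["0028,0008"]]))))
    if (!is.na(nframes) && nframes > 1L)
      stop("multi-frame DICOM not supported; extract a single frame first: ",
           path)
  }
  if (!(samples %in% c(1L, 3L)))
    stop("unsupported SamplesPerPixel (", samples, ") in: ", path)
  if (!(bits %in% c(8L, 16L)))
    stop("unsupported BitsAllocated (", bits, ") in: ", path)
  pdata <- need("7fe0,0010", "PixelData")
  npx <- rows * cols * samples
  if (bits == 8L) {
    if (length(pdata) < npx)
      stop("unreadable DICOM file (truncated PixelData): ", path)
    v <- as.integer(pdata[seq_len(npx)])
  } else {
    if (length(pdata) < 2L * npx)
      stop("unreadable DICOM file (truncated PixelData): ", path)
    even <- seq(2L, 2L * npx, by = 2L)
    v <- as.integer(pdata[even - 1L]) + 256L * as.integer(pdata[even])
  }
  if (samples == 1L) {
    px <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  } else {
    ## planar configuration 0 (interleaved) assumed
    px <- array(0L, dim = c(rows, cols, 3L))
    for (ch in 1:3)
      px[, , ch] <- matrix(v[seq(ch, npx, by = 3L)], nrow = rows,
                           ncol = cols, byrow = TRUE)
  }
  if (startsWith(photometric, "MONOCHROME1"))
    px <- (2^bits - 1) - px
  list(pixels = px, bitDepth = as.integer(bits))
}

#' Convert a RawImage to an 8-bit greyscale image
#'
#' RGB samples are combined with the ITU-R BT.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B) and rounded half-up to integers.
#' Single-channel input is passed through; 16-bit input is linearly
#' rescaled onto `[0, 255]` with the byte-scale formula first.
#'
#' @param img a [RawImage-class].
#' @return an unnormalized [GreyImage-class].
#' @export
rgbToGrey <- function(img) {
  stopifnot(is(img, "RawImage"))
  px <- img@pixels
  if (img@bitDepth > 8L) {
    ## rescale each channel jointly onto the byte scale before combining
    fmin <- min(px); fmax <- max(px)
    px <- if (fmax == fmin) array(0, dim(px)) else
      roundHalfUp(255 * (px - fmin) / (fmax - fmin))
  }
  if (img@channels == 3L) {
    grey <- roundHalfUp(0.299 * px[, , 1] + 0.587 * px[, , 2] +
                        0.114 * px[, , 3])
  } else {
    grey <- if (length(dim(px)) == 3L) px[, , 1, drop = TRUE] else px
  }
  GreyImage(pmin(pmax(grey, 0), 255), normalized = FALSE,
            plane = img@plane, sourceId = img@sourceId)
}

#' Byte-scale ("grey-level stretching") normalization
#'
#' Linearly stretches the image so its intensities fill the whole display
#' range: `G_i = round(T * (f_i - f_min) / (f_max - f_min))` with `T = 255`
#' and `f_min`, `f_max` the per-image minimum and maximum (rounding is
#' half-up). A non-constant image therefore attains exactly 0 and 255 after
#' normalization. A constant image (`f_max == f_min`) maps to all zeros with
#' a warning rather than an error, so batch runs survive degenerate frames.
#'
#' The stretch is idempotent: a normalized image is its own fixed point
#' (its range already spans 0-255), so re-applying it returns the input
#' unchanged.
#'
#' @param img a [GreyImage-class].
#' @return the normalized [GreyImage-class].
#' @export
byteScaleNormalize <- function(img) {
  stopifnot(is(img, "GreyImage"))
  if (img@normalized) return(img)
  f <- img@pixels
  fmin <- min(f); fmax <- max(f)
  if (fmax == fmin) {
    warning("constant image (f_max == f_min); output set to all zeros: ",
            img@sourceId)
    g <- matrix(0, nrow(f), ncol(f))
  } else {
    g <- roundHalfUp(255 * (f - fmin) / (fmax - fmin))
  }
  GreyImage(g, normalized = TRUE, plane = img@plane, sourceId = img@sourceId)
}

#' Write a GreyImage as an 8-bit grey PNG
#'
#' The round trip through [readUltrasound()] + [rgbToGrey()] restores the
#' pixel matrix bit-for-bit.
#'
#' @param img a [GreyImage-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGreyPNG <- function(img, path) {
  stopifnot(is(img, "GreyImage"))
  png::writePNG(img@pixels / 255, target = path)
  invisible(path)
}

#' Read an image manifest
#'
#' A manifest CSV lists the ultrasonograms of a study, one row per image,
#' with columns `bird_id`, `group`, `plane`, `path`. Relative paths are
#' resolved against the manifest's own directory.
#'
#' @param path manifest CSV path.
#' @return a data.frame with columns `bird_id`, `group`, `plane`, `path`.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("bird_id", "group", "plane", "path")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  bad <- !(m$plane %in% VALID_PLANES)
  if (any(bad))
    stop("invalid plane label(s) in manifest: ",
         paste(unique(m$plane[bad]), collapse = ", "))
  rel <- !file.exists(m$path) & !grepl("^/", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}
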