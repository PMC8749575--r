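# Fixture builders and independent (naive) oracles used across the suite.
# All binary fixtures are written to tempdir() at test time.

constImage <- function(value, nr = 64, nc = 64, ...) {
  GreyImage(matrix(value, nr, nc), ...)
}

randomGreyImage <- function(nr = 64, nc = 64, lo = 0, hi = 255) {
  GreyImage(matrix(sample(lo:hi, nr * nc, replace = TRUE), nr, nc))
}

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# Minimal explicit-VR little-endian DICOM writer for test fixtures.
# pixels: matrix (grey) or rows x cols x 3 array (RGB, interleaved).
writeTestDicom <- function(path, pixels, bits = 8,
                           photometric = if (length(dim(pixels)) == 3)
                             "RGB" else "MONOCHROME2",
                           nFrames = NULL) {
  elem <- function(group, element, vr, value) {
    hdr <- c(u16le(group), u16le(element), charToRaw(vr))
    if (vr %in% c("OB", "OW")) {
      c(hdr, as.raw(c(0, 0)), u32le(length(value)), value)
    } else {
      c(hdr, u16le(length(value)), value)
    }
  }
  evenStr <- function(s) {
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    charToRaw(s)
  }
  d <- dim(pixels)
  samples <- if (length(d) == 3) 3L else 1L
  if (samples == 1L) {
    v <- as.integer(t(pixels))                      # row-major
  } else {
    v <- as.integer(aperm(pixels, c(3, 2, 1)))      # interleaved row-major
  }
  pdata <- if (bits == 8) as.raw(v) else
    as.raw(as.vector(rbind(v %% 256, v %/% 256)))
  body <- c(
    elem(0x0028, 0x0002, "US", u16le(samples)),
    elem(0x0028, 0x0004, "CS", evenStr(photometric)),
    if (!is.null(nFrames)) elem(0x0028, 0x0008, "IS",
                                evenStr(as.character(nFrames))),
    elem(0x0028, 0x0010, "US", u16le(d[1])),
    elem(0x0028, 0x0011, "US", u16le(d[2])),
    elem(0x0028, 0x0100, "US", u16le(bits)),
    elem(0x7FE0, 0x0010, "OW", pdata)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# Minimal 24-bit uncompressed bottom-up BMP writer (rows padded to 4 bytes).
writeTestBmp <- function(path, rgb) {
  d <- dim(rgb)
  h <- d[1]; w <- d[2]
  rowBytes <- ((w * 3) %/% 4 + as.integer((w * 3) %% 4 > 0)) * 4
  pix <- raw(rowBytes * h)
  for (r in seq_len(h)) {
    src <- h - r + 1                               # bottom-up
    triple <- as.vector(rbind(rgb[src, , 3], rgb[src, , 2], rgb[src, , 1]))
    pix[(r - 1) * rowBytes + seq_along(triple)] <- as.raw(triple)
  }
  hdr <- c(charToRaw("BM"), u32le(54 + length(pix)), u32le(0), u32le(54),
           u32le(40), u32le(w), u32le(h), u16le(1), u16le(24), u32le(0),
           u32le(length(pix)), u32le(2835), u32le(2835), u32le(0), u32le(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(hdr, pix), con)
  invisible(path)
}

# Brute-force oracle: every pixel of the image, one distance test at a time.
naiveSpotStats <- function(img, centers, diameter, mphMode = "per-spot") {
  px <- pixels(img)
  r <- diameter / 2
  means <- numeric(nrow(centers)); sds <- numeric(nrow(centers))
  for (s in seq_len(nrow(centers))) {
    vals <- c()
    r0 <- max(1, floor(centers[s, 1] - r)); r1 <- min(nrow(px), ceiling(centers[s, 1] + r))
    c0 <- max(1, floor(centers[s, 2] - r)); c1 <- min(ncol(px), ceiling(centers[s, 2] + r))
    for (i in r0:r1) for (j in c0:c1) {
      if (sqrt((i - centers[s, 1])^2 + (j - centers[s, 2])^2) < r)
        vals <- c(vals, px[i, j])
    }
    means[s] <- mean(vals)
    sds[s] <- sqrt(sum((vals - mean(vals))^2) / (length(vals) - 1))
  }
  mph <- if (mphMode == "per-spot") mean(sds) else
    sqrt(sum((means - mean(means))^2) / (length(means) - 1))
  list(mpi = mean(means), mph = mph)
}

# Textbook-formula Pearson oracle, written against sums rather than stats::.
naivePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  slope <- sxy / sxx
  list(r = r, slope = slope, intercept = my - slope * mx)
}

# Writes a tiny study of constant-valued PNGs and returns its manifest.
writeConstantStudy <- function(dir, nPerGroup = 3, value = 42, nr = 90,
                               nc = 90) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  k <- 0
  for (g in c("C", "Exp1", "Exp2")) for (b in seq_len(nPerGroup))
    for (pl in c("L", "T", "O1", "O2")) {
      k <- k + 1
      id <- sprintf("%s_%02d", g, b)
      f <- file.path(dir, sprintf("%s_%s.png", id, pl))
      png::writePNG(matrix(value / 255, nr, nc), f)
      rows[[k]] <- data.frame(bird_id = id, group = g, plane = pl, path = f,
                              stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}
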