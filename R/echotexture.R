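#' Construct a SpotSet
#'
#' @param centers numeric 4 x 2 matrix of `(row, col)` spot centers
#'   (1-based pixel coordinates).
#' @param diameter common spot diameter in pixels (default 33, the
#'   conventional spot-meter size for muscle echotexture).
#' @return a [SpotSet-class].
#' @export
SpotSet <- function(centers, diameter = 33) {
  centers <- as.matrix(centers)
  dimnames(centers) <- NULL
  new("SpotSet", centers = centers, diameter = as.numeric(diameter))
}

spotInBounds <- function(center, diameter, nrow, ncol) {
  r <- diameter / 2
  center[1] - r >= 0.5 && center[1] + r <= nrow + 0.5 &&
    center[2] - r >= 0.5 && center[2] + r <= ncol + 0.5
}

assertSpotsInside <- function(img, spots) {
  px <- pixels(img)
  ctr <- spotCenters(spots)
  for (i in seq_len(nrow(ctr))) {
    if (!spotInBounds(ctr[i, ], spotDiameter(spots), nrow(px), ncol(px)))
      stop(sprintf(
        "spot %d at (%g, %g) with diameter %g exceeds the %d x %d image bounds",
        i, ctr[i, 1], ctr[i, 2], spotDiameter(spots), nrow(px), ncol(px)))
  }
  invisible(TRUE)
}

#' Default 2 x 2 spot-meter layout
#'
#' Places the four spot meters on a 2 x 2 grid centered at `anchor`:
#' centers at `anchor +/- spacing/2` in each direction. Spot positions
#' are a free choice of the analyst (they are normally placed manually
#' inside homogeneous muscle parenchyma); this layout is a reproducible
#' convenience anchored at the image center by default.
#'
#' @param img a [GreyImage-class].
#' @param anchor `(row, col)` grid center; defaults to the image center.
#' @param spacing center-to-center distance in pixels; must exceed
#'   `diameter` so circles stay strictly non-overlapping.
#' @param diameter spot diameter in pixels.
#' @return a [SpotSet-class] whose circles all lie inside the image.
#' @export
defaultSpotLayout <- function(img, anchor = NULL, spacing = 40, diameter = 33) {
  stopifnot(is(img, "GreyImage"))
  px <- pixels(img)
  if (is.null(anchor))
    anchor <- c((nrow(px) + 1) / 2, (ncol(px) + 1) / 2)
  if (anchor[1] < 1 || anchor[1] > nrow(px) ||
      anchor[2] < 1 || anchor[2] > ncol(px))
    stop("anchor lies outside the image")
  if (spacing <= diameter)
    stop(sprintf(
      "spacing (%g) must exceed the diameter (%g): tangent or overlapping circles are invalid",
      spacing, diameter))
  h <- spacing / 2
  centers <- rbind(
    anchor + c(-h, -h), anchor + c(-h, h),
    anchor + c( h, -h), anchor + c( h, h))
  for (i in 1:4) {
    if (!spotInBounds(centers[i, ], diameter, nrow(px), ncol(px)))
      stop(sprintf(
        "layout leaves the image bounds: spot %d at (%g, %g), diameter %g, image %d x %d",
        i, centers[i, 1], centers[i, 2], diameter, nrow(px), ncol(px)))
  }
  SpotSet(centers, diameter)
}

diskOffsets <- function(center, diameter) {
  r <- diameter / 2
  rr <- floor(r)
  rows <- (floor(center[1]) - rr - 1L):(ceiling(center[1]) + rr + 1L)
  cols <- (floor(center[2]) - rr - 1L):(ceiling(center[2]) + rr + 1L)
  grid <- expand.grid(col = cols, row = rows)       # row-major order
  d2 <- (grid$row - center[1])^2 + (grid$col - center[2])^2
  keep <- d2 < r^2                                   # strictly inside
  cbind(row = grid$row[keep], col = grid$col[keep])
}

#' Pixel values inside one circular spot meter
#'
#' Returns the intensities of all pixels whose centers lie strictly within
#' `diameter / 2` (Euclidean distance) of the spot center, in deterministic
#' row-major order (left to right within each row, top row first).
#'
#' @param img a [GreyImage-class].
#' @param center `(row, col)` spot center.
#' @param diameter spot diameter in pixels.
#' @return numeric vector of pixel intensities.
#' @export
spotPixelValues <- function(img, center, diameter = 33) {
  stopifnot(is(img, "GreyImage"))
  px <- pixels(img)
  if (!spotInBounds(center, diameter, nrow(px), ncol(px)))
    stop(sprintf("spot at (%g, %g) with diameter %g exceeds the %d x %d image bounds",
                 center[1], center[2], diameter, nrow(px), ncol(px)))
  idx <- diskOffsets(center, diameter)
  px[idx]
}

#' Mean pixel intensity (MPI) and pixel heterogeneity (MPH)
#'
#' First-order echotexture statistics over the four spot meters. Per spot,
#' the mean and the sample (n-1) standard deviation of its pixel values are
#' computed; the image-level MPI is the arithmetic mean of the four spot
#' means. For MPH two conventions exist and both are implemented:
#'
#' * `"per-spot"` (default): the mean of the four within-spot sample SDs —
#'   the heterogeneity of the grey levels inside the regions of interest,
#'   matching first-order texture methodology;
#' * `"across-spots"`: the sample SD of the four spot means — the
#'   dispersion between regions.
#'
#' @param img a [GreyImage-class]; the study pipeline normalizes images
#'   (see [byteScaleNormalize()]) before echotexture analysis, but the
#'   statistics are defined for any grey image.
#' @param spots a [SpotSet-class], fully inside the image.
#' @param mphMode `"per-spot"` or `"across-spots"`.
#' @return named list with elements `mpi`, `mph`, and `spotStats`
#'   (data.frame of per-spot `n`, `mean`, `sd`).
#' @export
computeMpiMph <- function(img, spots, mphMode = c("per-spot", "across-spots")) {
  mphMode <- match.arg(mphMode)
  stopifnot(is(img, "GreyImage"), is(spots, "SpotSet"))
  assertSpotsInside(img, spots)
  ctr <- spotCenters(spots)
  dia <- spotDiameter(spots)
  means <- sds <- ns <- numeric(4)
  for (i in 1:4) {
    v <- spotPixelValues(img, ctr[i, ], dia)
    if (length(v) < 2L)
      stop(sprintf("spot %d contains %d pixel(s); at least 2 are needed for the SD",
                   i, length(v)))
    ns[i] <- length(v); means[i] <- mean(v); sds[i] <- stats::sd(v)
  }
  mph <- if (mphMode == "per-spot") mean(sds) else stats::sd(means)
  list(mpi = mean(means), mph = mph,
       spotStats = data.frame(spot = 1:4, n = ns, mean = means, sd = sds))
}

#' Read a spot-placement CSV
#'
#' Columns: `bird_id`, `plane`, `spot_index` (1-4), `center_row`,
#' `center_col`, `diameter`. Coordinates are 1-based pixel positions.
#'
#' @param path CSV path.
#' @return named list of [SpotSet-class] objects, keyed `"<bird_id>:<plane>"`.
#' @export
readSpotsCsv <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("bird_id", "plane", "spot_index", "center_row", "center_col",
           "diameter")
  miss <- setdiff(req, names(s))
  if (length(miss))
    stop("spots CSV lacks column(s): ", paste(miss, collapse = ", "))
  keys <- paste(s$bird_id, s$plane, sep = ":")
  out <- list()
  for (k in unique(keys)) {
    sub <- s[keys == k, ]
    sub <- sub[order(sub$spot_index), ]
    if (nrow(sub) != 4L)
      stop("spot set '", k, "' has ", nrow(sub), " spots; exactly 4 required")
    if (length(unique(sub$diameter)) != 1L)
      stop("spot set '", k, "' mixes diameters; all four must be identical")
    out[[k]] <- SpotSet(cbind(sub$center_row, sub$center_col),
                        diameter = sub$diameter[1])
  }
  out
}

#' Batch echotexture analysis over a study manifest
#'
#' Reads every image in the manifest, converts it to greyscale, optionally
#' applies the byte-scale normalization, and computes MPI/MPH over the
#' image's spot set. Per-row failures (missing file, missing spot set,
#' unreadable image) are collected into a run report and do not abort the
#' batch.
#'
#' @param manifest data.frame as returned by [readManifest()], or a path to
#'   a manifest CSV.
#' @param spots named list of [SpotSet-class] objects keyed
#'   `"<bird_id>:<plane>"` (see [readSpotsCsv()]), a single [SpotSet-class]
#'   applied to every image, or `NULL` to use [defaultSpotLayout()] with
#'   `diameter`.
#' @param diameter spot diameter for the default layout.
#' @param normalize apply [byteScaleNormalize()] before measuring (the
#'   study procedure). Set `FALSE` to measure raw envelope intensities,
#'   e.g. when validating simulator calibration.
#' @param mphMode MPH convention, see [computeMpiMph()].
#' @return data.frame of echotexture records with columns `bird_id`,
#'   `group`, `plane`, `mpi`, `mph`, ordered by (group, bird_id, plane);
#'   failed rows are attached as a data.frame in `attr(, "failures")`.
#' @export
analyzeBatch <- function(manifest, spots = NULL, diameter = 33,
                         normalize = TRUE,
                         mphMode = c("per-spot", "across-spots")) {
  mphMode <- match.arg(mphMode)
  if (is.character(manifest)) manifest <- readManifest(manifest)
  records <- list()
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      raw <- readUltrasound(row$path, plane = row$plane)
      grey <- rgbToGrey(raw)
      if (normalize) grey <- byteScaleNormalize(grey)
      ss <- if (is.null(spots)) {
        defaultSpotLayout(grey, diameter = diameter)
      } else if (is(spots, "SpotSet")) {
        spots
      } else {
        key <- paste(row$bird_id, row$plane, sep = ":")
        if (is.null(spots[[key]]))
          stop("no spot set for '", key, "'")
        spots[[key]]
      }
      st <- computeMpiMph(grey, ss, mphMode = mphMode)
      data.frame(bird_id = row$bird_id, group = row$group, plane = row$plane,
                 mpi = st$mpi, mph = st$mph, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(bird_id = row$bird_id, plane = row$plane, path = row$path,
                   error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  out <- if (length(records)) do.call(rbind, records) else
    data.frame(bird_id = character(), group = character(),
               plane = character(), mpi = numeric(), mph = numeric())
  out <- out[order(out$group, out$bird_id,
                   match(out$plane, VALID_PLANES)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures) else
    data.frame(bird_id = character(), plane = character(), path = character(),
               error = character())
  out
}

#' Group summary of echotexture records
#'
#' Mean and SEM per group for each plane-prefixed echotexture variable
#' (L-MPI, T-MPI, O1-MPI, O2-MPI, L-MPH, ..., O2-MPH), the usual
#' group-comparison table shape.
#'
#' @param records data.frame from [analyzeBatch()] (columns `bird_id`,
#'   `group`, `plane`, `mpi`, `mph`).
#' @return data.frame with columns `variable`, `group`, `n`, `mean`, `sem`.
#' @export
groupSummary <- function(records) {
  rows <- list()
  for (var in c("MPI", "MPH")) {
    col <- tolower(var)
    for (pl in VALID_PLANES) {
      sub <- records[records$plane == pl, ]
      if (nrow(sub) == 0) next
      for (g in unique(sub$group)) {
        v <- sub[[col]][sub$group == g]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = paste0(pl, "-", var), group = g, n = length(v),
          mean = mean(v),
          sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write echotexture records to CSV
#'
#' Columns `bird_id`, `group`, `plane`, `mpi`, `mph`; numeric columns at
#' 6 significant digits.
#'
#' @param records data.frame from [analyzeBatch()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeEchotextureCsv <- function(records, path) {
  out <- records
  out$mpi <- signif(out$mpi, 6)
  out$mph <- signif(out$mph, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
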