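#' Reference trait model (group means and SEMs)
#'
#' The default trait-table generator settings: per-group means and SEMs of
#' the 29 physicochemical, morphometric and sensory characteristics of the
#' reference turkey study (three diet groups, n = 15 birds/group). Sensory
#' traits were scored on a 1 (poor) to 5 (superior) scale in steps of 0.5.
#'
#' @return data.frame with columns `variable`, `type`, `group`, `mean`,
#'   `sem` (long format, one row per variable x group).
#' @export
defaultTraitModel <- function() {
  loadModelCsv("reference_trait_model.csv", hasType = TRUE)
}

#' Reference echotexture model (group means and SEMs)
#'
#' Per-group means and SEMs of the eight plane-prefixed echotexture
#' variables (L/T/O1/O2 x MPI/MPH) of the reference study.
#'
#' @return data.frame with columns `variable`, `group`, `mean`, `sem`.
#' @export
defaultEchoModel <- function() {
  loadModelCsv("reference_echo_model.csv", hasType = FALSE)
}

## zero-padded so lexicographic order equals numeric order at any n
birdIds <- function(group, n) {
  sprintf("%s_%0*d", group, max(2L, nchar(as.character(n))), seq_len(n))
}

loadModelCsv <- function(fname, hasType) {
  path <- system.file("extdata", fname, package = "echotex", mustWork = TRUE)
  w <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  rows <- list()
  for (g in GROUP_LEVELS) {
    d <- data.frame(variable = w$variable, stringsAsFactors = FALSE)
    if (hasType) d$type <- w$type
    d$group <- g
    d$mean <- w[[paste0("mean_", g)]]
    d$sem <- w[[paste0("sem_", g)]]
    rows[[g]] <- d
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference correlation tables
#'
#' The published significant echotexture-trait correlations of the
#' reference study (within-group and pooled screens), with their
#' regression lines. Shipped as reference data for consistency checks;
#' note the within-group table prints one row with p = 0.07.
#'
#' @param which `"within"` (per-group screen) or `"pooled"`.
#' @return data.frame with columns `group`, `input_variable`,
#'   `output_variable`, `r`, `p_value`, `intercept`, `slope`.
#' @export
referenceCorrelations <- function(which = c("within", "pooled")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("reference_correlations_", which, ".csv"),
                      package = "echotex", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## separable circular convolution with a Gaussian kernel, rescaled so an
## i.i.d. input field keeps its marginal variance exactly
smoothAnisotropic <- function(z, sdRow, sdCol) {
  kern <- function(sd) {
    if (sd <= 0) return(1)
    half <- max(1L, ceiling(3 * sd))
    k <- stats::dnorm(-half:half, sd = sd)
    k / sqrt(sum(k^2))
  }
  kr <- kern(sdRow); kc <- kern(sdCol)
  if (length(kr) > 1) {
    if (length(kr) >= nrow(z)) stop("smoothing kernel taller than the image")
    z <- stats::filter(z, kr, method = "convolution", sides = 2,
                       circular = TRUE)
  }
  if (length(kc) > 1) {
    if (length(kc) >= ncol(z)) stop("smoothing kernel wider than the image")
    z <- t(stats::filter(t(z), kc, method = "convolution", sides = 2,
                         circular = TRUE))
  }
  matrix(as.numeric(z), nrow(z), ncol(z))
}

#' Simulate a fully developed speckle ultrasonogram
#'
#' Pixels are the envelope `sqrt(Z1^2 + Z2^2)` of two independent zero-mean
#' Gaussian fields of scale `sigma` — i.e. Rayleigh-distributed amplitudes,
#' the classical model of fully developed speckle — optionally smoothed by
#' an anisotropic Gaussian kernel that elongates the speckle grain along
#' the image columns, emulating the fiber-orientation dependence of muscle
#' echotexture across scanning planes. Smoothing is applied to the Gaussian
#' fields and renormalized, so the Rayleigh marginal distribution (mean
#' `sigma * sqrt(pi/2)`, SD `sigma * sqrt(2 - pi/2)`) is preserved exactly.
#' Values are rounded half-up and clamped to `[0, 255]`; a warning is
#' raised when more than 1% of pixels clamp.
#'
#' @param sigma Rayleigh scale in grey levels (> 0).
#' @param size `(rows, cols)`, at least `(64, 64)`.
#' @param anisotropy smoothing-kernel aspect ratio >= 1; 1 (default) means
#'   no smoothing, values > 1 smooth with kernel SDs `(1, anisotropy)`
#'   pixels in the (row, column) directions.
#' @param seed optional integer seed; a fixed seed gives bit-identical
#'   images.
#' @param plane optional scanning-plane label carried into the image.
#' @param sourceId provenance string.
#' @return a [GreyImage-class] (not normalized).
#' @export
simulateSpeckleImage <- function(sigma, size = c(480, 640), anisotropy = 1,
                                 seed = NULL, plane = NA_character_,
                                 sourceId = "speckle-sim") {
  stopifnot(sigma > 0, length(size) == 2, all(size >= 64), anisotropy >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- size[1] * size[2]
  z1 <- matrix(stats::rnorm(n, 0, sigma), size[1], size[2])
  z2 <- matrix(stats::rnorm(n, 0, sigma), size[1], size[2])
  if (anisotropy > 1) {
    z1 <- smoothAnisotropic(z1, 1, anisotropy)
    z2 <- smoothAnisotropic(z2, 1, anisotropy)
  }
  env <- sqrt(z1^2 + z2^2)
  px <- roundHalfUp(env)
  nClamp <- sum(px > 255)
  if (nClamp > 0.01 * n)
    warning(sprintf(
      "sigma = %g clamps %.1f%% of pixels at 255; envelope statistics are distorted",
      sigma, 100 * nClamp / n))
  GreyImage(pmin(px, 255), normalized = FALSE, plane = plane,
            sourceId = sourceId)
}

#' Calibrate the Rayleigh scale for a target mean pixel intensity
#'
#' Inverts the Rayleigh mean, `E[amplitude] = sigma * sqrt(pi/2)`, so that
#' unsmoothed, unclamped simulated images have expected spot-meter mean
#' equal to `targetMpi` (raw envelope intensities, i.e. before any
#' byte-scale display normalization).
#'
#' @param targetMpi target mean grey level, strictly between 0 and 255.
#' @return the Rayleigh scale `sigma = targetMpi / sqrt(pi/2)`.
#' @export
calibrateSigma <- function(targetMpi) {
  if (!is.numeric(targetMpi) || length(targetMpi) != 1 ||
      targetMpi <= 0 || targetMpi >= 255)
    stop("targetMpi must lie strictly between 0 and 255")
  sigma <- targetMpi / sqrt(pi / 2)
  pClamp <- exp(-255^2 / (2 * sigma^2))
  if (pClamp > 0.01)
    warning(sprintf(
      "target MPI %g implies heavy clamping at 255 (expected fraction %.2f)",
      targetMpi, pClamp))
  sigma
}

#' Simulate a study trait table with matched echotexture records
#'
#' Draws, per bird, a latent multivariate-normal vector covering the eight
#' echotexture variables and all traits, with unit variances and the
#' requested echotexture-trait cross-correlations planted (all other
#' variables independent — the reference study reports no within-group
#' covariances). Each variable is then mapped onto its group scale,
#' `mean + SD * z`, with `SD = SEM * sqrt(nStudy)` reconstructed from the
#' printed standard errors. Sensory traits are snapped to the 0.5-step
#' scoring grid and clipped to `[1, 5]` after correlation planting, so grid
#' attenuation is part of the simulated measurement process. Echotexture
#' values are clamped to their physical ranges (`[0, 255]` for MPI,
#' non-negative for MPH).
#'
#' @param nPerGroup birds per group (>= 3).
#' @param traitModel long data.frame (`variable`, `type`, `group`, `mean`,
#'   `sem`); default [defaultTraitModel()].
#' @param echoModel long data.frame (`variable`, `group`, `mean`, `sem`);
#'   default [defaultEchoModel()].
#' @param targetCorrelations `NULL`, or a data.frame with columns
#'   `input_variable` (echotexture variable, e.g. `"L-MPH"`),
#'   `output_variable` (trait) and `r` (|r| < 1).
#' @param seed optional integer master seed; groups are drawn in the fixed
#'   order C, Exp1, Exp2, one latent matrix per group, so a fixed seed
#'   gives bit-identical tables.
#' @param nStudy the sample size whose SEMs the model tabulates (15 for the
#'   shipped reference models); `SD = SEM * sqrt(nStudy)` regardless of
#'   `nPerGroup`.
#' @return list with `traits` (wide data.frame: `bird_id`, `group`, one
#'   column per trait) and `echo` (long records: `bird_id`, `group`,
#'   `plane`, `mpi`, `mph`).
#' @export
simulateTraitTable <- function(nPerGroup = 15, traitModel = defaultTraitModel(),
                               echoModel = defaultEchoModel(),
                               targetCorrelations = NULL, seed = NULL,
                               nStudy = 15) {
  stopifnot(nPerGroup >= 3)
  if (!is.null(seed)) set.seed(seed)
  echoVars <- unique(echoModel$variable)
  traitVars <- unique(traitModel$variable)
  allVars <- c(echoVars, traitVars)
  p <- length(allVars)

  Sigma <- diag(p)
  if (!is.null(targetCorrelations) && nrow(targetCorrelations) > 0) {
    for (k in seq_len(nrow(targetCorrelations))) {
      xv <- targetCorrelations$input_variable[k]
      yv <- targetCorrelations$output_variable[k]
      r <- targetCorrelations$r[k]
      if (!(xv %in% echoVars))
        stop("unknown echotexture variable in target correlation: ", xv)
      if (!(yv %in% traitVars))
        stop("unknown trait in target correlation: ", yv)
      if (abs(r) >= 1)
        stop(sprintf("target correlation (%s, %s, r = %g) must satisfy |r| < 1",
                     xv, yv, r))
      i <- match(xv, allVars); j <- match(yv, allVars)
      Sigma[i, j] <- Sigma[j, i] <- r
    }
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      trip <- apply(targetCorrelations, 1, function(z)
        sprintf("(%s, %s, r = %s)", z[["input_variable"]],
                z[["output_variable"]], z[["r"]]))
      stop("requested correlation set is not positive semi-definite: ",
           paste(trip, collapse = ", "))
    }
  }
  L <- tryCatch(chol(Sigma), error = function(e) {
    ## PSD but singular: eigen square root
    ed <- eigen(Sigma, symmetric = TRUE)
    t(ed$vectors %*% diag(sqrt(pmax(ed$values, 0))))
  })

  sensory <- if ("type" %in% names(traitModel))
    unique(traitModel$variable[traitModel$type == "sensory"]) else character()

  traitRows <- list(); echoRows <- list()
  for (g in GROUP_LEVELS) {
    Z <- matrix(stats::rnorm(nPerGroup * p), nPerGroup, p) %*% L
    colnames(Z) <- allVars
    ids <- birdIds(g, nPerGroup)

    tm <- traitModel[traitModel$group == g, ]
    td <- data.frame(bird_id = ids, group = g, stringsAsFactors = FALSE)
    for (v in traitVars) {
      mu <- tm$mean[tm$variable == v]
      sdv <- tm$sem[tm$variable == v] * sqrt(nStudy)
      val <- mu + sdv * Z[, v]
      if (v %in% sensory)
        val <- pmin(5, pmax(1, roundHalfUp(val * 2) / 2))
      td[[v]] <- val
    }
    traitRows[[g]] <- td

    em <- echoModel[echoModel$group == g, ]
    eg <- list()
    for (pl in VALID_PLANES) {
      mpiV <- paste0(pl, "-MPI"); mphV <- paste0(pl, "-MPH")
      mpiMu <- em$mean[em$variable == mpiV]
      mpiSd <- em$sem[em$variable == mpiV] * sqrt(nStudy)
      mphMu <- em$mean[em$variable == mphV]
      mphSd <- em$sem[em$variable == mphV] * sqrt(nStudy)
      eg[[pl]] <- data.frame(
        bird_id = ids, group = g, plane = pl,
        mpi = pmin(255, pmax(0, mpiMu + mpiSd * Z[, mpiV])),
        mph = pmax(0, mphMu + mphSd * Z[, mphV]),
        stringsAsFactors = FALSE)
    }
    echoRows[[g]] <- do.call(rbind, eg)
  }
  traits <- do.call(rbind, traitRows)
  echo <- do.call(rbind, echoRows)
  echo <- echo[order(echo$group, echo$bird_id,
                     match(echo$plane, VALID_PLANES)), ]
  rownames(traits) <- rownames(echo) <- NULL
  list(traits = traits, echo = echo)
}

#' Simulate a complete study on disk
#'
#' Writes everything [runAnalyze()] consumes: one speckle PNG per bird and
#' scanning plane (Rayleigh scale calibrated per group x plane so raw
#' envelope spot means match the echotexture model's MPI targets, with
#' plane-specific anisotropic smoothing), a manifest CSV, a spot-placement
#' CSV (2 x 2 default layout at each image center), the trait table CSV,
#' and the statistically calibrated echotexture record CSV from
#' [simulateTraitTable()] (the table route carries any planted
#' echotexture-trait correlations; image-derived records are independent of
#' the traits by construction).
#'
#' Random-number contract: the trait/echo tables use the master `seed`;
#' image `i` (in manifest order) uses `seed + 1000 + i`.
#'
#' @param outDir output directory (created if needed).
#' @param nPerGroup birds per group.
#' @param size image `(rows, cols)`; default the scanner resolution
#'   480 x 640.
#' @param diameter,spacing spot-meter layout parameters.
#' @param anisotropy named vector of smoothing aspect ratios per plane.
#' @param targetCorrelations planted correlations, see
#'   [simulateTraitTable()].
#' @param traitModel,echoModel generator models (defaults: the reference
#'   study tables).
#' @param seed integer master seed.
#' @return invisible list of the written paths (`manifest`, `spots`,
#'   `traits`, `echoTable`, `imageDir`).
#' @export
simulateStudy <- function(outDir, nPerGroup = 15, size = c(480, 640),
                          diameter = 33, spacing = 40,
                          anisotropy = c(L = 3, T = 1, O1 = 1.5, O2 = 2.5),
                          targetCorrelations = NULL,
                          traitModel = defaultTraitModel(),
                          echoModel = defaultEchoModel(), seed = 1) {
  stopifnot(nPerGroup >= 3)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  imgDir <- file.path(outDir, "images")
  dir.create(imgDir, showWarnings = FALSE)

  tab <- simulateTraitTable(nPerGroup = nPerGroup, traitModel = traitModel,
                            echoModel = echoModel,
                            targetCorrelations = targetCorrelations,
                            seed = seed)
  traitPath <- file.path(outDir, "traits.csv")
  utils::write.csv(tab$traits, traitPath, row.names = FALSE, quote = FALSE)
  echoTablePath <- file.path(outDir, "echo_table.csv")
  utils::write.csv(tab$echo, echoTablePath, row.names = FALSE, quote = FALSE)

  manifest <- list(); spotsRows <- list()
  anchor <- c((size[1] + 1) / 2, (size[2] + 1) / 2)
  h <- spacing / 2
  centers <- rbind(anchor + c(-h, -h), anchor + c(-h, h),
                   anchor + c(h, -h), anchor + c(h, h))
  idx <- 0L
  for (g in GROUP_LEVELS) {
    em <- echoModel[echoModel$group == g, ]
    for (b in seq_len(nPerGroup)) {
      id <- birdIds(g, nPerGroup)[b]
      for (pl in VALID_PLANES) {
        idx <- idx + 1L
        sigma <- calibrateSigma(em$mean[em$variable == paste0(pl, "-MPI")])
        img <- simulateSpeckleImage(sigma, size = size,
                                    anisotropy = unname(anisotropy[pl]),
                                    seed = seed + 1000L + idx, plane = pl,
                                    sourceId = sprintf("%s_%s", id, pl))
        fname <- sprintf("%s_%s.png", id, pl)
        writeGreyPNG(img, file.path(imgDir, fname))
        manifest[[idx]] <- data.frame(
          bird_id = id, group = g, plane = pl,
          path = file.path("images", fname), stringsAsFactors = FALSE)
        spotsRows[[idx]] <- data.frame(
          bird_id = id, plane = pl, spot_index = 1:4,
          center_row = centers[, 1], center_col = centers[, 2],
          diameter = diameter, stringsAsFactors = FALSE)
      }
    }
  }
  manifestPath <- file.path(outDir, "manifest.csv")
  utils::write.csv(do.call(rbind, manifest), manifestPath,
                   row.names = FALSE, quote = FALSE)
  spotsPath <- file.path(outDir, "spots.csv")
  utils::write.csv(do.call(rbind, spotsRows), spotsPath,
                   row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifestPath, spots = spotsPath,
                 traits = traitPath, echoTable = echoTablePath,
                 imageDir = imgDir))
}
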