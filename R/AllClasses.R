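#' @import methods
NULL

VALID_PLANES <- c("L", "T", "O1", "O2")
GROUP_LEVELS <- c("C", "Exp1", "Exp2")

#' RawImage: an ultrasonogram as read from its container
#'
#' Holds the original integer sample values of a B-mode ultrasonogram prior
#' to greyscale conversion, together with container metadata and the
#' scanning-plane label (L = longitudinal, T = transverse, O1/O2 = oblique;
#' the plane is defined by the transducer orientation relative to the
#' sternum/keel axis).
#'
#' Pixel coordinates throughout the package are 1-based `(row, col)`.
#'
#' @slot pixels integer array; `rows x cols` for single-channel images or
#'   `rows x cols x 3` for RGB.
#' @slot channels integer, 1 (grey) or 3 (RGB).
#' @slot bitDepth integer, bits per sample (8 or 16).
#' @slot sourceId character, free-text provenance (usually the file name).
#' @slot plane character, one of `"L"`, `"T"`, `"O1"`, `"O2"`, or `NA` when
#'   unlabeled.
#' @name RawImage-class
#' @aliases RawImage-class
#' @exportClass RawImage
setClass("RawImage",
  representation(
    pixels   = "array",
    channels = "integer",
    bitDepth = "integer",
    sourceId = "character",
    plane    = "character"
  )
)

setValidity("RawImage", function(object) {
  d <- dim(object@pixels)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    return("pixels must be a 2-D or 3-D array")
  if (any(d[1:2] < 1L))
    return("pixels must be non-empty")
  if (!(object@channels %in% c(1L, 3L)))
    return("channels must be 1 or 3")
  if (length(d) == 3L && d[3] != object@channels)
    return("third dimension of pixels must equal channels")
  if (length(d) == 2L && object@channels != 1L)
    return("2-D pixels imply channels = 1")
  if (!(object@bitDepth %in% c(8L, 16L)))
    return("bitDepth must be 8 or 16")
  px <- object@pixels
  if (anyNA(px)) return("pixels must not contain NA")
  if (min(px) < 0 || max(px) > 2^object@bitDepth - 1)
    return(sprintf("sample values must lie in [0, %d]", 2^object@bitDepth - 1))
  if (!is.na(object@plane) && !(object@plane %in% VALID_PLANES))
    return("plane must be one of L, T, O1, O2 or NA")
  TRUE
})

#' GreyImage: an 8-bit greyscale ultrasonogram
#'
#' A single-channel pixel matrix with intensities on the display scale
#' 0 (absolute black) to 255 (absolute white), with provenance, the
#' scanning-plane label, and a flag recording whether the byte-scale
#' (histogram stretching) normalization has been applied.
#'
#' @slot pixels numeric matrix of whole numbers in `[0, 255]` (rows x cols).
#' @slot normalized logical; `TRUE` after [byteScaleNormalize()].
#' @slot plane character scanning-plane label or `NA`.
#' @slot sourceId character provenance.
#' @name GreyImage-class
#' @aliases GreyImage-class
#' @exportClass GreyImage
setClass("GreyImage",
  representation(
    pixels     = "matrix",
    normalized = "logical",
    plane      = "character",
    sourceId   = "character"
  )
)

setValidity("GreyImage", function(object) {
  px <- object@pixels
  if (!is.numeric(px) || length(px) == 0L)
    return("pixels must be a non-empty numeric matrix")
  if (anyNA(px)) return("pixels must not contain NA")
  if (min(px) < 0 || max(px) > 255)
    return("pixel intensities must lie in [0, 255]")
  if (any(px != round(px)))
    return("pixel intensities must be whole numbers")
  if (length(object@normalized) != 1L || is.na(object@normalized))
    return("normalized must be TRUE or FALSE")
  if (object@normalized && min(px) != max(px) &&
      (min(px) != 0 || max(px) != 255))
    return("a normalized non-constant image must attain both 0 and 255")
  if (!is.na(object@plane) && !(object@plane %in% VALID_PLANES))
    return("plane must be one of L, T, O1, O2 or NA")
  TRUE
})

#' SpotSet: four identical non-overlapping circular spot meters
#'
#' The echotexture region-of-interest layout: exactly four circular spot
#' meters of identical diameter (default 33 pixels) whose pairwise
#' center distances strictly exceed the diameter, so the circles never
#' touch or overlap.
#'
#' @slot centers numeric 4 x 2 matrix of `(row, col)` centers (1-based).
#' @slot diameter numeric, the common spot diameter in pixels (>= 3).
#' @name SpotSet-class
#' @aliases SpotSet-class
#' @exportClass SpotSet
setClass("SpotSet",
  representation(centers = "matrix", diameter = "numeric")
)

setValidity("SpotSet", function(object) {
  ctr <- object@centers
  if (!is.numeric(ctr) || !identical(dim(ctr), c(4L, 2L)))
    return("centers must be a numeric 4 x 2 matrix (one (row, col) per spot)")
  if (anyNA(ctr)) return("centers must not contain NA")
  if (length(object@diameter) != 1L || is.na(object@diameter) ||
      object@diameter < 3)
    return("diameter must be a single number >= 3")
  d <- as.matrix(stats::dist(ctr))
  mind <- min(d[upper.tri(d)])
  if (mind <= object@diameter)
    return(sprintf(
      "spots overlap or touch: minimum center distance %.3f must exceed the diameter %g",
      mind, object@diameter))
  TRUE
})

#' ScreenResult: the outcome of a correlation screen
#'
#' One row per (echotexture variable, trait) pair actually tested, with the
#' Pearson coefficient, two-tailed p-value, least-squares regression line,
#' formatted equation string and Guilford strength label, plus the
#' candidate-correlation bookkeeping: the nominal number of possible
#' candidates, the number of pairs actually tested, the number significant
#' at `alpha`, and the percentage `100 * significant / possible` rounded to
#' one decimal.
#'
#' @slot results data.frame of all tested pairs (columns `group`,
#'   `input_variable`, `output_variable`, `r`, `p_value`, `slope`,
#'   `intercept`, `n`, `equation`, `strength_label`, `significant`).
#' @slot alpha numeric significance threshold.
#' @slot possible integer nominal candidate count ([countCandidates()]).
#' @slot performed integer number of pairs actually tested.
#' @slot nSignificant integer number of pairs with `p < alpha`.
#' @slot percentage numeric, `100 * nSignificant / possible`, one decimal.
#' @slot pooled logical; `TRUE` when groups were pooled before screening.
#' @slot skipped data.frame of (group, variable) pairs skipped for zero
#'   variance.
#' @name ScreenResult-class
#' @aliases ScreenResult-class
#' @exportClass ScreenResult
setClass("ScreenResult",
  representation(
    results      = "data.frame",
    alpha        = "numeric",
    possible     = "integer",
    performed    = "integer",
    nSignificant = "integer",
    percentage   = "numeric",
    pooled       = "logical",
    skipped      = "data.frame"
  )
)

setValidity("ScreenResult", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must lie strictly between 0 and 1")
  if (object@nSignificant > object@possible)
    return("significant correlations cannot exceed the possible candidates")
  if (nrow(object@results) > 0) {
    if (any(abs(object@results$r) > 1 + 1e-12))
      return("|r| must not exceed 1")
    if (any(object@results$p_value < 0 | object@results$p_value > 1))
      return("p-values must lie in [0, 1]")
  }
  TRUE
})

#' AnovaResult: a group-comparison analysis
#'
#' Main-effect F statistics and p-values plus pairwise post-hoc comparisons
#' (Tukey HSD or LSD) and a compact letter display per factor, following the
#' a/b/c superscript convention of group-mean tables (letter "a" attaches to
#' the largest mean; levels sharing a letter do not differ at `alpha`).
#'
#' @slot terms data.frame with columns `term`, `df`, `F`, `p`.
#' @slot pairwise data.frame with columns `term`, `level1`, `level2`,
#'   `estimate`, `p` (Tukey-adjusted or plain LSD p-values).
#' @slot letters named list; per factor a named character vector of letters.
#' @slot means named list; per factor a named numeric vector of level means.
#' @slot method character, `"tukey"` or `"lsd"`.
#' @slot alpha numeric significance threshold used for the letters.
#' @slot residualDf numeric residual degrees of freedom.
#' @name AnovaResult-class
#' @aliases AnovaResult-class
#' @exportClass AnovaResult
setClass("AnovaResult",
  representation(
    terms      = "data.frame",
    pairwise   = "data.frame",
    letters    = "list",
    means      = "list",
    method     = "character",
    alpha      = "numeric",
    residualDf = "numeric"
  )
)

setValidity("AnovaResult", function(object) {
  if (nrow(object@terms) > 0 && any(object@terms$F < 0, na.rm = TRUE))
    return("F statistics must be non-negative")
  if (!(object@method %in% c("tukey", "lsd")))
    return("method must be 'tukey' or 'lsd'")
  TRUE
})
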