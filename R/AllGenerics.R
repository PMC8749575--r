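#' Accessors for image and result objects
#'
#' Slot access for the package's S4 containers goes through these accessor
#' generics; user code should never reach into slots directly.
#'
#' @param x an object of the documented class.
#' @return see the individual accessor descriptions.
#' @name accessors
NULL

#' @describeIn accessors the pixel matrix/array of a [RawImage-class] or
#'   [GreyImage-class].
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @describeIn accessors the scanning-plane label (`"L"`, `"T"`, `"O1"`,
#'   `"O2"` or `NA`).
#' @export
setGeneric("imagePlane", function(x) standardGeneric("imagePlane"))

#' @describeIn accessors free-text provenance (usually the source file name).
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @describeIn accessors `TRUE` once the byte-scale normalization has been
#'   applied to a [GreyImage-class].
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @describeIn accessors the 4 x 2 matrix of spot centers of a
#'   [SpotSet-class].
#' @export
setGeneric("spotCenters", function(x) standardGeneric("spotCenters"))

#' @describeIn accessors the common spot diameter (pixels) of a
#'   [SpotSet-class].
#' @export
setGeneric("spotDiameter", function(x) standardGeneric("spotDiameter"))

#' @describeIn accessors all tested (echotexture variable, trait) rows of a
#'   [ScreenResult-class].
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))

#' @describeIn accessors only the rows of a [ScreenResult-class] significant
#'   at its `alpha`.
#' @export
setGeneric("significantCorrelations",
           function(x) standardGeneric("significantCorrelations"))

#' @describeIn accessors candidate-correlation bookkeeping of a
#'   [ScreenResult-class]: named vector with `possible`, `performed`,
#'   `significant` and `percentage`.
#' @export
setGeneric("screenCounts", function(x) standardGeneric("screenCounts"))

#' @describeIn accessors the main-effect table (`term`, `df`, `F`, `p`) of an
#'   [AnovaResult-class].
#' @export
setGeneric("anovaTerms", function(x) standardGeneric("anovaTerms"))

#' @describeIn accessors the pairwise post-hoc table of an
#'   [AnovaResult-class].
#' @export
setGeneric("pairwiseComparisons",
           function(x) standardGeneric("pairwiseComparisons"))

#' @describeIn accessors the compact letter display(s) of an
#'   [AnovaResult-class] (named list, one character vector per factor).
#' @export
setGeneric("letterDisplay", function(x) standardGeneric("letterDisplay"))
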