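#' @rdname accessors
#' @export
setMethod("pixels", "RawImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixels", "GreyImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("imagePlane", "RawImage", function(x) x@plane)

#' @rdname accessors
#' @export
setMethod("imagePlane", "GreyImage", function(x) x@plane)

#' @rdname accessors
#' @export
setMethod("sourceId", "RawImage", function(x) x@sourceId)

#' @rdname accessors
#' @export
setMethod("sourceId", "GreyImage", function(x) x@sourceId)

#' @rdname accessors
#' @export
setMethod("isNormalized", "GreyImage", function(x) x@normalized)

#' @rdname accessors
#' @export
setMethod("spotCenters", "SpotSet", function(x) x@centers)

#' @rdname accessors
#' @export
setMethod("spotDiameter", "SpotSet", function(x) x@diameter)

#' @rdname accessors
#' @export
setMethod("screenTable", "ScreenResult", function(x) x@results)

#' @rdname accessors
#' @export
setMethod("significantCorrelations", "ScreenResult", function(x) {
  x@results[x@results$significant, , drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("screenCounts", "ScreenResult", function(x) {
  c(possible    = x@possible,
    performed   = x@performed,
    significant = x@nSignificant,
    percentage  = x@percentage)
})

#' @rdname accessors
#' @export
setMethod("anovaTerms", "AnovaResult", function(x) x@terms)

#' @rdname accessors
#' @export
setMethod("pairwiseComparisons", "AnovaResult", function(x) x@pairwise)

#' @rdname accessors
#' @export
setMethod("letterDisplay", "AnovaResult", function(x) x@letters)

setMethod("show", "RawImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RawImage: %d x %d px, %d channel(s), %d-bit, plane %s [%s]\n",
              d[1], d[2], object@channels, object@bitDepth,
              ifelse(is.na(object@plane), "<unlabeled>", object@plane),
              object@sourceId))
})

setMethod("show", "GreyImage", function(object) {
  px <- object@pixels
  cat(sprintf(
    "GreyImage: %d x %d px, range [%d, %d], %s, plane %s [%s]\n",
    nrow(px), ncol(px), min(px), max(px),
    if (object@normalized) "normalized" else "not normalized",
    ifelse(is.na(object@plane), "<unlabeled>", object@plane),
    object@sourceId))
})

setMethod("show", "SpotSet", function(object) {
  cat(sprintf("SpotSet: 4 spot meters, diameter %g px\n", object@diameter))
  ctr <- object@centers
  for (i in seq_len(4))
    cat(sprintf("  spot %d: center (%g, %g)\n", i, ctr[i, 1], ctr[i, 2]))
})

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf(
    "ScreenResult (%s, alpha = %g): %d significant of %d possible (%0.1f%%); %d pairs tested\n",
    if (object@pooled) "pooled" else "within-group",
    object@alpha, object@nSignificant, object@possible,
    object@percentage, object@performed))
  sig <- object@results[object@results$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    cat("Significant correlations:\n")
    print(sig[, c("group", "input_variable", "output_variable",
                  "r", "p_value", "equation", "strength_label")],
          row.names = FALSE, digits = 3)
  }
  if (nrow(object@skipped) > 0)
    cat(sprintf("(%d zero-variance variable/group combinations skipped)\n",
                nrow(object@skipped)))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("AnovaResult (%s post hoc, alpha = %g)\n",
              toupper(object@method), object@alpha))
  print(object@terms, row.names = FALSE, digits = 4)
  for (f in names(object@letters)) {
    m <- object@means[[f]]
    l <- object@letters[[f]]
    cat(sprintf("  %s: %s\n", f,
                paste(sprintf("%s = %.3g %s", names(m), m, l[names(m)]),
                      collapse = ", ")))
  }
})
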