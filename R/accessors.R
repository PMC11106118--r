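#' @rdname ScanImage-class
#' @param object,x a \code{ScanImage}, \code{ZStack} or \code{BinaryMask}.
#' @export
setGeneric("scanPixels", function(x) standardGeneric("scanPixels"))

#' @rdname ScanImage-class
#' @export
setMethod("scanPixels", "ScanImage", function(x) x@pixels)

#' @rdname ScanImage-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ScanImage-class
#' @export
setMethod("pixelSize", "ScanImage", function(x) x@pixelSize)

#' @rdname ScanImage-class
#' @export
setMethod("pixelSize", "BinaryMask", function(x) x@pixelSize)

#' @rdname ScanImage-class
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' @rdname ScanImage-class
#' @export
setMethod("sourceId", "ScanImage", function(x) x@sourceId)

#' @rdname ZStack-class
#' @param x a \code{ZStack}.
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))

#' @rdname ZStack-class
#' @export
setMethod("nPlanes", "ZStack", function(x) length(x@planes))

#' @rdname ZStack-class
#' @param i plane index.
#' @export
setGeneric("getPlane", function(x, i) standardGeneric("getPlane"))

#' @rdname ZStack-class
#' @export
setMethod("getPlane", "ZStack", function(x, i) x@planes[[i]])

#' @rdname BinaryMask-class
#' @param x a \code{BinaryMask}.
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))

#' @rdname BinaryMask-class
#' @export
setMethod("maskGrid", "BinaryMask", function(x) x@grid)

#' @rdname BinaryMask-class
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))

#' @rdname BinaryMask-class
#' @export
setMethod("thresholdUsed", "BinaryMask", function(x) x@thresholdUsed)

#' @rdname SizeClassScheme-class
#' @param x a \code{SizeClassScheme}.
#' @export
setGeneric("sizeBoundaries", function(x) standardGeneric("sizeBoundaries"))

#' @rdname SizeClassScheme-class
#' @export
setMethod("sizeBoundaries", "SizeClassScheme", function(x) x@boundaries)

#' @rdname SizeClassScheme-class
#' @export
setGeneric("sizeClassLabels", function(x) standardGeneric("sizeClassLabels"))

#' @rdname SizeClassScheme-class
#' @export
setMethod("sizeClassLabels", "SizeClassScheme", function(x) {
  b <- x@boundaries
  paste0(b[-length(b)], "-", b[-1])
})

#' @rdname LoqTable-class
#' @param x a \code{LoqTable} or \code{SampleSummary}.
#' @export
setGeneric("loqTable", function(x) standardGeneric("loqTable"))

#' @rdname LoqTable-class
#' @export
setMethod("loqTable", "LoqTable", function(x) x@table)

#' @rdname SampleSummary-class
#' @param x a \code{SampleSummary}.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname SampleSummary-class
#' @export
setMethod("sampleId", "SampleSummary", function(x) x@sampleId)

#' @rdname SampleSummary-class
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname SampleSummary-class
#' @export
setMethod("categoryCounts", "SampleSummary", function(x) x@categories)

#' @rdname SampleSummary-class
#' @export
setGeneric("isCorrected", function(x) standardGeneric("isCorrected"))

#' @rdname SampleSummary-class
#' @export
setMethod("isCorrected", "SampleSummary", function(x) x@corrected)

#' MP-suspect totals of a sample summary
#'
#' Sums the per-category counts and mass estimates of a [SampleSummary]
#' over all categories. Censored categories contribute 0 to the corrected
#' totals by construction.
#'
#' @param x a \code{SampleSummary}.
#' @return named list with \code{raw_count}, \code{raw_mass_ug},
#'   \code{corrected_count}, \code{corrected_mass_ug}.
#' @export
setGeneric("mpTotals", function(x) standardGeneric("mpTotals"))

#' @rdname mpTotals
#' @export
setMethod("mpTotals", "SampleSummary", function(x) {
  cc <- x@categories
  list(
    raw_count = sum(cc$raw_count),
    raw_mass_ug = sum(cc$raw_mass_ug),
    corrected_count = sum(cc$corrected_count),
    corrected_mass_ug = sum(cc$corrected_mass_ug)
  )
})

setMethod("show", "ScanImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ScanImage %d x %d px, %.3g um/px", d[1], d[2],
              object@pixelSize))
  if (nzchar(object@sourceId)) cat(sprintf(" [%s]", object@sourceId))
  cat("\n")
})

setMethod("show", "ZStack", function(object) {
  d <- dim(object@planes[[1]]@pixels)
  cat(sprintf("ZStack with %d plane(s), %d x %d px, %.3g um/px\n",
              length(object@planes), d[1], d[2],
              object@planes[[1]]@pixelSize))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d px, %d foreground px (threshold %.2f)\n",
              nrow(object@grid), ncol(object@grid), sum(object@grid),
              object@thresholdUsed))
})

setMethod("show", "ClassifierConfig", function(object) {
  cat("ClassifierConfig\n")
  cat(sprintf("  fluorescence groups : weak <= %g < medium <= %g < bright\n",
              object@tpbWeakMax, object@tpbMediumMax))
  cat(sprintf("  MP-suspect          : TPB >= %g and red fraction in [%g, %g]\n",
              object@tpbMpMin, object@redFractionMpRange[1],
              object@redFractionMpRange[2]))
  cat(sprintf("  shapes              : fibre aspect >= %g; spheroid circ >= %g, aspect <= %g\n",
              object@fibreAspectMin, object@spheroidCircularityMin,
              object@spheroidAspectMax))
})

setMethod("show", "SizeClassScheme", function(object) {
  cat("SizeClassScheme:", paste(sizeClassLabels(object), collapse = ", "),
      "um\n")
})

setMethod("show", "LoqTable", function(object) {
  nz <- sum(object@table$loq_count > 0)
  cat(sprintf("LoqTable from %d blank(s): %d categories, %d with LOQ > 0\n",
              object@nBlanks, nrow(object@table), nz))
})

setMethod("show", "SampleSummary", function(object) {
  t <- mpTotals(object)
  cat(sprintf("SampleSummary '%s' (%s)\n", object@sampleId,
              if (object@corrected) "blank-corrected" else "raw"))
  cat(sprintf("  MP-suspect: %g particles, %.4g ug (raw)", t$raw_count,
              t$raw_mass_ug))
  if (object@corrected) {
    cat(sprintf("; %g particles, %.4g ug (corrected)", t$corrected_count,
                t$corrected_mass_ug))
  }
  cat("\n")
})
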