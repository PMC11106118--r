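#' @import methods
NULL

#' Calibrated RGB filter scan
#'
#' An 8-bit RGB fluorescence micrograph of a filter membrane together with
#' its spatial calibration. Pixel values are stored on the native 0--255
#' scale; \code{pixelSize} is the edge length of one pixel in micrometres.
#'
#' @slot pixels numeric array \code{height x width x 3} with values in
#'   \code{[0, 255]} (R, G, B).
#' @slot pixelSize micrometres per pixel edge, \code{> 0}.
#' @slot sourceId free-text identifier (file path or fixture label).
#' @slot meta optional acquisition metadata (objective, excitation, exposure).
#'
#' @seealso [loadScan()], [maxProject()], [binarize()]
#' @export
setClass("ScanImage",
  representation(
    pixels = "array",
    pixelSize = "numeric",
    sourceId = "character",
    meta = "list"
  ),
  prototype(
    pixels = array(0, c(1, 1, 3)),
    pixelSize = 5,
    sourceId = "",
    meta = list()
  )
)

setValidity("ScanImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) {
    return("pixels must be a height x width x 3 array")
  }
  if (d[1] < 1L || d[2] < 1L) return("image grid must be non-empty")
  rng <- range(object@pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255) {
    return("channel values must lie in [0, 255]")
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) {
    return("pixelSize must be a single positive number (um/pixel)")
  }
  TRUE
})

#' Ordered z-stack of filter scans
#'
#' A list of dimension-identical [ScanImage] planes acquired at different
#' focal depths; collapsed to a single in-focus image by [maxProject()].
#'
#' @slot planes list of [ScanImage] objects with identical dimensions and
#'   pixel size.
#' @export
setClass("ZStack", representation(planes = "list"))

setValidity("ZStack", function(object) {
  if (length(object@planes) < 1L) return("a z-stack needs at least one plane")
  if (!all(vapply(object@planes, is, logical(1), "ScanImage"))) {
    return("all planes must be ScanImage objects")
  }
  d1 <- dim(object@planes[[1]]@pixels)
  ps1 <- object@planes[[1]]@pixelSize
  for (p in object@planes) {
    if (!identical(dim(p@pixels), d1)) return("plane dimensions differ")
    if (p@pixelSize != ps1) return("plane pixel sizes differ")
  }
  TRUE
})

#' Binary particle mask
#'
#' Foreground/background raster aligned to a [ScanImage], produced by
#' [binarize()]. Records the brightness threshold actually applied so every
#' downstream count is traceable to the segmentation.
#'
#' @slot grid logical matrix, \code{TRUE} = particle pixel.
#' @slot thresholdUsed effective brightness cut on the 0--255 scale.
#' @slot pixelSize micrometres per pixel, copied from the source image.
#' @export
setClass("BinaryMask",
  representation(grid = "matrix", thresholdUsed = "numeric",
                 pixelSize = "numeric")
)

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@grid)) return("grid must be a logical matrix")
  if (length(object@thresholdUsed) != 1L ||
      object@thresholdUsed < 0 || object@thresholdUsed > 255) {
    return("thresholdUsed must lie in [0, 255]")
  }
  TRUE
})

#' Classification thresholds for MP / natural-particle separation
#'
#' Holds every tunable cut used to separate microplastic-suspect (MP)
#' particles from particles of natural origin (PNO) and to subdivide
#' particles by shape and fluorescence group. Defaults are re-derived
#' working values on the 8-bit brightness scale, not published constants;
#' all of them are serialisable with [writeClassifierConfig()].
#'
#' @slot tpbWeakMax upper total-particle-brightness (TPB) bound of the
#'   "weak" fluorescence group (default 40).
#' @slot tpbMediumMax upper TPB bound of the "medium" group (default 75);
#'   anything brighter is "bright".
#' @slot tpbMpMin minimum TPB for a particle to be MP-suspect (default 45).
#' @slot redFractionMpRange closed interval of the red colour fraction
#'   compatible with Nile-red-stained polymers (default \code{[0.34, 0.80]}).
#' @slot fibreAspectMin minimum aspect ratio classifying a fibre (default 3).
#' @slot spheroidCircularityMin minimum circularity for a spheroid
#'   (default 0.85).
#' @slot spheroidAspectMax maximum aspect ratio for a spheroid (default 1.3).
#' @slot fragmentHeightFactor height of the cuboid volume model as a
#'   multiple of the minor axis (default 1).
#' @export
setClass("ClassifierConfig",
  representation(
    tpbWeakMax = "numeric",
    tpbMediumMax = "numeric",
    tpbMpMin = "numeric",
    redFractionMpRange = "numeric",
    fibreAspectMin = "numeric",
    spheroidCircularityMin = "numeric",
    spheroidAspectMax = "numeric",
    fragmentHeightFactor = "numeric"
  )
)

setValidity("ClassifierConfig", function(object) {
  inrange <- function(x, lo, hi) length(x) == 1L && is.finite(x) &&
    x >= lo && x <= hi
  if (!inrange(object@tpbWeakMax, 0, 255)) return("tpbWeakMax outside [0,255]")
  if (!inrange(object@tpbMediumMax, 0, 255)) {
    return("tpbMediumMax outside [0,255]")
  }
  if (object@tpbWeakMax >= object@tpbMediumMax) {
    return("tpbWeakMax must be < tpbMediumMax")
  }
  if (!inrange(object@tpbMpMin, 0, 255)) return("tpbMpMin outside [0,255]")
  r <- object@redFractionMpRange
  if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] ||
      r[1] < 0 || r[2] > 1) {
    return("redFractionMpRange must be an ordered interval within [0,1]")
  }
  if (object@fibreAspectMin < 1) return("fibreAspectMin must be >= 1")
  if (!inrange(object@spheroidCircularityMin, 0, 1)) {
    return("spheroidCircularityMin outside [0,1]")
  }
  if (object@spheroidAspectMax < 1) return("spheroidAspectMax must be >= 1")
  if (object@fragmentHeightFactor <= 0) {
    return("fragmentHeightFactor must be > 0")
  }
  TRUE
})

#' Size-class scheme for particle binning
#'
#' Six size classes on the maximum Feret diameter: 5--10, 10--50, 50--100,
#' 100--500, 500--1000 and 1000--5000 um. Bins are lower-inclusive and
#' upper-exclusive except the top class, which is closed at 5000 um.
#' Particles below 5 um are assigned a below-range label and excluded from
#' MP reporting.
#'
#' @slot boundaries strictly increasing numeric vector of class boundaries
#'   in micrometres (default \code{c(5, 10, 50, 100, 500, 1000, 5000)}).
#' @export
setClass("SizeClassScheme", representation(boundaries = "numeric"))

setValidity("SizeClassScheme", function(object) {
  b <- object@boundaries
  if (length(b) < 2L || any(!is.finite(b)) || any(diff(b) <= 0)) {
    return("boundaries must be strictly increasing")
  }
  if (any(b <= 0)) return("boundaries must be positive")
  TRUE
})

#' Per-category limits of quantification from procedural blanks
#'
#' For every combination of size class, shape class and fluorescence group,
#' the mean and sample SD of the procedural-blank counts and mass estimates,
#' and the limit of quantification LOQ = mean + 10 x SD. Categories absent
#' from all blanks carry mean = SD = LOQ = 0.
#'
#' @slot table data.frame with columns \code{size_class}, \code{shape_class},
#'   \code{fluor_group}, \code{blank_mean_count}, \code{blank_sd_count},
#'   \code{loq_count}, \code{blank_mean_mass_ug}, \code{blank_sd_mass_ug},
#'   \code{loq_mass_ug}.
#' @slot nBlanks number of procedural blanks the table was computed from.
#' @seealso [computeLoq()], [blankCorrect()]
#' @export
setClass("LoqTable", representation(table = "data.frame", nBlanks = "integer"))

setValidity("LoqTable", function(object) {
  need <- c("size_class", "shape_class", "fluor_group",
            "blank_mean_count", "blank_sd_count", "loq_count",
            "blank_mean_mass_ug", "blank_sd_mass_ug", "loq_mass_ug")
  if (!all(need %in% names(object@table))) {
    return(paste("LoqTable missing columns:",
                 paste(setdiff(need, names(object@table)), collapse = ", ")))
  }
  if (object@nBlanks < 1L) return("nBlanks must be >= 1")
  t <- object@table
  if (any(t$blank_mean_count < 0) || any(t$blank_sd_count < 0)) {
    return("blank moments must be non-negative")
  }
  if (any(t$loq_count + 1e-9 < t$blank_mean_count)) {
    return("loq_count must be >= blank_mean_count")
  }
  TRUE
})

#' Per-sample particle counts and mass estimates by category
#'
#' Raw and (after [blankCorrect()]) blank-corrected counts and mass
#' estimates of MP-suspect particles for each category (size class x shape
#' class x fluorescence group). Censored categories (raw value at or below
#' the LOQ) report 0 and are flagged.
#'
#' @slot sampleId sample identifier.
#' @slot categories data.frame with category keys and columns
#'   \code{raw_count}, \code{raw_mass_ug}, \code{corrected_count},
#'   \code{corrected_mass_ug}, \code{censored_count}, \code{censored_mass}.
#' @slot corrected whether blank correction has been applied.
#' @seealso [aggregateSample()], [mpTotals()]
#' @export
setClass("SampleSummary",
  representation(sampleId = "character", categories = "data.frame",
                 corrected = "logical")
)

setValidity("SampleSummary", function(object) {
  need <- c("size_class", "shape_class", "fluor_group",
            "raw_count", "raw_mass_ug", "corrected_count",
            "corrected_mass_ug", "censored_count", "censored_mass")
  if (!all(need %in% names(object@categories))) {
    return(paste("SampleSummary missing columns:",
                 paste(setdiff(need, names(object@categories)),
                       collapse = ", ")))
  }
  cc <- object@categories
  if (any(cc$raw_count < 0) || any(cc$corrected_count < 0) ||
      any(cc$raw_mass_ug < 0) || any(cc$corrected_mass_ug < 0)) {
    return("counts and masses must be non-negative")
  }
  TRUE
})
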