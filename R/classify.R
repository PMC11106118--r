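#' Create a classifier configuration
#'
#' Constructs a [ClassifierConfig] with the package's default thresholds.
#' The defaults are working values re-derived so that brightly and
#' medium-stained polymers are retained as MP-suspect while weakly stained
#' material and off-colour natural particles are rejected; they are not
#' published constants and should be tuned per laboratory. See the
#' \code{ClassifierConfig} class for the meaning of each cut.
#'
#' @param tpb_weak_max,tpb_medium_max,tpb_mp_min TPB cuts on \code{[0,255]}.
#' @param red_fraction_mp_range closed interval of MP-compatible red
#'   fractions.
#' @param fibre_aspect_min,spheroid_circularity_min,spheroid_aspect_max
#'   shape cuts.
#' @param fragment_height_factor cuboid height as a multiple of the minor
#'   axis.
#' @return a [ClassifierConfig].
#' @export
classifierConfig <- function(tpb_weak_max = 40, tpb_medium_max = 75,
                             tpb_mp_min = 45,
                             red_fraction_mp_range = c(0.34, 0.80),
                             fibre_aspect_min = 3.0,
                             spheroid_circularity_min = 0.85,
                             spheroid_aspect_max = 1.3,
                             fragment_height_factor = 1.0) {
  new("ClassifierConfig",
      tpbWeakMax = tpb_weak_max, tpbMediumMax = tpb_medium_max,
      tpbMpMin = tpb_mp_min,
      redFractionMpRange = as.numeric(red_fraction_mp_range),
      fibreAspectMin = fibre_aspect_min,
      spheroidCircularityMin = spheroid_circularity_min,
      spheroidAspectMax = spheroid_aspect_max,
      fragmentHeightFactor = fragment_height_factor)
}

#' Serialise / read a classifier configuration
#'
#' Round-trips a [ClassifierConfig] through a YAML file so threshold sets
#' can be versioned alongside results.
#'
#' @param cfg a [ClassifierConfig].
#' @param path YAML file path.
#' @return \code{writeClassifierConfig} returns the path invisibly;
#'   \code{readClassifierConfig} returns a [ClassifierConfig].
#' @export
writeClassifierConfig <- function(cfg, path) {
  stopifnot(is(cfg, "ClassifierConfig"))
  yaml::write_yaml(list(
    tpb_weak_max = cfg@tpbWeakMax, tpb_medium_max = cfg@tpbMediumMax,
    tpb_mp_min = cfg@tpbMpMin,
    red_fraction_mp_range = cfg@redFractionMpRange,
    fibre_aspect_min = cfg@fibreAspectMin,
    spheroid_circularity_min = cfg@spheroidCircularityMin,
    spheroid_aspect_max = cfg@spheroidAspectMax,
    fragment_height_factor = cfg@fragmentHeightFactor
  ), path)
  invisible(path)
}

#' @rdname writeClassifierConfig
#' @export
readClassifierConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(classifierConfig, vals)
}

#' Create a size-class scheme
#'
#' @param boundaries_um strictly increasing class boundaries in
#'   micrometres; the default gives the six classes 5--10, 10--50, 50--100,
#'   100--500, 500--1000 and 1000--5000 um.
#' @return a [SizeClassScheme].
#' @export
sizeClassScheme <- function(boundaries_um = c(5, 10, 50, 100, 500, 1000,
                                              5000)) {
  new("SizeClassScheme", boundaries = as.numeric(boundaries_um))
}

#' Classify particle shape
#'
#' Assigns each particle to fibre, spheroid or fragment from its
#' fitted-ellipse aspect ratio and circularity: fibres are strongly
#' elongated (aspect ratio at or above \code{fibreAspectMin}), spheroids
#' are round and nearly isometric, everything else is a fragment.
#'
#' @param m a list or data.frame with elements/columns \code{aspect_ratio}
#'   and \code{circularity} (one value or vectors).
#' @param cfg a [ClassifierConfig].
#' @return character vector of \code{"fragment"}, \code{"spheroid"},
#'   \code{"fibre"}.
#' @export
classifyShape <- function(m, cfg = classifierConfig()) {
  stopifnot(is(cfg, "ClassifierConfig"))
  ar <- m$aspect_ratio
  circ <- m$circularity
  out <- rep("fragment", length(ar))
  out[circ >= cfg@spheroidCircularityMin & ar <= cfg@spheroidAspectMax] <-
    "spheroid"
  out[ar >= cfg@fibreAspectMin] <- "fibre"
  out
}

#' Classify particle fluorescence
#'
#' Assigns the ordinal fluorescence group (weak / medium / bright) from
#' the total particle brightness and flags MP-suspect particles: a
#' particle is MP-suspect when its TPB reaches \code{tpbMpMin} and its red
#' colour fraction falls inside the MP-compatible interval. Weakly
#' stained or off-colour particles (typical of matrix residues such as
#' fishbone or shell) fail one of the two cuts.
#'
#' @param f a list or data.frame with elements/columns \code{tpb} and
#'   \code{red_fraction} (one value or vectors).
#' @param cfg a [ClassifierConfig].
#' @return data.frame with columns \code{fluor_group} and
#'   \code{mp_suspect}.
#' @examples
#' classifyFluorescence(list(tpb = c(88, 26), red_fraction = c(0.5, 0.5)))
#' @export
classifyFluorescence <- function(f, cfg = classifierConfig()) {
  stopifnot(is(cfg, "ClassifierConfig"))
  tpb <- f$tpb
  red <- f$red_fraction
  group <- ifelse(tpb <= cfg@tpbWeakMax, "weak",
                  ifelse(tpb <= cfg@tpbMediumMax, "medium", "bright"))
  suspect <- tpb >= cfg@tpbMpMin &
    !is.na(red) & red >= cfg@redFractionMpRange[1L] &
    red <= cfg@redFractionMpRange[2L]
  data.frame(fluor_group = group, mp_suspect = suspect,
             stringsAsFactors = FALSE)
}

#' Assign particles to size classes
#'
#' Bins maximum Feret diameters into the scheme's size classes
#' (lower-inclusive, upper-exclusive; the top class is closed at its upper
#' boundary). Sizes below the scheme floor map to \code{"below-range"} and
#' above the top boundary to \code{"above-range"}; both are excluded from
#' MP reporting.
#'
#' @param feret_max_um positive Feret diameters in micrometres.
#' @param scheme a [SizeClassScheme].
#' @return character vector of class labels.
#' @examples
#' assignSizeClass(c(4, 10, 5000))
#' @export
assignSizeClass <- function(feret_max_um, scheme = sizeClassScheme()) {
  stopifnot(is(scheme, "SizeClassScheme"))
  if (any(!is.finite(feret_max_um)) || any(feret_max_um <= 0)) {
    stop("feret_max_um must be positive", call. = FALSE)
  }
  b <- scheme@boundaries
  labels <- sizeClassLabels(scheme)
  idx <- findInterval(feret_max_um, b, rightmost.closed = TRUE)
  out <- rep("below-range", length(feret_max_um))
  inside <- idx >= 1L & idx <= length(labels)
  out[inside] <- labels[idx[inside]]
  out[feret_max_um > b[length(b)]] <- "above-range"
  out
}

#' Estimate particle volume from 2D morphology
#'
#' Approximates each particle by a 3D solid chosen by its shape class:
#' spheroids become spheres with the area-equivalent circular diameter
#' (\eqn{V = \pi d^3 / 6}), fragments become cuboids of major x minor x
#' (height factor x minor), and fibres become cylinders with length equal
#' to the major axis and diameter equal to the minor axis
#' (\eqn{V = L \pi (W/2)^2}).
#'
#' @param shape_class character vector of \code{"fragment"},
#'   \code{"spheroid"}, \code{"fibre"}.
#' @param m list or data.frame with \code{area_um2}, \code{major_axis_um},
#'   \code{minor_axis_um} (vectors aligned with \code{shape_class}).
#' @param height_factor cuboid height as a multiple of the minor axis
#'   (default 1).
#' @return numeric vector of volumes in cubic micrometres.
#' @examples
#' estimateVolume("spheroid", list(area_um2 = pi * 25^2,
#'   major_axis_um = 50, minor_axis_um = 50))  # (pi/6) * 50^3
#' @export
estimateVolume <- function(shape_class, m, height_factor = 1) {
  area <- m$area_um2
  major <- m$major_axis_um
  minor <- m$minor_axis_um
  d_eq <- 2 * sqrt(area / pi)
  out <- numeric(length(shape_class))
  sph <- shape_class == "spheroid"
  fib <- shape_class == "fibre"
  frg <- !sph & !fib
  out[sph] <- pi / 6 * d_eq[sph]^3
  out[fib] <- major[fib] * pi * (minor[fib] / 2)^2
  out[frg] <- major[frg] * minor[frg] * minor[frg] * height_factor
  out
}

#' Convert particle volume to mass
#'
#' \eqn{m[\mu g] = V[\mu m^3] \times \rho[g\,cm^{-3}] \times 10^{-6}}
#' (1 um^3 = 1e-12 cm^3 and 1 g = 1e6 ug).
#'
#' @param volume_um3 volumes in cubic micrometres.
#' @param density_g_cm3 assumed polymer density in g/cm^3 (> 0).
#' @return mass in micrograms.
#' @export
estimateMass <- function(volume_um3, density_g_cm3) {
  if (any(!is.finite(density_g_cm3)) || any(density_g_cm3 <= 0)) {
    stop("density_g_cm3 must be > 0", call. = FALSE)
  }
  volume_um3 * density_g_cm3 * 1e-6
}

#' Default polymer density table
#'
#' Typical densities of the polymers most frequently reported in food,
#' with a conservative fallback of 1.05 g/cm^3 for particles of unknown
#' composition (polymer identification from fluorescence alone is not
#' reliable, so screening reports usually use the fallback).
#'
#' @return data.frame with columns \code{polymer} and
#'   \code{density_g_cm3}.
#' @export
densityTable <- function() {
  data.frame(
    polymer = c("PE", "PP", "PS", "PA6", "PA12", "PET", "PVC", "unknown"),
    density_g_cm3 = c(0.94, 0.91, 1.05, 1.14, 1.01, 1.38, 1.40, 1.05),
    stringsAsFactors = FALSE
  )
}
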