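.SHAPE_CLASSES <- c("fragment", "spheroid", "fibre")
.FLUOR_GROUPS <- c("weak", "medium", "bright")

# full category universe for a scheme: size class x shape x fluorescence
.categoryGrid <- function(scheme = sizeClassScheme()) {
  g <- expand.grid(size_class = sizeClassLabels(scheme),
                   shape_class = .SHAPE_CLASSES,
                   fluor_group = .FLUOR_GROUPS,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[order(g$size_class, g$shape_class, g$fluor_group), , drop = FALSE]
}

.categoryKey <- function(df) {
  paste(df$size_class, df$shape_class, df$fluor_group, sep = "|")
}

#' Measure and classify all particles of a scan
#'
#' Runs the per-particle measurement and classification chain on a set of
#' labelled components: morphology and fluorescence features, shape class,
#' fluorescence group, MP-suspect flag, size class, volume and mass.
#' Returns one row per particle; non-suspect particles are retained for
#' audit and only filtered out during aggregation.
#'
#' @param components list of pixel-coordinate sets from
#'   [labelParticles()].
#' @param image the original colour [ScanImage].
#' @param cfg a [ClassifierConfig].
#' @param scheme a [SizeClassScheme].
#' @param density_g_cm3 assumed density for mass estimation (default the
#'   unknown-composition fallback, 1.05 g/cm^3).
#' @return data.frame with one row per particle (columns
#'   \code{particle_id}, the morphology and fluorescence features,
#'   \code{shape_class}, \code{fluor_group}, \code{mp_suspect},
#'   \code{size_class}, \code{volume_um3}, \code{mass_ug}).
#' @export
particleTable <- function(components, image, cfg = classifierConfig(),
                          scheme = sizeClassScheme(),
                          density_g_cm3 = 1.05) {
  stopifnot(is(image, "ScanImage"))
  cols <- c("particle_id", "area_um2", "perimeter_um", "feret_max_um",
            "major_axis_um", "minor_axis_um", "aspect_ratio", "circularity",
            "tpb", "mean_r", "mean_g", "mean_b", "red_fraction",
            "green_fraction", "blue_fraction", "shape_class", "fluor_group",
            "mp_suspect", "size_class", "volume_um3", "mass_ug")
  if (length(components) == 0L) {
    out <- as.data.frame(matrix(nrow = 0L, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  rows <- lapply(seq_along(components), function(i) {
    m <- measureMorphology(components[[i]], image@pixelSize)
    f <- measureFluorescence(components[[i]], image)
    data.frame(particle_id = sprintf("p%04d", i), as.data.frame(m),
               as.data.frame(f), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$shape_class <- classifyShape(out, cfg)
  fl <- classifyFluorescence(out, cfg)
  out$fluor_group <- fl$fluor_group
  out$mp_suspect <- fl$mp_suspect
  out$size_class <- assignSizeClass(out$feret_max_um, scheme)
  out$volume_um3 <- estimateVolume(out$shape_class, out,
                                   height_factor = cfg@fragmentHeightFactor)
  out$mass_ug <- estimateMass(out$volume_um3, density_g_cm3)
  out[, cols]
}

#' Aggregate particles into a per-sample summary
#'
#' Counts MP-suspect particles and sums their mass estimates per category
#' (size class x shape class x fluorescence group). Below-range and
#' above-range particles and non-suspect particles are excluded from the
#' summary; the full category grid is reported with zeros for empty
#' categories so summaries from different samples always align.
#'
#' @param records particle data.frame from [particleTable()] (may be
#'   empty).
#' @param scheme a [SizeClassScheme].
#' @param sample_id identifier stored in the summary.
#' @return an uncorrected [SampleSummary].
#' @export
aggregateSample <- function(records, scheme = sizeClassScheme(),
                            sample_id = "sample") {
  grid <- .categoryGrid(scheme)
  grid$raw_count <- 0
  grid$raw_mass_ug <- 0
  if (!is.null(records) && nrow(records) > 0L) {
    keep <- records$mp_suspect & records$size_class %in%
      sizeClassLabels(scheme)
    rec <- records[keep, , drop = FALSE]
    if (nrow(rec) > 0L) {
      key <- .categoryKey(rec)
      cnt <- tapply(rep(1, nrow(rec)), key, sum)
      mss <- tapply(rec$mass_ug, key, sum)
      gkey <- .categoryKey(grid)
      grid$raw_count[match(names(cnt), gkey)] <- as.numeric(cnt)
      grid$raw_mass_ug[match(names(mss), gkey)] <- as.numeric(mss)
    }
  }
  grid$corrected_count <- grid$raw_count
  grid$corrected_mass_ug <- grid$raw_mass_ug
  grid$censored_count <- FALSE
  grid$censored_mass <- FALSE
  rownames(grid) <- NULL
  new("SampleSummary", sampleId = sample_id, categories = grid,
      corrected = FALSE)
}

#' Per-category limits of quantification from procedural blanks
#'
#' Computes, for every category, the mean and sample standard deviation
#' (n - 1 denominator; 0 when only one blank is supplied) of the blank
#' counts and mass estimates, and the limit of quantification
#' LOQ = mean + 10 x SD. Categories absent from every blank get
#' mean = SD = LOQ = 0.
#'
#' @param blank_summaries list of uncorrected [SampleSummary] objects, one
#'   per procedural blank (three per sample series is typical).
#' @return a [LoqTable].
#' @examples
#' # blanks with counts 2, 3, 4 in one category give LOQ = 3 + 10 * 1 = 13
#' @export
computeLoq <- function(blank_summaries) {
  if (length(blank_summaries) < 1L) {
    stop("at least one procedural blank is required", call. = FALSE)
  }
  stopifnot(all(vapply(blank_summaries, is, logical(1), "SampleSummary")))
  key0 <- .categoryKey(blank_summaries[[1L]]@categories)
  counts <- vapply(blank_summaries, function(s) {
    if (!identical(.categoryKey(s@categories), key0)) {
      stop("blank summaries use different category schemes", call. = FALSE)
    }
    s@categories$raw_count
  }, numeric(length(key0)))
  masses <- vapply(blank_summaries, function(s) s@categories$raw_mass_ug,
                   numeric(length(key0)))
  counts <- matrix(counts, nrow = length(key0))
  masses <- matrix(masses, nrow = length(key0))
  n <- length(blank_summaries)
  sdev <- function(m) if (n == 1L) rep(0, nrow(m)) else apply(m, 1L, stats::sd)
  t <- blank_summaries[[1L]]@categories[, c("size_class", "shape_class",
                                            "fluor_group")]
  t$blank_mean_count <- rowMeans(counts)
  t$blank_sd_count <- sdev(counts)
  t$loq_count <- t$blank_mean_count + 10 * t$blank_sd_count
  t$blank_mean_mass_ug <- rowMeans(masses)
  t$blank_sd_mass_ug <- sdev(masses)
  t$loq_mass_ug <- t$blank_mean_mass_ug + 10 * t$blank_sd_mass_ug
  rownames(t) <- NULL
  new("LoqTable", table = t, nBlanks = as.integer(n))
}

#' Blank-correct a sample summary
#'
#' Applies per-category LOQ censoring and blank subtraction: a category
#' whose raw value exceeds its LOQ is corrected by subtracting the blank
#' mean (floored at zero); a category at or below the LOQ is censored and
#' reports zero. Counts and mass estimates are corrected independently.
#'
#' @param sample an uncorrected [SampleSummary].
#' @param loq a [LoqTable] sharing the sample's category scheme.
#' @return the corrected [SampleSummary] (\code{isCorrected} = TRUE).
#' @export
blankCorrect <- function(sample, loq) {
  stopifnot(is(sample, "SampleSummary"), is(loq, "LoqTable"))
  cc <- sample@categories
  lt <- loq@table
  if (!identical(.categoryKey(cc), .categoryKey(lt))) {
    stop("sample and LOQ table use different category schemes",
         call. = FALSE)
  }
  above_c <- cc$raw_count > lt$loq_count
  cc$corrected_count <- ifelse(above_c,
                               pmax(cc$raw_count - lt$blank_mean_count, 0), 0)
  cc$censored_count <- !above_c
  above_m <- cc$raw_mass_ug > lt$loq_mass_ug
  cc$corrected_mass_ug <- ifelse(above_m,
                                 pmax(cc$raw_mass_ug - lt$blank_mean_mass_ug,
                                      0), 0)
  cc$censored_mass <- !above_m
  new("SampleSummary", sampleId = sample@sampleId, categories = cc,
      corrected = TRUE)
}
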