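#' Series-level analysis configuration
#'
#' Bundles everything needed to analyse a sample series: the sample
#' scans, the procedural-blank scans used for LOQ correction, the
#' classifier thresholds, size-class scheme and assumed density. Scans
#' may be given as [ScanImage]/[ZStack] objects or file paths (paths are
#' read with [loadScan()] using \code{pixel_size_um}/\code{objective}).
#'
#' @param samples named list of sample scans (>= 1).
#' @param blanks list of procedural-blank scans (may be empty; blank
#'   correction is then skipped with a warning).
#' @param classifier a [ClassifierConfig].
#' @param scheme a [SizeClassScheme].
#' @param density_g_cm3 assumed particle density.
#' @param pixel_size_um,objective calibration applied when scans are
#'   given as paths.
#' @param threshold,auto_offset,opening_radius,min_area_px segmentation
#'   settings passed to [runSample()].
#' @return a \code{seriesConfig} list.
#' @export
seriesConfig <- function(samples, blanks = list(),
                         classifier = classifierConfig(),
                         scheme = sizeClassScheme(), density_g_cm3 = 1.05,
                         pixel_size_um = NULL, objective = NULL,
                         threshold = NULL, auto_offset = 0,
                         opening_radius = 0, min_area_px = 2) {
  if (length(samples) < 1L) {
    stop("a series needs at least one sample", call. = FALSE)
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- sprintf("sample-%d", seq_along(samples))
  }
  if (length(blanks) > 0L &&
      (is.null(names(blanks)) || any(!nzchar(names(blanks))))) {
    names(blanks) <- sprintf("blank-%d", seq_along(blanks))
  }
  structure(list(samples = samples, blanks = blanks,
                 classifier = classifier, scheme = scheme,
                 density_g_cm3 = density_g_cm3,
                 pixel_size_um = pixel_size_um, objective = objective,
                 threshold = threshold, auto_offset = auto_offset,
                 opening_radius = opening_radius, min_area_px = min_area_px),
            class = "seriesConfig")
}

.resolveScan <- function(x, cfg) {
  if (is(x, "ScanImage")) return(x)
  if (is(x, "ZStack")) return(maxProject(x))
  if (is.character(x)) {
    return(loadScan(x, pixel_size_um = cfg$pixel_size_um,
                    objective = cfg$objective))
  }
  stop("scan must be a ScanImage, ZStack or file path", call. = FALSE)
}

#' Analyse one filter scan
#'
#' Runs the full per-sample chain: (optional z-stack projection),
#' brightness thresholding, optional morphological opening, 8-connected
#' labelling with minimum-area filtering, per-particle measurement and
#' classification, and aggregation into an uncorrected [SampleSummary].
#' The processing log records the threshold actually used and the
#' particle attrition per stage (raw components, area-filtered,
#' MP-suspect).
#'
#' @param scan a [ScanImage], [ZStack] or file path.
#' @param classifier a [ClassifierConfig].
#' @param scheme a [SizeClassScheme].
#' @param density_g_cm3 assumed particle density.
#' @param threshold explicit brightness threshold, or \code{NULL} for
#'   Otsu.
#' @param auto_offset signed offset added to the automatic threshold.
#' @param opening_radius morphological opening radius in pixels; 0 (the
#'   default) skips opening and leaves isolated-pixel removal to the
#'   minimum-area filter, which preserves genuine few-pixel particles.
#' @param min_area_px minimum component area in pixels.
#' @param sample_id identifier for the summary.
#' @return list with \code{particles} (data.frame), \code{summary}
#'   (uncorrected [SampleSummary]) and \code{log}.
#' @export
runSample <- function(scan, classifier = classifierConfig(),
                      scheme = sizeClassScheme(), density_g_cm3 = 1.05,
                      threshold = NULL, auto_offset = 0, opening_radius = 0,
                      min_area_px = 2, sample_id = "sample") {
  image <- if (is(scan, "ZStack")) maxProject(scan) else scan
  if (is.character(image)) {
    image <- loadScan(image, pixel_size_um = NULL, objective = NULL)
  }
  stopifnot(is(image, "ScanImage"))
  mask <- binarize(image, threshold = threshold, auto_offset = auto_offset)
  if (opening_radius >= 1) mask <- cleanMask(mask, opening_radius)
  raw_components <- labelParticles(mask, min_area_px = 1)
  components <- raw_components[
    vapply(raw_components, nrow, integer(1)) >= min_area_px]
  particles <- particleTable(components, image, cfg = classifier,
                             scheme = scheme,
                             density_g_cm3 = density_g_cm3)
  summary <- aggregateSample(particles, scheme = scheme,
                             sample_id = sample_id)
  list(
    particles = particles,
    summary = summary,
    log = list(sample_id = sample_id, threshold_used = thresholdUsed(mask),
               n_components_raw = length(raw_components),
               n_after_area_filter = length(components),
               n_mp_suspect = sum(particles$mp_suspect))
  )
}

# stable hash of the configuration for provenance reporting
.configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(cfg, NULL, version = 2L), f)
  unname(tools::md5sum(f))
}

#' Analyse a sample series with blank correction
#'
#' Analyses the procedural blanks first, derives the per-category
#' [LoqTable] (LOQ = blank mean + 10 x SD), then analyses every sample
#' and blank-corrects it against the series LOQ. Without blanks the
#' samples are reported uncorrected with a warning. The report echoes
#' the configuration and its hash so every number is traceable.
#'
#' @param config a [seriesConfig()].
#' @return list with \code{samples} (per sample: \code{particles},
#'   \code{summary}, \code{log}), \code{blanks}, \code{loq} (or
#'   \code{NULL}), \code{corrected}, \code{config}, \code{config_hash}.
#' @export
runSeries <- function(config) {
  stopifnot(inherits(config, "seriesConfig"))
  run1 <- function(x, id) {
    runSample(.resolveScan(x, config), classifier = config$classifier,
              scheme = config$scheme, density_g_cm3 = config$density_g_cm3,
              threshold = config$threshold,
              auto_offset = config$auto_offset,
              opening_radius = config$opening_radius,
              min_area_px = config$min_area_px, sample_id = id)
  }
  blanks <- mapply(run1, config$blanks, names(config$blanks),
                   SIMPLIFY = FALSE)
  loq <- NULL
  if (length(blanks) > 0L) {
    loq <- computeLoq(lapply(blanks, `[[`, "summary"))
  } else {
    warning("no procedural blanks supplied; reporting uncorrected results",
            call. = FALSE)
  }
  samples <- mapply(run1, config$samples, names(config$samples),
                    SIMPLIFY = FALSE)
  if (!is.null(loq)) {
    samples <- lapply(samples, function(s) {
      s$summary <- blankCorrect(s$summary, loq)
      s
    })
  }
  list(samples = samples, blanks = blanks, loq = loq,
       corrected = !is.null(loq), config = config,
       config_hash = .configHash(config))
}

.summaryAsList <- function(summary) {
  t <- mpTotals(summary)
  list(sample_id = sampleId(summary), corrected = isCorrected(summary),
       totals = t, categories = categoryCounts(summary))
}

#' Write analysis reports
#'
#' Writes the results of [runSample()] or [runSeries()] to disk:
#' per-particle CSVs (one row per particle, fixed column order),
#' per-sample summary CSVs/JSONs, and a series-level JSON containing the
#' LOQ table, totals, censoring flags and the configuration echo. Output
#' is byte-identical across re-runs with identical inputs.
#'
#' @param results a [runSeries()] result (or a single [runSample()]
#'   result).
#' @param dir output directory, created if needed.
#' @param formats subset of \code{c("csv", "json")}.
#' @return character vector of the files written, invisibly.
#' @export
writeReports <- function(results, dir, formats = c("csv", "json")) {
  formats <- match.arg(formats, c("csv", "json"), several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(results$summary)) {          # single-sample result
    results <- list(samples = list(results), blanks = list(), loq = NULL,
                    corrected = FALSE, config = NULL, config_hash = NA)
  }
  written <- character(0)
  for (s in c(results$samples, results$blanks)) {
    id <- sampleId(s$summary)
    if ("csv" %in% formats) {
      f1 <- file.path(dir, sprintf("particles_%s.csv", id))
      utils::write.csv(s$particles, f1, row.names = FALSE)
      f2 <- file.path(dir, sprintf("summary_%s.csv", id))
      utils::write.csv(categoryCounts(s$summary), f2, row.names = FALSE)
      written <- c(written, f1, f2)
    }
    if ("json" %in% formats) {
      f3 <- file.path(dir, sprintf("summary_%s.json", id))
      jsonlite::write_json(.summaryAsList(s$summary), f3,
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      written <- c(written, f3)
    }
  }
  if ("json" %in% formats) {
    series <- list(
      corrected = results$corrected,
      config_hash = results$config_hash,
      loq = if (!is.null(results$loq)) loqTable(results$loq) else NULL,
      samples = lapply(results$samples, function(s) {
        c(.summaryAsList(s$summary), list(log = s$log))
      })
    )
    f <- file.path(dir, "series.json")
    jsonlite::write_json(series, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
    written <- c(written, f)
  }
  invisible(written)
}
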