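#' Construct a ScanImage from a pixel array
#'
#' @param pixels numeric array \code{height x width x 3}, values in
#'   \code{[0, 255]}. A plain matrix is treated as a grey image and
#'   replicated across the three channels.
#' @param pixel_size_um micrometres per pixel edge (> 0).
#' @param source_id free-text identifier.
#' @param meta optional named list of acquisition metadata.
#' @return a [ScanImage].
#' @export
scanImage <- function(pixels, pixel_size_um, source_id = "", meta = list()) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  }
  new("ScanImage", pixels = pixels, pixelSize = as.numeric(pixel_size_um),
      sourceId = source_id, meta = meta)
}

# objective label -> pixel pitch (um/px)
.OBJECTIVE_PIXEL_SIZES <- c("2.5x" = 10, "5x" = 5, "10x" = 1)

#' Pixel size for a microscope objective
#'
#' Maps the objective labels used for filter scanning to their pixel pitch:
#' 2.5x scans at 10 um/pixel, 5x at 5 um/pixel and 10x at 1 um/pixel.
#'
#' @param objective one of \code{"2.5x"}, \code{"5x"}, \code{"10x"}.
#' @return micrometres per pixel.
#' @export
objectivePixelSize <- function(objective) {
  objective <- tolower(as.character(objective))
  if (!objective %in% names(.OBJECTIVE_PIXEL_SIZES)) {
    stop("unknown objective label '", objective,
         "'; supply pixel_size_um explicitly", call. = FALSE)
  }
  unname(.OBJECTIVE_PIXEL_SIZES[objective])
}

.resolvePixelSize <- function(pixel_size_um, objective) {
  if (!is.null(pixel_size_um)) {
    pixel_size_um <- as.numeric(pixel_size_um)
    if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
      stop("pixel_size_um must be > 0", call. = FALSE)
    }
    return(pixel_size_um)
  }
  if (is.null(objective)) {
    stop("supply pixel_size_um or an objective label", call. = FALSE)
  }
  objectivePixelSize(objective)
}

# normalise a decoded raster (values 0..1) to a h x w x 3 array on 0..255
.asRGB255 <- function(raster) {
  if (is.matrix(raster)) raster <- array(rep(raster, 3L), c(dim(raster), 3L))
  if (dim(raster)[3] >= 4L) raster <- raster[, , 1:3, drop = FALSE]
  if (dim(raster)[3] == 2L) {                       # grey + alpha
    raster <- array(rep(raster[, , 1L], 3L), c(dim(raster)[1:2], 3L))
  }
  raster * 255
}

#' Read a calibrated filter scan
#'
#' Reads an 8-bit RGB TIFF or PNG scan of a filter membrane and attaches
#' its pixel calibration, either directly in um/pixel or via the objective
#' label used for acquisition. Greyscale rasters are promoted to RGB;
#' alpha channels are dropped. Multi-page TIFFs are z-stacks and must be
#' read with [loadZStack()].
#'
#' @param path path to a TIFF or PNG file.
#' @param pixel_size_um micrometres per pixel; overrides \code{objective}.
#' @param objective objective label (\code{"2.5x"}, \code{"5x"},
#'   \code{"10x"}) used when \code{pixel_size_um} is missing.
#' @param meta optional acquisition metadata list.
#' @return a [ScanImage].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(runif(48), c(4, 4, 3)), f)
#' loadScan(f, objective = "5x")
#' @export
loadScan <- function(path, pixel_size_um = NULL, objective = NULL,
                     meta = list()) {
  ps <- .resolvePixelSize(pixel_size_um, objective)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raster <- switch(ext,
    tif = ,
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (length(pages) > 1L) {
        stop("multi-page TIFF is a z-stack; use loadZStack()", call. = FALSE)
      }
      pages[[1L]]
    },
    png = png::readPNG(path),
    stop("unsupported image format '", ext, "' (use TIFF or PNG)",
         call. = FALSE)
  )
  scanImage(.asRGB255(raster), ps, source_id = path, meta = meta)
}

#' Read a multi-plane z-stack
#'
#' Reads a multi-page TIFF as an ordered [ZStack]; single-page files yield
#' a one-plane stack. All planes share the supplied calibration.
#'
#' @inheritParams loadScan
#' @return a [ZStack].
#' @seealso [maxProject()]
#' @export
loadZStack <- function(path, pixel_size_um = NULL, objective = NULL,
                       meta = list()) {
  ps <- .resolvePixelSize(pixel_size_um, objective)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  planes <- lapply(seq_along(pages), function(i) {
    scanImage(.asRGB255(pages[[i]]), ps,
              source_id = sprintf("%s#%d", path, i), meta = meta)
  })
  new("ZStack", planes = planes)
}

#' Maximum projection of a z-stack
#'
#' Collapses a [ZStack] to a single 2D image by taking, per channel and
#' pixel position, the maximum value across planes. Used for 10x scans
#' whose depth of field is smaller than the particle relief. The
#' projection is idempotent and independent of plane order.
#'
#' @param stack a [ZStack] (a single [ScanImage] is returned unchanged).
#' @return a [ScanImage] with the pixel size of the input planes.
#' @export
maxProject <- function(stack) {
  if (is(stack, "ScanImage")) return(stack)
  stopifnot(is(stack, "ZStack"))
  px <- stack@planes[[1L]]@pixels
  for (p in stack@planes[-1L]) px <- pmax(px, p@pixels)
  scanImage(px, stack@planes[[1L]]@pixelSize,
            source_id = sub("#1$", "", stack@planes[[1L]]@sourceId),
            meta = stack@planes[[1L]]@meta)
}

#' Write a scan to disk
#'
#' Writes a [ScanImage] as an 8-bit PNG or TIFF (decided by the file
#' extension).
#'
#' @param image a [ScanImage].
#' @param path output path ending in \code{.png}, \code{.tif} or
#'   \code{.tiff}.
#' @return the path, invisibly.
#' @export
writeScan <- function(image, path) {
  stopifnot(is(image, "ScanImage"))
  raster <- image@pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(raster, path),
    tif = ,
    tiff = tiff::writeTIFF(raster, path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Export a binary mask
#'
#' Writes a [BinaryMask] as a single-channel 8-bit PNG or TIFF with values
#' 0 (background) and 255 (particle).
#'
#' @param mask a [BinaryMask].
#' @param path output path ending in \code{.png}, \code{.tif} or
#'   \code{.tiff}.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  raster <- matrix(as.numeric(mask@grid), nrow(mask@grid), ncol(mask@grid))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(raster, path),
    tif = ,
    tiff = tiff::writeTIFF(raster, path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}
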