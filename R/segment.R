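#' Per-pixel brightness channel
#'
#' The brightness of an RGB pixel is the maximum of its three channel
#' values, matching the definition used for total particle brightness.
#'
#' @param image a [ScanImage].
#' @return numeric matrix of brightness values in \code{[0, 255]}.
#' @export
brightnessChannel <- function(image) {
  stopifnot(is(image, "ScanImage"))
  px <- image@pixels
  pmax(px[, , 1L], px[, , 2L], px[, , 3L])
}

#' Separate particles from background
#'
#' Thresholds the brightness channel of a scan into a binary particle
#' mask. With no explicit threshold, a global Otsu threshold is computed
#' on the 256-level brightness histogram and shifted by \code{auto_offset};
#' this replaces interactive brightness/contrast editing with a
#' deterministic, recorded cut. Pixels strictly brighter than the
#' effective threshold become foreground.
#'
#' @param image a [ScanImage].
#' @param threshold explicit brightness cut in \code{[0, 255]}, or
#'   \code{NULL} for automatic (Otsu) thresholding.
#' @param auto_offset signed brightness offset added to the automatic
#'   threshold (ignored when \code{threshold} is given).
#' @return a [BinaryMask] with \code{thresholdUsed} recording the cut.
#' @examples
#' img <- scanImage(array(c(rep(5, 32), rep(200, 16)), c(4, 4, 3)), 5)
#' sum(maskGrid(binarize(img, threshold = 100)))
#' @export
binarize <- function(image, threshold = NULL, auto_offset = 0) {
  stopifnot(is(image, "ScanImage"))
  b <- brightnessChannel(image)
  if (!is.null(threshold)) {
    if (!is.finite(threshold) || threshold < 0 || threshold > 255) {
      stop("threshold must lie in [0, 255]", call. = FALSE)
    }
    eff <- as.numeric(threshold)
  } else {
    # EBImage::otsu works on [0,1]-scaled data with a discrete histogram
    eff <- 255 * EBImage::otsu(EBImage::Image(b / 255), range = c(0, 1),
                               levels = 256L) + auto_offset
    eff <- min(max(eff, 0), 255)
  }
  new("BinaryMask", grid = b > eff, thresholdUsed = eff,
      pixelSize = image@pixelSize)
}

#' Remove single-pixel artefacts by morphological opening
#'
#' Applies a binary "open" (erosion then dilation) with a square
#' structuring element of edge \code{2 * opening_radius + 1}. Isolated
#' pixels left over from segmentation are removed; structures wider than
#' the element survive with at most boundary-band erosion. Note that
#' genuine particles smaller than the element are also erased, which is
#' why the default pipeline removes isolated pixels through the
#' minimum-area filter of [labelParticles()] instead (see the package
#' vignette).
#'
#' @param mask a [BinaryMask].
#' @param opening_radius radius of the structuring element in pixels
#'   (>= 1; the default 1 gives a 3x3 element).
#' @return the opened [BinaryMask].
#' @export
cleanMask <- function(mask, opening_radius = 1) {
  stopifnot(is(mask, "BinaryMask"))
  if (opening_radius < 1) stop("opening_radius must be >= 1", call. = FALSE)
  size <- 2L * as.integer(opening_radius) + 1L
  opened <- EBImage::opening(
    matrix(as.numeric(mask@grid), nrow(mask@grid), ncol(mask@grid)),
    EBImage::makeBrush(size, shape = "box")
  )
  new("BinaryMask", grid = opened > 0.5, thresholdUsed = mask@thresholdUsed,
      pixelSize = mask@pixelSize)
}

# merge 4-connected labels that touch diagonally into 8-connected components
.merge8 <- function(lab) {
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  a <- lab[-nrow(lab), -ncol(lab)]; b <- lab[-1L, -1L]       # \ diagonal
  c1 <- lab[-nrow(lab), -1L]; d <- lab[-1L, -ncol(lab)]      # / diagonal
  keep1 <- a > 0 & b > 0 & a != b
  keep2 <- c1 > 0 & d > 0 & c1 != d
  edges <- rbind(cbind(a[keep1], b[keep1]), cbind(c1[keep2], d[keep2]))
  if (nrow(edges) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nlab - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  relab <- c(0L, comp)                      # index by label + 1
  matrix(relab[lab + 1L], nrow(lab), ncol(lab))
}

#' Label connected particles in a mask
#'
#' Finds 8-connected foreground components, discards components smaller
#' than \code{min_area_px} pixels and returns the survivors as pixel
#' coordinate sets in deterministic raster order (component containing
#' the first foreground pixel in row-major scan order first). The default
#' minimum area of 2 px removes isolated single pixels; at 5 um/pixel it
#' corresponds to a reliable detection floor of roughly 10 um.
#'
#' @param mask a [BinaryMask].
#' @param min_area_px minimum component size in pixels (>= 1, default 2).
#' @return list of integer matrices with columns \code{row}, \code{col},
#'   one per particle.
#' @export
labelParticles <- function(mask, min_area_px = 2) {
  stopifnot(is(mask, "BinaryMask"))
  if (min_area_px < 1) stop("min_area_px must be >= 1", call. = FALSE)
  if (!any(mask@grid)) return(list())
  lab <- EBImage::bwlabel(matrix(as.numeric(mask@grid),
                                 nrow(mask@grid), ncol(mask@grid)))
  lab <- .merge8(lab)
  idx <- which(lab > 0, arr.ind = TRUE)
  labels <- lab[lab > 0]
  comps <- split.data.frame(idx, labels)
  sizes <- vapply(comps, nrow, integer(1))
  comps <- comps[sizes >= min_area_px]
  if (length(comps) == 0L) return(list())
  # raster order: first pixel of the component in row-major scan
  first <- vapply(comps, function(m) {
    min((m[, 1L] - 1L) * ncol(lab) + m[, 2L])
  }, numeric(1))
  comps <- comps[order(first)]
  lapply(unname(comps), function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(NULL, c("row", "col"))
    m
  })
}
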