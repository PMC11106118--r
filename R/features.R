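# --- internal geometry helpers (pixel units) --------------------------------

# maximum caliper (Feret) diameter of a pixel set, in pixel units.
# Pixels are modelled as unit squares: the Feret diameter is the maximum
# pairwise distance over the corners of the pixels on the convex hull of
# the pixel centers (the hull of all corners is the Minkowski sum of the
# center hull with a unit square, so hull-pixel corners suffice). For a
# single pixel this gives sqrt(2).
.feretMaxPx <- function(coords) {
  xy <- cbind(coords[, 2L], coords[, 1L])      # x = col, y = row
  hull <- if (nrow(xy) > 2L) xy[grDevices::chull(xy), , drop = FALSE] else xy
  corners <- rbind(
    hull + rep(c(-0.5, -0.5), each = nrow(hull)),
    hull + rep(c(-0.5,  0.5), each = nrow(hull)),
    hull + rep(c( 0.5, -0.5), each = nrow(hull)),
    hull + rep(c( 0.5,  0.5), each = nrow(hull))
  )
  sqrt(max(stats::dist(corners)^2))
}

# Crofton-style perimeter estimate, in pixel units: foreground/background
# transitions are counted along the horizontal, vertical and both diagonal
# scan-line families (diagonal lines have spacing 1/sqrt(2)) and combined
# with the Cauchy-Crofton formula P = (pi/8) * (n_h + n_v + n_d/sqrt(2)).
# Exact for digitised discs; ~5% low for axis-aligned squares.
.croftonPerimeterPx <- function(coords) {
  r0 <- min(coords[, 1L]); c0 <- min(coords[, 2L])
  nr <- max(coords[, 1L]) - r0 + 3L
  nc <- max(coords[, 2L]) - c0 + 3L
  m <- matrix(FALSE, nr, nc)
  m[cbind(coords[, 1L] - r0 + 2L, coords[, 2L] - c0 + 2L)] <- TRUE
  nh <- sum(m[, -1L] != m[, -ncol(m)])
  nv <- sum(m[-1L, ] != m[-nrow(m), ])
  nd <- sum(m[-nrow(m), -ncol(m)] != m[-1L, -1L]) +
        sum(m[-nrow(m), -1L] != m[-1L, -ncol(m)])
  (pi / 8) * (nh + nv + nd / sqrt(2))
}

# fitted-ellipse axes from second central moments, in pixel units.
# Each pixel contributes its own second moment of 1/12 (unit square), so
# a single pixel yields equal axes and aspect ratio 1. Full axis lengths
# are 4 * sqrt(eigenvalue), the ellipse with matching area and moments.
.ellipseAxesPx <- function(coords) {
  x <- coords[, 2L]; y <- coords[, 1L]
  n <- length(x)
  if (n == 1L) {
    cxx <- cyy <- 1 / 12
    cxy <- 0
  } else {
    cxx <- stats::var(x) * (n - 1) / n + 1 / 12
    cyy <- stats::var(y) * (n - 1) / n + 1 / 12
    cxy <- stats::cov(x, y) * (n - 1) / n
  }
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L), symmetric = TRUE)$values
  ev <- pmax(ev, 1e-12)
  c(major = 4 * sqrt(ev[1L]), minor = 4 * sqrt(ev[2L]))
}

# --- exported measurements ---------------------------------------------------

#' Morphological features of one particle
#'
#' Measures a labelled particle (a pixel-coordinate set from
#' [labelParticles()]) on the binary image: area, Crofton-style perimeter,
#' maximum Feret (caliper) diameter over the convex hull of the pixel
#' outlines, fitted-ellipse major/minor axes from second central moments,
#' aspect ratio and circularity \eqn{4\pi A / P^2} (clipped to 1 to absorb
#' discretisation overshoot on small discs). All lengths are returned in
#' micrometres using the supplied pixel calibration.
#'
#' @param component integer matrix with columns \code{row}, \code{col}.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @return named list with \code{area_um2}, \code{perimeter_um},
#'   \code{feret_max_um}, \code{major_axis_um}, \code{minor_axis_um},
#'   \code{aspect_ratio}, \code{circularity}.
#' @examples
#' sq <- as.matrix(expand.grid(row = 1:10, col = 1:10))
#' m <- measureMorphology(sq, 5)
#' m$area_um2       # 2500
#' m$feret_max_um   # ~70.7 (diagonal)
#' @export
measureMorphology <- function(component, pixel_size_um) {
  component <- as.matrix(component)
  if (nrow(component) == 0L) stop("empty component", call. = FALSE)
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be > 0", call. = FALSE)
  }
  area <- nrow(component) * pixel_size_um^2
  per <- .croftonPerimeterPx(component) * pixel_size_um
  axes <- .ellipseAxesPx(component) * pixel_size_um
  list(
    area_um2 = area,
    perimeter_um = per,
    feret_max_um = .feretMaxPx(component) * pixel_size_um,
    major_axis_um = unname(axes["major"]),
    minor_axis_um = unname(axes["minor"]),
    aspect_ratio = unname(axes["major"] / axes["minor"]),
    circularity = min(1, 4 * pi * area / per^2)
  )
}

#' Fluorescence features of one particle
#'
#' Reads the original colour image under a particle footprint and computes
#' the total particle brightness (TPB, the mean over particle pixels of
#' the per-pixel brightness max(R, G, B)), the mean channel values, and
#' the colour fractions (each channel mean divided by the sum of the
#' three). The fractions sum to 1 whenever the particle is not entirely
#' black.
#'
#' @param component integer matrix with columns \code{row}, \code{col};
#'   all pixels must lie inside the image.
#' @param image the original colour [ScanImage].
#' @return named list with \code{tpb}, \code{mean_r}, \code{mean_g},
#'   \code{mean_b}, \code{red_fraction}, \code{green_fraction},
#'   \code{blue_fraction}.
#' @export
measureFluorescence <- function(component, image) {
  stopifnot(is(image, "ScanImage"))
  component <- as.matrix(component)
  if (nrow(component) == 0L) stop("empty component", call. = FALSE)
  d <- dim(image@pixels)
  if (any(component[, 1L] < 1L) || any(component[, 1L] > d[1L]) ||
      any(component[, 2L] < 1L) || any(component[, 2L] > d[2L])) {
    stop("component pixel outside image bounds", call. = FALSE)
  }
  r <- image@pixels[, , 1L][component]
  g <- image@pixels[, , 2L][component]
  b <- image@pixels[, , 3L][component]
  means <- c(mean(r), mean(g), mean(b))
  tot <- sum(means)
  fr <- if (tot > 0) means / tot else c(NA_real_, NA_real_, NA_real_)
  list(
    tpb = mean(pmax(r, g, b)),
    mean_r = means[1L], mean_g = means[2L], mean_b = means[3L],
    red_fraction = fr[1L], green_fraction = fr[2L], blue_fraction = fr[3L]
  )
}
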