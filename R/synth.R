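# truncated-normal sampling by inverse CDF; errors when the truncation
# window carries essentially no mass (misconfigured spec)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-8) {
    stop(sprintf("truncation [%g, %g] has no mass for normal(%g, %g)",
                 lo, hi, mean, sd), call. = FALSE)
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

.rtrunclnorm <- function(n, median, log_sd, lo, hi) {
  mu <- log(median)
  plo <- stats::plnorm(lo, mu, log_sd)
  phi <- stats::plnorm(hi, mu, log_sd)
  if (phi - plo < 1e-8) {
    stop(sprintf("size truncation [%g, %g] has no mass for log-normal median %g",
                 lo, hi, median), call. = FALSE)
  }
  stats::qlnorm(stats::runif(n, plo, phi), mu, log_sd)
}

#' Describe one synthetic particle class
#'
#' A generative description of a particle population class: its truth
#' label (MP or PNO), shape mixture, log-normal size distribution
#' (truncated to 5--5000 um), truncated-normal total-particle-brightness
#' distribution on \code{[0, 255]} and red-fraction distribution.
#'
#' @param label class name (e.g. a polymer or a matrix particle type).
#' @param truth \code{"MP"} or \code{"PNO"}.
#' @param n number of particles to draw for this class.
#' @param shape_probs named numeric over \code{fragment}, \code{spheroid},
#'   \code{fibre}; must sum to 1.
#' @param size_median_um,size_log_sd log-normal size parameters.
#' @param tpb_mean,tpb_sd brightness distribution parameters.
#' @param red_mean,red_sd red-fraction distribution parameters.
#' @return a \code{particleClassSpec} list.
#' @export
particleClassSpec <- function(label, truth, n, shape_probs,
                              size_median_um, size_log_sd,
                              tpb_mean, tpb_sd, red_mean, red_sd) {
  stopifnot(truth %in% c("MP", "PNO"), length(n) == 1L, n >= 0)
  shape_probs <- unlist(shape_probs)[c("fragment", "spheroid", "fibre")]
  shape_probs[is.na(shape_probs)] <- 0
  names(shape_probs) <- c("fragment", "spheroid", "fibre")
  if (abs(sum(shape_probs) - 1) > 1e-6) {
    stop("shape_probs must sum to 1", call. = FALSE)
  }
  structure(list(label = label, truth = truth, n = as.integer(n),
                 shape_probs = shape_probs,
                 size_median_um = size_median_um, size_log_sd = size_log_sd,
                 tpb_mean = tpb_mean, tpb_sd = tpb_sd,
                 red_mean = red_mean, red_sd = red_sd),
            class = "particleClassSpec")
}

#' Packaged reference population specification
#'
#' Reads the packaged fixture configuration describing six bright
#' MP classes and four weak/off-colour natural-particle classes
#' (fishbone, chitin, mussel shell, cotton), 100 particles each. The
#' numeric parameters are synthetic assumptions documented in the YAML
#' file and the package vignette.
#'
#' @return list of [particleClassSpec()] objects.
#' @export
referencePopulationSpec <- function() {
  path <- system.file("extdata", "reference_population.yaml",
                      package = "mpscreen", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  lapply(cfg$classes, function(cl) {
    particleClassSpec(cl$label, cl$truth, cl$count, cl$shape_probs,
                      cl$size_median_um, cl$size_log_sd,
                      cl$tpb_mean, cl$tpb_sd, cl$red_mean, cl$red_sd)
  })
}

#' Draw a labelled particle population
#'
#' Samples particle parameter records from a list of class
#' specifications. A single seeded random stream is consumed class by
#' class in list order, so a fixed seed and spec give identical output.
#' Class counts are exact; sizes, brightness and colour are drawn from
#' the class distributions with their stated truncations. Aspect ratios
#' are drawn per shape: near-isometric for spheroids, moderate for
#' fragments, 5--30 for fibres.
#'
#' @param classes list of [particleClassSpec()] objects.
#' @param seed integer seed.
#' @return data.frame with one row per particle: \code{class_label},
#'   \code{truth}, \code{shape_class}, \code{size_um}, \code{aspect},
#'   \code{tpb}, \code{red_fraction}.
#' @export
samplePopulation <- function(classes, seed = 1) {
  set.seed(seed)
  rows <- lapply(classes, function(cl) {
    n <- cl$n
    if (n == 0L) return(NULL)
    shape <- sample(names(cl$shape_probs), n, replace = TRUE,
                    prob = cl$shape_probs)
    size <- .rtrunclnorm(n, cl$size_median_um, cl$size_log_sd, 5, 5000)
    aspect <- numeric(n)
    aspect[shape == "spheroid"] <- stats::runif(sum(shape == "spheroid"),
                                                1.0, 1.25)
    aspect[shape == "fragment"] <- stats::runif(sum(shape == "fragment"),
                                                1.35, 2.8)
    aspect[shape == "fibre"] <- stats::runif(sum(shape == "fibre"), 5, 30)
    tpb <- .rtruncnorm(n, cl$tpb_mean, cl$tpb_sd, 0, 255)
    red <- .rtruncnorm(n, cl$red_mean, cl$red_sd, 0.02, 0.98)
    data.frame(class_label = cl$label, truth = cl$truth, shape_class = shape,
               size_um = size, aspect = aspect, tpb = tpb,
               red_fraction = red, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(class_label = character(), truth = character(),
                      shape_class = character(), size_um = numeric(),
                      aspect = numeric(), tpb = numeric(),
                      red_fraction = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Packaged labelled reference fixture set
#'
#' Draws the packaged reference population (ten classes, 100 particles
#' each) with a fixed seed: the offline stand-in for a labelled reference
#' particle measurement used to validate the default classifier.
#'
#' @param seed integer seed.
#' @return data.frame as returned by [samplePopulation()].
#' @export
referenceFixtureSet <- function(seed = 1) {
  samplePopulation(referencePopulationSpec(), seed = seed)
}

#' Describe the rendering of a synthetic filter image
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um pixel pitch in micrometres.
#' @param bg_mean,bg_sd background brightness mean and per-channel noise
#'   SD on the 8-bit scale.
#' @param gap_px minimum inter-particle gap in pixels (well-separated
#'   placement).
#' @param pixel_noise_sd per-pixel brightness noise SD inside particles.
#' @param patches_per_mp expected number of diffuse matrix-residue
#'   patches per megapixel (low-contrast Gaussian blobs; default 0).
#' @return a \code{renderSpec} list.
#' @export
renderSpec <- function(width_px = 1024, height_px = 1024, pixel_size_um = 5,
                       bg_mean = 8, bg_sd = 3, gap_px = 4,
                       pixel_noise_sd = 6, patches_per_mp = 0) {
  stopifnot(width_px >= 8, height_px >= 8, pixel_size_um > 0, bg_sd >= 0,
            gap_px >= 1)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um, bg_mean = bg_mean,
                 bg_sd = bg_sd, gap_px = gap_px,
                 pixel_noise_sd = pixel_noise_sd,
                 patches_per_mp = patches_per_mp),
            class = "renderSpec")
}

# rasterise one particle footprint around (cy, cx); returns row/col matrix
.footprintPixels <- function(shape, len_px, wid_px, theta, cy, cx, nr, nc) {
  h <- ceiling(len_px / 2) + 1L
  rows <- max(1L, floor(cy - h)):min(nr, ceiling(cy + h))
  cols <- max(1L, floor(cx - h)):min(nc, ceiling(cx + h))
  gx <- rep(cols, each = length(rows)) - cx
  gy <- rep(rows, times = length(cols)) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  a <- len_px / 2
  b <- max(wid_px / 2, 0.5)           # keep at least one pixel of width
  inside <- switch(shape,
    spheroid = (u / a)^2 + (v / b)^2 <= 1,
    fragment = abs(u) <= a & abs(v) <= b,
    fibre = {
      core <- pmax(abs(u) - pmax(a - b, 0), 0)
      core^2 + v^2 <= b^2
    },
    stop("unknown shape class '", shape, "'", call. = FALSE)
  )
  if (!any(inside)) {
    return(matrix(c(round(cy), round(cx)), 1L, 2L,
                  dimnames = list(NULL, c("row", "col"))))
  }
  cbind(row = rep(rows, times = length(cols))[inside],
        col = rep(cols, each = length(rows))[inside])
}

#' Render a synthetic stained-filter image
#'
#' Draws a particle population onto a noisy dim background as bright
#' shapes (ellipses for spheroids, rectangles for fragments, capsules for
#' fibres) at random orientations, with per-pixel brightness drawn around
#' each particle's TPB and channel values split according to its colour
#' fractions so that the rendered TPB and red fraction match the
#' generating parameters. Particles are placed on a shuffled grid whose
#' cell size guarantees the requested minimum gap, so footprints are
#' disjoint; an image too small for the requested population raises a
#' configuration error. The ground-truth sidecar records each particle's
#' generating parameters and exact footprint.
#'
#' @param particles data.frame from [samplePopulation()].
#' @param spec a [renderSpec()].
#' @param seed integer seed; fixed seed and inputs give a bit-identical
#'   image.
#' @return list with \code{image} (a [ScanImage]) and \code{truth} (a
#'   data.frame with one row per rendered particle, including a
#'   \code{footprint} list-column of linear pixel indices).
#' @export
renderFilterImage <- function(particles, spec = renderSpec(), seed = 1) {
  set.seed(seed)
  nr <- spec$height_px; nc <- spec$width_px
  n <- nrow(particles)
  clip01 <- function(x) pmin(pmax(x, 0), 255)

  # background with optional diffuse matrix-residue patches
  ch <- lapply(1:3, function(i) {
    matrix(clip01(stats::rnorm(nr * nc, spec$bg_mean, spec$bg_sd)), nr, nc)
  })
  n_patch <- stats::rpois(1L, spec$patches_per_mp * nr * nc / 1e6)
  if (n_patch > 0) {
    for (i in seq_len(n_patch)) {
      pcy <- stats::runif(1, 1, nr); pcx <- stats::runif(1, 1, nc)
      sig <- stats::runif(1, 10, 40); amp <- stats::runif(1, 5, 15)
      rows <- max(1L, floor(pcy - 3 * sig)):min(nr, ceiling(pcy + 3 * sig))
      cols <- max(1L, floor(pcx - 3 * sig)):min(nc, ceiling(pcx + 3 * sig))
      bump <- amp * exp(-(outer((rows - pcy)^2, (cols - pcx)^2, "+")) /
                          (2 * sig^2))
      for (k in 1:3) ch[[k]][rows, cols] <- clip01(ch[[k]][rows, cols] + bump)
    }
  }

  truth <- NULL
  if (n > 0L) {
    len_px <- particles$size_um / spec$pixel_size_um
    wid_px <- len_px / particles$aspect
    cell <- ceiling(max(len_px)) + spec$gap_px
    nx <- nc %/% cell; ny <- nr %/% cell
    if (nx * ny < n) {
      stop(sprintf(paste("cannot place %d particles with gap %d px in a",
                         "%d x %d image (max %d cells of %d px)"),
                   n, spec$gap_px, nc, nr, nx * ny, cell), call. = FALSE)
    }
    cells <- sample(nx * ny, n)
    cellx <- (cells - 1L) %% nx
    celly <- (cells - 1L) %/% nx
    theta <- stats::runif(n, 0, pi)
    jit <- pmax((cell - spec$gap_px - len_px) / 2, 0)
    cy <- celly * cell + cell / 2 + stats::runif(n, -1, 1) * jit
    cx <- cellx * cell + cell / 2 + stats::runif(n, -1, 1) * jit
    fps <- vector("list", n)
    for (i in seq_len(n)) {
      fp <- .footprintPixels(particles$shape_class[i], len_px[i], wid_px[i],
                             theta[i], cy[i], cx[i], nr, nc)
      fps[[i]] <- fp
      bb <- clip01(stats::rnorm(nrow(fp), particles$tpb[i],
                                spec$pixel_noise_sd))
      fr <- particles$red_fraction[i]
      fracs <- c(fr, (1 - fr) * 0.55, (1 - fr) * 0.45)
      scale <- fracs / max(fracs)
      for (k in 1:3) ch[[k]][fp] <- clip01(bb * scale[k])
    }
    truth <- data.frame(particle_id = sprintf("gt%04d", seq_len(n)),
                        particles, center_row = cy, center_col = cx,
                        n_px = vapply(fps, nrow, integer(1)),
                        stringsAsFactors = FALSE)
    truth$footprint <- lapply(fps, function(fp) {
      (fp[, "col"] - 1L) * nr + fp[, "row"]
    })
  } else {
    truth <- data.frame(particle_id = character(), n_px = integer(),
                        stringsAsFactors = FALSE)
    truth$footprint <- list()
  }

  px <- array(0, c(nr, nc, 3L))
  for (k in 1:3) px[, , k] <- ch[[k]]
  img <- scanImage(px, spec$pixel_size_um,
                   source_id = sprintf("synthetic-seed%d", seed))
  list(image = img, truth = truth)
}

#' Export a ground-truth sidecar
#'
#' Writes the ground-truth table of [renderFilterImage()] as a CSV next
#' to a rendered image (the pixel footprints are serialised as
#' semicolon-separated linear indices).
#'
#' @param truth ground-truth data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  flat <- truth
  flat$footprint <- vapply(truth$footprint, paste, character(1),
                           collapse = ";")
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

# nominal per-particle mass of a blank-contamination category, from the
# geometric-mean size of the class and the category's shape model
.categoryUnitMass <- function(size_class, shape_class,
                              scheme = sizeClassScheme(),
                              density_g_cm3 = 1.05) {
  b <- sizeBoundaries(scheme)
  labels <- sizeClassLabels(scheme)
  i <- match(size_class, labels)
  g <- sqrt(b[i] * b[i + 1L])
  vol <- switch(shape_class,
    spheroid = pi / 6 * g^3,
    fragment = g * (g / 2)^2,
    fibre = g * pi * (g / 20)^2
  )
  estimateMass(vol, density_g_cm3)
}

#' Simulate a series of procedural blanks
#'
#' Generates uncorrected blank [SampleSummary] objects with
#' Poisson-distributed contamination counts. The default contamination
#' profile is dominated by rounded (spheroid) particles of medium
#' fluorescence in the 10--100 um classes, with occasional fibres, the
#' pattern typical of airborne and reagent contamination. Mass estimates
#' use a nominal per-particle mass from each category's geometric-mean
#' size.
#'
#' @param seed integer seed.
#' @param n_blanks number of blanks (>= 1, default 3 per sample series).
#' @param rates named numeric of Poisson means per category, names in the
#'   form \code{"size|shape|fluor"}; \code{NULL} for the default profile.
#' @param scheme a [SizeClassScheme].
#' @param density_g_cm3 density for the nominal masses.
#' @return list of \code{n_blanks} uncorrected [SampleSummary] objects.
#' @export
blankSeries <- function(seed = 1, n_blanks = 3, rates = NULL,
                        scheme = sizeClassScheme(), density_g_cm3 = 1.05) {
  if (n_blanks < 1L) stop("n_blanks must be >= 1", call. = FALSE)
  if (is.null(rates)) {
    rates <- c("10-50|spheroid|medium" = 2, "50-100|spheroid|medium" = 1,
               "100-500|fibre|medium" = 0.3)
  }
  set.seed(seed)
  grid <- .categoryGrid(scheme)
  gkey <- .categoryKey(grid)
  if (!all(names(rates) %in% gkey)) {
    stop("unknown category in rates: ",
         paste(setdiff(names(rates), gkey), collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(n_blanks), function(i) {
    cc <- grid
    cc$raw_count <- 0
    cc$raw_mass_ug <- 0
    idx <- match(names(rates), gkey)
    cnt <- stats::rpois(length(rates), rates)
    cc$raw_count[idx] <- cnt
    cc$raw_mass_ug[idx] <- cnt * mapply(.categoryUnitMass,
                                        cc$size_class[idx],
                                        cc$shape_class[idx],
                                        MoreArgs = list(
                                          scheme = scheme,
                                          density_g_cm3 = density_g_cm3))
    cc$corrected_count <- cc$raw_count
    cc$corrected_mass_ug <- cc$raw_mass_ug
    cc$censored_count <- FALSE
    cc$censored_mass <- FALSE
    new("SampleSummary", sampleId = sprintf("blank-%d", i),
        categories = cc, corrected = FALSE)
  })
}
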