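test_that("scan loading applies objective calibration and validates input", {
  expect_equal(objectivePixelSize("5x"), 5)
  expect_equal(objectivePixelSize("2.5x"), 10)
  expect_equal(objectivePixelSize("10x"), 1)
  expect_error(objectivePixelSize("40x"), "unknown objective")

  f <- tempfile(fileext = ".png")
  set.seed(11)
  px <- array(sample(0:255, 4 * 6 * 3, replace = TRUE), c(4, 6, 3))
  writeScan(scanImage(px, 5), f)
  img <- loadScan(f, objective = "5x")
  expect_s4_class(img, "ScanImage")
  expect_equal(pixelSize(img), 5)
  expect_equal(scanPixels(img), px, tolerance = 1e-12)

  expect_error(loadScan(f, pixel_size_um = 0), "pixel_size_um")
  expect_error(loadScan(f), "objective")
  expect_error(loadScan(tempfile(fileext = ".png"), pixel_size_um = 5),
               "not found")
})

test_that("multi-page TIFFs round-trip as z-stacks", {
  f <- tempfile(fileext = ".tif")
  a <- array(round(runif(4 * 4 * 3) * 255) / 255, c(4, 4, 3))
  b <- array(round(runif(4 * 4 * 3) * 255) / 255, c(4, 4, 3))
  tiff::writeTIFF(list(a, b), f, bits.per.sample = 8L)
  zs <- loadZStack(f, pixel_size_um = 1)
  expect_equal(nPlanes(zs), 2)
  expect_error(loadScan(f, pixel_size_um = 1), "z-stack")
})

test_that("maximum projection is the per-channel pixelwise maximum", {
  set.seed(3)
  mk <- function() scanImage(array(runif(60, 0, 255), c(4, 5, 3)), 1)
  a <- mk(); b <- mk()
  zero <- scanImage(array(0, c(4, 5, 3)), 1)

  one <- maxProject(new("ZStack", planes = list(a)))
  expect_equal(scanPixels(one), scanPixels(a))
  withzero <- maxProject(new("ZStack", planes = list(a, zero)))
  expect_equal(scanPixels(withzero), scanPixels(a))
  # idempotent and order-independent
  ab <- maxProject(new("ZStack", planes = list(a, b)))
  ba <- maxProject(new("ZStack", planes = list(b, a)))
  aab <- maxProject(new("ZStack", planes = list(a, a, b)))
  expect_equal(scanPixels(ab), scanPixels(ba))
  expect_equal(scanPixels(ab), scanPixels(aab))
  expect_equal(scanPixels(ab), pmax(scanPixels(a), scanPixels(b)))
  # mismatched plane dimensions are rejected by the class
  small <- scanImage(array(0, c(2, 2, 3)), 1)
  expect_error(new("ZStack", planes = list(a, small)), "dimensions")
})

test_that("binarize thresholds the brightness channel deterministically", {
  dark <- greyScan(matrix(0, 8, 8))
  expect_equal(sum(maskGrid(binarize(dark, threshold = 10))), 0)
  expect_error(binarize(dark, threshold = 300), "\\[0, 255\\]")

  # auto threshold recovers a rendered bright disc within a 1-px band
  out <- renderFilterImage(discPopulation(1, size_um = 100),
                           renderSpec(width_px = 64, height_px = 64,
                                      bg_sd = 0, pixel_noise_sd = 0),
                           seed = 4)
  mask <- binarize(out$image)
  got <- which(maskGrid(mask))
  want <- out$truth$footprint[[1]]
  expect_setequal(got, want)     # noise-free render: exact footprint

  # monotone: raising the threshold never adds foreground pixels
  set.seed(8)
  img <- greyScan(matrix(runif(400, 0, 255), 20, 20))
  thresholds <- c(20, 60, 120, 200)
  masks <- lapply(thresholds, function(t) maskGrid(binarize(img, t)))
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i]] | !masks[[i + 1]]))
  }
})

test_that("cleanMask removes isolated pixels but keeps wide structures", {
  g <- matrix(FALSE, 30, 30)
  g[5, 5] <- TRUE                       # isolated pixel
  g[10:29, 10:29] <- TRUE               # 20 x 20 square
  mask <- new("BinaryMask", grid = g, thresholdUsed = 0, pixelSize = 5)
  opened <- cleanMask(mask, opening_radius = 1)
  expect_false(maskGrid(opened)[5, 5])
  expect_equal(sum(maskGrid(opened)), 400)

  empty <- new("BinaryMask", grid = matrix(FALSE, 5, 5), thresholdUsed = 0,
               pixelSize = 5)
  expect_equal(sum(maskGrid(cleanMask(empty))), 0)
  expect_error(cleanMask(mask, opening_radius = 0), "opening_radius")
})

test_that("labelParticles uses 8-connectivity, area filter, raster order", {
  g <- matrix(FALSE, 20, 20)
  g[2, 2] <- TRUE; g[3, 3] <- TRUE      # diagonal pair: one component
  g[10:12, 10:12] <- TRUE
  mask <- new("BinaryMask", grid = g, thresholdUsed = 0, pixelSize = 5)
  comps <- labelParticles(mask, min_area_px = 2)
  expect_length(comps, 2)
  expect_equal(nrow(comps[[1]]), 2)     # top-left component first
  expect_equal(nrow(comps[[2]]), 9)

  # two discs separated by background: two components
  g2 <- matrix(FALSE, 30, 30)
  g2[3:7, 3:7] <- TRUE; g2[3:7, 15:19] <- TRUE
  comps2 <- labelParticles(new("BinaryMask", grid = g2, thresholdUsed = 0,
                               pixelSize = 5))
  expect_length(comps2, 2)

  # single pixel fails the default minimum area
  g3 <- matrix(FALSE, 5, 5); g3[3, 3] <- TRUE
  m3 <- new("BinaryMask", grid = g3, thresholdUsed = 0, pixelSize = 5)
  expect_length(labelParticles(m3, min_area_px = 2), 0)
  expect_length(labelParticles(m3, min_area_px = 1), 1)
})

test_that("morphology of canonical shapes matches closed forms", {
  m <- measureMorphology(squareComponent(10), 5)
  expect_equal(m$area_um2, 2500)
  expect_equal(m$feret_max_um, 10 * sqrt(2) * 5, tolerance = 1e-12)
  expect_equal(m$aspect_ratio, 1, tolerance = 1e-9)
  expect_true(m$circularity > 0.7 && m$circularity <= 1)

  px <- measureMorphology(matrix(c(3L, 4L), 1, 2), 5)
  expect_equal(px$area_um2, 25)
  expect_equal(px$aspect_ratio, 1, tolerance = 1e-9)
  expect_gt(px$feret_max_um, 0)

  d <- measureMorphology(discComponent(15), 1)
  expect_gt(d$circularity, 0.92)       # digitised disc is nearly circular
  expect_equal(d$feret_max_um, 31, tolerance = 0.05)
  expect_equal(d$major_axis_um, 30, tolerance = 0.05)

  expect_error(measureMorphology(matrix(0L, 0, 2), 5), "empty")
  expect_error(measureMorphology(squareComponent(2), -1), "pixel_size_um")
})

test_that("Feret measurement agrees with the brute-force corner oracle", {
  for (s in 1:20) {
    blob <- randomBlob(sample(3:40, 1), seed = s)
    got <- measureMorphology(blob, 1)$feret_max_um
    expect_equal(got, bruteFeret(blob), tolerance = 1e-9)
  }
})

test_that("area always equals pixel count times pixel area", {
  for (s in 1:100) {
    blob <- randomBlob(sample(1:30, 1), seed = 1000 + s)
    ps <- runif(1, 0.5, 10)
    m <- measureMorphology(blob, ps)
    expect_equal(m$area_um2 / ps^2, nrow(blob), tolerance = 1e-9)
  }
})

test_that("fluorescence features implement TPB and colour fractions", {
  grey <- greyScan(matrix(100, 5, 5))
  f <- measureFluorescence(squareComponent(2), grey)
  expect_equal(f$tpb, 100)
  expect_equal(f$red_fraction, 1 / 3, tolerance = 1e-12)

  px <- array(0, c(5, 5, 3)); px[, , 1] <- 200
  red <- scanImage(px, 5)
  f2 <- measureFluorescence(squareComponent(2), red)
  expect_equal(f2$tpb, 200)
  expect_equal(f2$red_fraction, 1)

  two <- greyScan(matrix(c(0, 200, 0, 0), 2, 2))
  f3 <- measureFluorescence(matrix(c(1L, 2L, 1L, 1L), 2, 2), two)
  expect_equal(f3$tpb, 100)

  expect_error(measureFluorescence(matrix(c(9L, 9L), 1, 2), grey), "bounds")

  # fractions sum to one for any non-black particle
  set.seed(21)
  for (i in 1:20) {
    img <- scanImage(array(runif(75, 1, 255), c(5, 5, 3)), 5)
    fr <- measureFluorescence(squareComponent(3), img)
    expect_equal(fr$red_fraction + fr$green_fraction + fr$blue_fraction, 1,
                 tolerance = 1e-9)
  }
})
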