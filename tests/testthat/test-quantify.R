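test_that("shape classification follows the aspect/circularity rules", {
  m <- list(aspect_ratio = c(5.0, 1.05, 1.5, 3.0),
            circularity = c(0.5, 0.95, 0.6, 0.9))
  expect_equal(classifyShape(m),
               c("fibre", "spheroid", "fragment", "fibre"))
  # identical features and config give identical labels
  expect_identical(classifyShape(m), classifyShape(m))
})

test_that("fluorescence classification separates bright MP from weak PNO", {
  f <- list(tpb = c(88, 26, 0, 60, 60),
            red_fraction = c(0.50, 0.50, NA, 0.90, 0.20))
  got <- classifyFluorescence(f)
  expect_equal(got$fluor_group, c("bright", "weak", "weak", "medium",
                                  "medium"))
  expect_equal(got$mp_suspect, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("size classes partition [5, 5000] with the stated conventions", {
  expect_equal(assignSizeClass(c(10, 5000, 4, 5500)),
               c("10-50", "1000-5000", "below-range", "above-range"))
  expect_error(assignSizeClass(0), "positive")

  # totality: every size in [5, 5000] maps to exactly one of six classes
  sizes <- c(seq(5, 5000, length.out = 2000), sizeBoundaries(sizeClassScheme()))
  classes <- assignSizeClass(sizes)
  expect_true(all(classes %in% sizeClassLabels(sizeClassScheme())))
  # boundary convention: lower-inclusive
  expect_equal(assignSizeClass(c(5, 10, 50, 100, 500, 1000)),
               c("5-10", "10-50", "50-100", "100-500", "500-1000",
                 "1000-5000"))
})

test_that("volume models match their closed forms", {
  sph <- estimateVolume("spheroid", list(area_um2 = pi * 25^2,
                                         major_axis_um = 50,
                                         minor_axis_um = 50))
  expect_equal(sph, pi / 6 * 50^3, tolerance = 1e-12)
  fib <- estimateVolume("fibre", list(area_um2 = 1000, major_axis_um = 100,
                                      minor_axis_um = 10))
  expect_equal(fib, 100 * pi * 25, tolerance = 1e-12)
  frg <- estimateVolume("fragment", list(area_um2 = 200, major_axis_um = 20,
                                         minor_axis_um = 10))
  expect_equal(frg, 2000, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:25) {
    a <- runif(1, 10, 500); b <- runif(1, 5, a)
    m <- list(area_um2 = runif(1, 10, 1e4), major_axis_um = a,
              minor_axis_um = b)
    d <- 2 * sqrt(m$area_um2 / pi)
    expect_equal(estimateVolume("spheroid", m), pi / 6 * d^3,
                 tolerance = 1e-12)
    expect_equal(estimateVolume("fibre", m), a * pi * (b / 2)^2,
                 tolerance = 1e-12)
    expect_equal(estimateVolume("fragment", m, height_factor = 0.5),
                 a * b * b * 0.5, tolerance = 1e-12)
  }
})

test_that("mass conversion is exact unit arithmetic", {
  expect_equal(estimateMass(1e6, 1.0), 1.0, tolerance = 1e-12)
  expect_equal(estimateMass(pi / 6 * 50^3, 1.05), 0.0687, tolerance = 1e-3)
  expect_error(estimateMass(100, 0), "density")
})

test_that("aggregation counts only in-range MP-suspect particles", {
  empty <- aggregateSample(NULL)
  expect_equal(mpTotals(empty)$raw_count, 0)

  rec <- recordTable(c(20, 30, 40))     # 3 fragments in 10-50, medium
  s <- aggregateSample(rec, sample_id = "x")
  cc <- categoryCounts(s)
  hit <- cc[cc$size_class == "10-50" & cc$shape_class == "fragment" &
              cc$fluor_group == "medium", ]
  expect_equal(hit$raw_count, 3)
  expect_equal(mpTotals(s)$raw_count, 3)

  # below-range and non-suspect particles are excluded
  rec2 <- rbind(recordTable(c(20, 4)), recordTable(30, suspect = FALSE))
  expect_equal(mpTotals(aggregateSample(rec2))$raw_count, 1)

  # totals equal brute-force re-summation for random record sets
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    rec <- recordTable(runif(n, 1, 6000),
                       shape = sample(c("fragment", "spheroid", "fibre"), n,
                                      replace = TRUE),
                       suspect = sample(c(TRUE, FALSE), n, replace = TRUE),
                       mass = runif(n))
    s <- aggregateSample(rec)
    keep <- rec$mp_suspect & !rec$size_class %in% c("below-range",
                                                    "above-range")
    expect_equal(mpTotals(s)$raw_count, sum(keep))
    expect_equal(mpTotals(s)$raw_mass_ug, sum(rec$mass_ug[keep]),
                 tolerance = 1e-9)
    expect_equal(sum(categoryCounts(s)$raw_count), sum(keep))
  }
})

# helper: one-category blank summaries with given counts
blankWithCounts <- function(counts, category = c("10-50", "spheroid",
                                                 "medium")) {
  lapply(seq_along(counts), function(i) {
    s <- aggregateSample(NULL, sample_id = sprintf("b%d", i))
    cc <- categoryCounts(s)
    j <- cc$size_class == category[1] & cc$shape_class == category[2] &
      cc$fluor_group == category[3]
    cc$raw_count[j] <- counts[i]
    cc$raw_mass_ug[j] <- counts[i] * 0.1
    new("SampleSummary", sampleId = sampleId(s), categories = cc,
        corrected = FALSE)
  })
}

test_that("LOQ is blank mean plus ten sample standard deviations", {
  loq <- computeLoq(blankWithCounts(c(2, 3, 4)))
  t <- loqTable(loq)
  j <- t$size_class == "10-50" & t$shape_class == "spheroid" &
    t$fluor_group == "medium"
  expect_equal(t$blank_mean_count[j], 3)
  expect_equal(t$blank_sd_count[j], 1)
  expect_equal(t$loq_count[j], 13)
  # all-equal blanks: sd 0, LOQ = mean
  t5 <- loqTable(computeLoq(blankWithCounts(c(5, 5, 5))))
  expect_equal(t5$loq_count[j], 5)
  # categories absent from every blank stay at zero
  expect_true(all(t$loq_count[!j] == 0))
  # single blank forces sd = 0
  one <- loqTable(computeLoq(blankWithCounts(7)))
  expect_equal(one$loq_count[j], 7)
  expect_error(computeLoq(list()), "at least one")
})

test_that("LOQ grows with blank mean and blank spread", {
  base <- loqTable(computeLoq(blankWithCounts(c(2, 3, 4))))
  shifted <- loqTable(computeLoq(blankWithCounts(c(4, 5, 6))))
  spread <- loqTable(computeLoq(blankWithCounts(c(0, 3, 6))))
  j <- base$size_class == "10-50" & base$shape_class == "spheroid" &
    base$fluor_group == "medium"
  expect_gt(shifted$loq_count[j], base$loq_count[j])
  expect_gt(spread$loq_count[j], base$loq_count[j])
})

test_that("blank correction subtracts the mean above LOQ and censors below", {
  loq <- computeLoq(blankWithCounts(c(2, 3, 4)))   # mean 3, LOQ 13
  # build the sample in the same (spheroid/medium) category as the blanks
  sample20 <- blankWithCounts(20)[[1]]
  cor20 <- blankCorrect(sample20, loq)
  cc <- categoryCounts(cor20)
  k <- cc$size_class == "10-50" & cc$shape_class == "spheroid" &
    cc$fluor_group == "medium"
  expect_equal(cc$corrected_count[k], 17)          # 20 - 3
  expect_false(cc$censored_count[k])

  sample12 <- blankWithCounts(12)[[1]]
  cc12 <- categoryCounts(blankCorrect(sample12, loq))
  expect_equal(cc12$corrected_count[k], 0)
  expect_true(cc12$censored_count[k])

  # floor at zero: raw above LOQ but below blank mean cannot go negative
  lowloq <- computeLoq(blankWithCounts(3))         # mean 3, sd 0, LOQ 3
  sample4 <- blankWithCounts(4)[[1]]
  cc4 <- categoryCounts(blankCorrect(sample4, lowloq))
  expect_equal(cc4$corrected_count[k], 1)
  expect_true(all(categoryCounts(blankCorrect(sample4, loq))$corrected_count
                  >= 0))

  # corrected totals always equal the category sums
  t <- mpTotals(cor20)
  expect_equal(t$corrected_count, sum(cc$corrected_count))
  expect_equal(t$corrected_mass_ug, sum(cc$corrected_mass_ug))

  # mismatched schemes are rejected
  other <- aggregateSample(NULL, scheme = sizeClassScheme(c(5, 100, 5000)))
  expect_error(blankCorrect(other, loq), "scheme")
})

test_that("blank correction never yields negative values", {
  set.seed(33)
  for (i in 1:10) {
    blanks <- blankWithCounts(rpois(3, 5))
    loq <- computeLoq(blanks)
    sample <- blankWithCounts(rpois(1, 20))[[1]]
    cc <- categoryCounts(blankCorrect(sample, loq))
    expect_true(all(cc$corrected_count >= 0))
    expect_true(all(cc$corrected_mass_ug >= 0))
  }
})

test_that("classifier configuration round-trips through YAML", {
  cfg <- classifierConfig(tpb_mp_min = 50,
                          red_fraction_mp_range = c(0.3, 0.7))
  f <- tempfile(fileext = ".yaml")
  writeClassifierConfig(cfg, f)
  back <- readClassifierConfig(f)
  expect_equal(back@tpbMpMin, 50)
  expect_equal(back@redFractionMpRange, c(0.3, 0.7))
  expect_error(classifierConfig(tpb_weak_max = 80, tpb_medium_max = 75),
               "tpbWeakMax")
})
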