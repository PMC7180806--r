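test_that("power spectrum matches the literal DFT summation oracle", {
  ## constant image: all energy in the single DC bin, value (c*N)^2
  cimg <- matrix(7, 4, 4)
  p <- powerSpectrum(cimg)
  expect_equal(p[3, 3], (7 * 16)^2, tolerance = 1e-9)
  expect_equal(sum(p) - p[3, 3], 0, tolerance = 1e-6)

  ## unit impulse anywhere: perfectly flat spectrum of ones
  imp <- matrix(0, 4, 4); imp[2, 3] <- 1
  expect_equal(powerSpectrum(imp), matrix(1, 4, 4), tolerance = 1e-12)

  ## oracle equality on random rasters, even and odd sizes
  set.seed(11)
  for (d in list(c(4, 4), c(5, 3), c(6, 5))) {
    x <- matrix(runif(prod(d), 0, 10), d[1], d[2])
    expect_equal(powerSpectrum(x), dftPowerOracle(x), tolerance = 1e-6)
  }

  ## Parseval: sum of spectrum = N * sum of squared pixels
  x <- matrix(rnorm(64), 8, 8)
  expect_equal(sum(powerSpectrum(x)), 64 * sum(x^2), tolerance = 1e-8)
})

test_that("frequency score is the in-circle power fraction", {
  ## constant image: all power at DC, inside any circle
  s <- fftScore(matrix(5, 8, 8), FrequencyRegion(0.05))
  expect_equal(scoreValue(s), 1, tolerance = 1e-12)

  ## impulse image has a flat spectrum: score = bins-in-circle / N
  imp <- matrix(0, 16, 16); imp[5, 9] <- 1
  for (rf in c(0.2, 0.5, 1)) {
    s <- fftScore(imp, FrequencyRegion(rf))
    expect_equal(scoreValue(s), circleBinCountOracle(16, 16, rf) / 256,
                 tolerance = 1e-9)
  }

  ## rectangular raster: radius scales with the smaller dimension
  imp2 <- matrix(0, 8, 16); imp2[3, 3] <- 1
  s2 <- fftScore(imp2, FrequencyRegion(0.5))
  expect_equal(scoreValue(s2), circleBinCountOracle(8, 16, 0.5) / 128,
               tolerance = 1e-9)

  expect_error(fftScore(matrix(0, 8, 8)), "zero total power")
})

test_that("score is scale-invariant, bounded and monotone in radius", {
  set.seed(12)
  for (i in 1:20) {
    x <- matrix(runif(256, 0, 255), 16, 16)
    s1 <- scoreValue(fftScore(x, FrequencyRegion(0.3)))
    expect_gte(s1, 0); expect_lte(s1, 1)
    ## intensity scaling leaves the ratio unchanged
    cmul <- runif(1, 0.1, 10)
    expect_equal(scoreValue(fftScore(cmul * x, FrequencyRegion(0.3))), s1,
                 tolerance = 1e-9)
    ## monotone non-decreasing in the radius fraction
    rfs <- sort(runif(4))
    vals <- vapply(rfs, function(rf)
      scoreValue(fftScore(x, FrequencyRegion(rf))), 0)
    expect_true(all(diff(vals) >= -1e-12))
  }
  ## excluding DC keeps the invariants
  sNoDc <- fftScore(matrix(runif(64, 1, 2), 8, 8),
                    FrequencyRegion(0.3, includeDC = FALSE))
  expect_gte(scoreValue(sNoDc), 0); expect_lte(scoreValue(sNoDc), 1)
})

test_that("coarse decisions partition scores with ambiguity at the boundaries", {
  th <- CoarseThresholds(0.30, 0.60)
  expect_identical(coarseClassify(0.20, th), "benign")
  expect_identical(coarseClassify(0.70, th), "malign")
  expect_identical(coarseClassify(0.45, th), "ambiguous")
  ## equality with either threshold defers to the fine stage
  expect_identical(coarseClassify(0.30, th), "ambiguous")
  expect_identical(coarseClassify(0.60, th), "ambiguous")

  ## decisions are monotone in the score value
  vals <- seq(0, 1, by = 0.01)
  dec <- vapply(vals, coarseClassify, "", th = th)
  expect_true(all(diff(match(dec, c("benign", "ambiguous", "malign"))) >= 0))

  expect_error(CoarseThresholds(0.7, 0.3), "thLow")
})

test_that("threshold calibration satisfies its purity contract", {
  ## cleanly separated data: every training sample is decided
  v <- c(rep(0.1, 5), rep(0.9, 5))
  l <- rep(c("benign", "malign"), each = 5)
  th <- calibrateThresholds(v, l, purity = 1)
  dec <- vapply(v, coarseClassify, "", th = th)
  expect_false(any(dec == "ambiguous"))
  expect_identical(dec, l)

  ## identical scores: both sides collapse, everything is ambiguous
  th2 <- calibrateThresholds(rep(0.5, 6), rep(c("benign", "malign"), 3),
                             purity = 1)
  expect_identical(thresholdBounds(th2), c(low = -Inf, high = Inf))

  ## interleaved scores at purity 1: decided samples carry zero errors
  v3 <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  l3 <- c("benign", "malign", "benign", "malign", "benign", "malign")
  th3 <- calibrateThresholds(v3, l3, purity = 1)
  dec3 <- vapply(v3, coarseClassify, "", th = th3)
  decided <- dec3 != "ambiguous"
  expect_true(any(decided))
  expect_identical(dec3[decided], l3[decided])

  ## property: purity holds against the sweep oracle on random score sets
  set.seed(13)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    lab <- sample(c("benign", "malign"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("benign", "malign")
    sc <- round(runif(n), 2)
    for (purity in c(0.8, 0.95, 1)) {
      th <- calibrateThresholds(sc, lab, purity)
      expect_true(thresholdsRespectPurity(sc, lab, th, purity))
      b <- thresholdBounds(th)
      expect_lte(b["low"], b["high"])
    }
  }

  expect_error(calibrateThresholds(numeric(0), character(0)), "length")
  expect_error(calibrateThresholds(c(0.3, 0.4), c("benign", "benign")),
               "each class")
})

test_that("malign phantoms score higher than benign ones on average", {
  n <- 15
  b <- vapply(1:n, function(s) {
    ph <- generatePhantom("benign", smallPhantomParams(s))
    scoreValue(fftScore(roiPixels(extractThyroidROI(phantomImage(ph))),
                        spectrumSide = 256))
  }, 0)
  m <- vapply(1:n, function(s) {
    ph <- generatePhantom("malign", smallPhantomParams(1000 + s))
    scoreValue(fftScore(roiPixels(extractThyroidROI(phantomImage(ph))),
                        spectrumSide = 256))
  }, 0)
  expect_gt(mean(m), mean(b))
})
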