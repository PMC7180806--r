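test_that("Otsu threshold matches the exhaustive-sweep oracle", {
  ## stated examples
  t1 <- otsuThreshold(matrix(c(10, 10, 200, 200), 2))
  expect_true(t1 >= 10 && t1 < 200)
  expect_identical(sum(matrix(c(10, 10, 200, 200), 2) > t1), 2L)

  t2 <- otsuThreshold(matrix(c(0, 255, 0, 255), 2))
  expect_identical(sum(matrix(c(0, 255, 0, 255), 2) > t2), 2L)

  t3 <- otsuThreshold(matrix(128, 3, 3))
  expect_true(attr(t3, "degenerate"))
  expect_identical(sum(matrix(128, 3, 3) > t3), 0L)

  ## property: equality with the oracle on random small images
  set.seed(41)
  for (i in 1:50) {
    h <- sample(2:32, 1); w <- sample(2:32, 1)
    img <- matrix(sample(0:255, h * w, replace = TRUE,
                         prob = runif(256)^2), h, w)
    expect_identical(as.integer(otsuThreshold(img)), otsuOracle(img))
  }
})

test_that("largest component matches a flood-fill oracle at both connectivities", {
  ## two disjoint blobs: only the larger survives
  m <- matrix(FALSE, 8, 8)
  m[1:1, 1:5] <- TRUE           # 5 px
  m[4:6, 4:6] <- TRUE           # 9 px
  out <- largestComponent(m)
  expect_identical(sum(out), 9L)
  expect_true(all(out[4:6, 4:6]))

  ## single blob is returned unchanged
  s <- matrix(FALSE, 5, 5); s[2:3, 2:3] <- TRUE; s[4, 2] <- TRUE
  expect_identical(largestComponent(s), s)

  ## size tie: first component in row-major order wins
  tie <- matrix(FALSE, 6, 10)
  tie[4:5, 1:3] <- TRUE         # top-left pixel (4,1): row-major later
  tie[1:2, 5:7] <- TRUE         # top-left pixel (1,5): row-major first
  out <- largestComponent(tie)
  expect_true(all(out[1:2, 5:7]))
  expect_false(any(out[4:5, 1:3]))

  expect_error(largestComponent(matrix(FALSE, 3, 3)), "no foreground")

  ## property: oracle equality on random masks, 4- and 8-connectivity
  set.seed(42)
  for (i in 1:50) {
    h <- sample(3:16, 1); w <- sample(3:16, 1)
    mk <- matrix(runif(h * w) < 0.4, h, w)
    if (!any(mk)) mk[1, 1] <- TRUE
    for (conn in c(4, 8))
      expect_identical(largestComponent(mk, conn),
                       largestComponentOracle(mk, conn))
  }
})

test_that("bounding boxes are tight, 0-based and half-open", {
  m <- matrix(FALSE, 6, 8)
  m[3:5, 4:7] <- TRUE
  b <- boundingBox(m)
  expect_identical(boxRange(b, "row"), c(2L, 5L))
  expect_identical(boxRange(b, "col"), c(3L, 7L))

  allt <- matrix(TRUE, 4, 9)
  expect_identical(boxRange(boundingBox(allt), "row"), c(0L, 4L))
  expect_identical(boxRange(boundingBox(allt), "col"), c(0L, 9L))

  single <- matrix(FALSE, 5, 5); single[4, 2] <- TRUE
  b1 <- boundingBox(single)
  expect_identical(boxRange(b1, "row"), c(3L, 4L))
  expect_identical(boxRange(b1, "col"), c(1L, 2L))

  expect_error(boundingBox(matrix(FALSE, 2, 2)), "empty")
})

test_that("ROI extraction recovers the phantom's ground-truth band", {
  for (seed in 1:5) {
    ph <- generatePhantom(if (seed %% 2) "benign" else "malign",
                          smallPhantomParams(seed))
    roi <- extractThyroidROI(phantomImage(ph))
    truth <- roiBox(ph)
    got <- roiBox(roi)
    expect_lte(max(abs(boxRange(got, "row") - boxRange(truth, "row"))), 2)
    expect_lte(max(abs(boxRange(got, "col") - boxRange(truth, "col"))), 2)
  }

  ## uniformly bright image (bright bimodal texture everywhere, no dark
  ## frame): box is the full frame
  bright <- matrix(180, 20, 30)
  bright[(row(bright) + col(bright)) %% 2 == 0] <- 220
  roi <- extractThyroidROI(bright)
  expect_identical(boxRange(roiBox(roi), "row"), c(0L, 20L))
  expect_identical(boxRange(roiBox(roi), "col"), c(0L, 30L))

  ## all-dark (constant) image errors, naming the failing stage
  expect_error(extractThyroidROI(matrix(0, 10, 10)), "binarization")

  ## artifact-only detection is rejected by the area floor
  art <- matrix(0, 40, 40) + matrix(runif(1600, 0, 2), 40, 40)
  art[3:4, 3:4] <- 250
  expect_error(extractThyroidROI(art, minAreaFraction = 0.05), "roi stage")
})

test_that("ROI extraction is idempotent on a bright region over zero padding", {
  ## bright bimodal texture: re-binarizing the crop keeps the full crop as
  ## one bright component
  inner <- matrix(180, 12, 17)
  inner[(row(inner) + col(inner)) %% 2 == 0] <- 220
  img <- matrix(0, 30, 40)
  img[8:19, 10:26] <- inner
  roi1 <- extractThyroidROI(img)
  expect_equal(dim(roiPixels(roi1)), c(12L, 17L))
  roi2 <- extractThyroidROI(roiPixels(roi1))
  expect_equal(roiPixels(roi2), roiPixels(roi1))
})

test_that("cropping stays within image bounds on random boxes", {
  set.seed(7)
  img <- matrix(runif(30 * 20), 30, 20)
  for (i in 1:100) {
    r0 <- sample(0:29, 1); r1 <- r0 + sample(seq_len(30 - r0), 1)
    c0 <- sample(0:19, 1); c1 <- c0 + sample(seq_len(20 - c0), 1)
    crop <- ThyroCascade:::.cropBox(img, BoundingBox(r0, c0, r1, c1))
    expect_identical(dim(crop), c(r1 - r0, c1 - c0))
    expect_identical(crop[1, 1], img[r0 + 1, c0 + 1])
    expect_identical(crop[r1 - r0, c1 - c0], img[r1, c1])
  }
})

test_that("CNN normalization resizes bilinearly, rescales and replicates", {
  ## identity size: values are input/255 on three identical channels
  m <- matrix(runif(32 * 32, 0, 255), 32, 32)
  out <- normalizeForCNN(m, 32)
  expect_identical(dim(out), c(32L, 32L, 3L))
  expect_equal(out[, , 1], m / 255, tolerance = 1e-12)
  expect_identical(out[, , 1], out[, , 2])
  expect_identical(out[, , 1], out[, , 3])

  ## constant ROI v -> constant v/255
  out2 <- normalizeForCNN(matrix(51, 10, 10), 32)
  expect_equal(as.vector(out2), rep(0.2, 32 * 32 * 3), tolerance = 1e-9)

  ## 2x2 checkerboard to 4x4: half-pixel-center bilinear arithmetic gives
  ## per-axis weights (1, 3/4, 1/4, 0) on the first input row/column
  chk <- matrix(c(0, 255, 255, 0), 2, 2)
  got <- ThyroCascade:::.resizeBilinear(chk, 4, 4) / 255
  expected <- matrix(c(0, 0.25, 0.75, 1,
                       0.25, 0.375, 0.625, 0.75,
                       0.75, 0.625, 0.375, 0.25,
                       1, 0.75, 0.25, 0), 4, 4, byrow = TRUE)
  expect_equal(got, expected, tolerance = 1e-9)

  expect_error(normalizeForCNN(m, 16), ">= 32")
})
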