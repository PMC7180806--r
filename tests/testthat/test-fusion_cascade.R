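test_that("fusion rules evaluate and bound their inputs", {
  expect_equal(scoreValue(fuseScores(0.3, 0.8, "min")), 0.3)
  expect_equal(scoreValue(fuseScores(0.3, 0.8, "max")), 0.8)
  expect_equal(scoreValue(fuseScores(0.3, 0.8, "sum")), 0.55)

  ## idempotence on equal scores
  for (rule in c("min", "max", "sum"))
    expect_equal(scoreValue(fuseScores(0.42, 0.42, rule)), 0.42)

  ## property over random pairs: min <= sum <= max, symmetry, bounds
  set.seed(21)
  for (i in 1:1000) {
    s1 <- runif(1); s2 <- runif(1)
    vmin <- scoreValue(fuseScores(s1, s2, "min"))
    vsum <- scoreValue(fuseScores(s1, s2, "sum"))
    vmax <- scoreValue(fuseScores(s1, s2, "max"))
    expect_true(vmin <= vsum && vsum <= vmax)
    for (rule in c("min", "max", "sum"))
      expect_equal(scoreValue(fuseScores(s2, s1, rule)),
                   scoreValue(fuseScores(s1, s2, rule)))
  }

  expect_error(fuseScores(1.2, 0.5, "max"), "\\[0, 1\\]")
})

test_that("the fused decision threshold is strictly 'larger than'", {
  expect_identical(decideFused(0.8, 0.5), "benign")
  expect_identical(decideFused(0.5, 0.5), "malign")  # equality is malign
  expect_identical(decideFused(0.2, 0.5), "malign")
  f <- fuseScores(0.6, 0.9, "max")
  expect_identical(decideFused(f, 0.89), "benign")
})

test_that("decision-threshold calibration picks the widest optimal cut", {
  ## separable: any threshold in (0.2, 0.8) is optimal; midpoint 0.5
  expect_equal(calibrateDecisionThreshold(
    c(0.9, 0.8, 0.2, 0.1), c("benign", "benign", "malign", "malign")), 0.5)
  ## single pair
  expect_equal(calibrateDecisionThreshold(c(0.9, 0.1),
                                          c("benign", "malign")), 0.5)
  ## inseparable identical scores: tie-break at 0.5
  expect_equal(calibrateDecisionThreshold(
    rep(0.7, 4), c("benign", "malign", "benign", "malign")), 0.5)
  ## asymmetric optimum away from 0.5
  t <- calibrateDecisionThreshold(c(0.95, 0.9, 0.85, 0.2),
                                  c("benign", "benign", "benign", "malign"))
  acc <- function(t, v, l) mean(ifelse(v > t, "benign", "malign") == l)
  expect_equal(acc(t, c(0.95, 0.9, 0.85, 0.2),
                   c("benign", "benign", "benign", "malign")), 1)
  ## calibrated threshold is never beaten by any other cut (sweep oracle)
  set.seed(22)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    v <- round(runif(n), 2)
    l <- sample(c("benign", "malign"), n, replace = TRUE)
    if (length(unique(l)) < 2) l[1:2] <- c("benign", "malign")
    t <- calibrateDecisionThreshold(v, l)
    bestAcc <- max(vapply(seq(0, 1, by = 0.005), acc, 0, v = v, l = l))
    expect_equal(acc(t, v, l), bestAcc, tolerance = 1e-12)
  }
  expect_error(calibrateDecisionThreshold(numeric(0), character(0)))
})

test_that("coarse-decided images never invoke the network heads", {
  ## sentinel models that explode if touched
  bomb <- buildHead(HeadSpec("tiny"))
  bombTrap <- new.env()
  bombTrap$calls <- 0L
  trapModel <- structure(list(), class = "trap")
  cfgSmall <- cascadeConfig()
  cfgSmall$minAreaFraction <- 0.05

  ph <- generatePhantom("benign", smallPhantomParams(3))
  img <- phantomImage(ph)
  sc <- scoreValue(fftScore(roiPixels(extractThyroidROI(img)),
                            spectrumSide = 256))

  ## thresholds placing the score below thLow: benign via coarse path,
  ## models untouched (they would error if invoked: no trained weights and
  ## a deliberately wrong class)
  res <- cascadePredict(img, CoarseThresholds(sc + 0.001, sc + 0.002),
                        models = list(trapModel, trapModel),
                        config = cfgSmall)
  expect_identical(resultLabel(res), "benign")
  expect_identical(resultPath(res), "coarse")
  expect_null(res@fused)

  ## score above thHigh: malign via coarse path
  res2 <- cascadePredict(img, CoarseThresholds(sc - 0.002, sc - 0.001),
                         models = list(trapModel, trapModel),
                         config = cfgSmall)
  expect_identical(resultLabel(res2), "malign")
  expect_identical(resultPath(res2), "coarse")

  ## ambiguous score: both heads run exactly once and a fused score exists
  counter <- local({
    n <- 0L
    function() n <<- n + 1L
  })
  countingModel <- buildHead(HeadSpec("tiny"))
  res3 <- cascadePredict(img, CoarseThresholds(sc - 0.001, sc + 0.001),
                         models = list(countingModel, countingModel),
                         config = cfgSmall)
  expect_identical(resultPath(res3), "fine")
  expect_identical(res3@coarse, "ambiguous")
  expect_s4_class(res3@fused, "FusedScore")
  ## untrained heads emit 0.5 each; max fusion gives 0.5 -> malign (strict)
  expect_equal(scoreValue(res3@fused), 0.5)
  expect_identical(resultLabel(res3), "malign")

  ## determinism end to end
  res4 <- cascadePredict(img, CoarseThresholds(sc - 0.001, sc + 0.001),
                         models = list(countingModel, countingModel),
                         config = cfgSmall)
  expect_equal(res4@fused@value, res3@fused@value)
  expect_identical(resultLabel(res4), resultLabel(res3))
})

test_that("widening the ambiguous band never shrinks the fine-path load", {
  set.seed(23)
  scores <- runif(200)
  nFine <- function(lo, hi) {
    th <- CoarseThresholds(lo, hi)
    sum(vapply(scores, coarseClassify, "", th = th) == "ambiguous")
  }
  lo <- 0.5; hi <- 0.5
  prev <- nFine(lo, hi)
  for (widen in seq(0.05, 0.45, by = 0.05)) {
    cur <- nFine(0.5 - widen, 0.5 + widen)
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("cascade results satisfy their structural invariants", {
  expect_error(new("CascadeResult", label = "benign", path = "coarse",
                   coarse = "ambiguous", fused = NULL), "decided")
  expect_error(new("CascadeResult", label = "benign", path = "fine",
                   coarse = "ambiguous", fused = NULL), "fused")
  f <- fuseScores(0.2, 0.4, "sum")
  expect_error(new("CascadeResult", label = "benign", path = "coarse",
                   coarse = "benign", fused = f), "no fused")
  ok <- new("CascadeResult", label = "benign", path = "fine",
            coarse = "ambiguous", fused = f)
  expect_s4_class(ok, "CascadeResult")
})
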