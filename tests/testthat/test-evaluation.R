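test_that("confusion counts tally malign as the positive class", {
  all5m3b <- c(rep("malign", 5), rep("benign", 3))
  r <- reportCounts(evalMetrics(confusionCounts(all5m3b, all5m3b)))
  expect_identical(r, c(tp = 5L, fn = 0L, tn = 3L, fp = 0L))

  flipped <- ifelse(all5m3b == "malign", "benign", "malign")
  r2 <- reportCounts(evalMetrics(confusionCounts(all5m3b, flipped)))
  expect_identical(r2, c(tp = 0L, fn = 5L, tn = 0L, fp = 3L))

  ## mixed toy list against a hand tally
  lab <- c("malign", "malign", "benign", "benign", "malign", "benign",
           "malign", "benign")
  prd <- c("malign", "benign", "benign", "malign", "malign", "benign",
           "benign", "benign")
  cc <- confusionCounts(lab, prd)
  expect_identical(reportCounts(evalMetrics(cc)),
                   c(tp = 2L, fn = 2L, tn = 3L, fp = 1L))

  expect_error(confusionCounts(lab, prd[1:3]), "length")
})

test_that("metrics recompute exactly from counts and flag undefined cases", {
  r <- evalMetrics(ConfusionCounts(50, 5, 8, 3))
  expect_equal(unname(reportMetrics(r)),
               c(50 / 55, 8 / 11, 58 / 66), tolerance = 1e-12)

  perfect <- evalMetrics(ConfusionCounts(5, 0, 3, 0))
  expect_equal(unname(reportMetrics(perfect)), c(1, 1, 1))

  ## no positives in ground truth: sensitivity undefined, not 0
  nopos <- evalMetrics(ConfusionCounts(0, 0, 3, 0))
  m <- reportMetrics(nopos)
  expect_true(is.na(m["sensitivity"]))
  expect_equal(unname(m["specificity"]), 1)
  expect_equal(unname(m["accuracy"]), 1)

  expect_error(evalMetrics(ConfusionCounts(0, 0, 0, 0)), "zero")

  ## algebraic identity of the three formulas on random tables
  set.seed(31)
  for (i in 1:1000) {
    v <- sample(0:50, 4, replace = TRUE)
    if (v[1] + v[2] == 0) v[1] <- 1
    if (v[3] + v[4] == 0) v[3] <- 1
    r <- evalMetrics(ConfusionCounts(v[1], v[2], v[3], v[4]))
    total <- sum(v)
    expect_equal(r@accuracy * total,
                 r@sensitivity * (v[1] + v[2]) +
                   r@specificity * (v[3] + v[4]),
                 tolerance = 1e-9)
  }
})

test_that("folds partition patients evenly per class at patient level", {
  dir <- withr::local_tempdir()
  man <- generateDataset(5, 5, 2, smallPhantomParams(seed = 9), dir)
  split <- makeFolds(man, k = 5, seed = 4)
  a <- foldAssignments(split)
  s <- manifestSamples(man)

  ## partition: every patient appears exactly once
  expect_setequal(names(a), unique(s$patient_id))
  ## 5 benign + 5 malign patients into 5 folds: exactly 1 + 1 per fold
  patClass <- vapply(names(a), function(p)
    s$label[s$patient_id == p][1], "")
  for (f in 0:4) {
    expect_identical(sum(a == f & patClass == "benign"), 1L)
    expect_identical(sum(a == f & patClass == "malign"), 1L)
  }
  ## all images of a patient share its fold by construction; assignments
  ## are per patient, so verify multiplicity survives the join
  imgFolds <- a[s$patient_id]
  expect_identical(length(imgFolds), nrow(s))
  expect_true(all(tapply(imgFolds, s$patient_id,
                         function(x) length(unique(x))) == 1))

  ## determinism and seed sensitivity
  expect_identical(foldAssignments(makeFolds(man, 5, seed = 4)), a)
  ## fewer patients than folds errors
  expect_error(makeFolds(man, k = 6), "fewer than")
})

test_that("per-class fold sizes differ by at most one on uneven counts", {
  dir <- withr::local_tempdir()
  man <- generateDataset(7, 11, 1, smallPhantomParams(seed = 10), dir)
  split <- makeFolds(man, k = 3, seed = 2)
  a <- foldAssignments(split)
  s <- manifestSamples(man)
  patClass <- vapply(names(a), function(p)
    s$label[s$patient_id == p][1], "")
  for (cl in c("benign", "malign")) {
    sizes <- table(a[patClass == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("cross-validation aggregates fold metrics without leakage", {
  dir <- withr::local_tempdir()
  man <- generateDataset(6, 6, 1, smallPhantomParams(seed = 12), dir)
  cfg <- cascadeConfig(trainConfig = TrainConfig(epochs = 6, batchSize = 12,
                                                 learningRate = 0.01,
                                                 seed = 3))
  cv <- crossValidate(man, k = 3, seed = 1, config = cfg)
  expect_length(cv$folds, 3)
  ## the reported mean is the unweighted mean of the fold reports
  accs <- vapply(cv$folds, function(r) reportMetrics(r)["accuracy"], 0)
  expect_equal(unname(cv$mean["accuracy"]), mean(accs), tolerance = 1e-12)
  sens <- vapply(cv$folds, function(r) reportMetrics(r)["sensitivity"], 0)
  expect_equal(unname(cv$mean["sensitivity"]), mean(sens), tolerance = 1e-12)
  expect_gte(cv$coarseFraction, 0)
  expect_lte(cv$coarseFraction, 1)
  ## folds come back in order with their ids
  expect_identical(vapply(cv$folds, function(r) r@foldId, 0L), 0:2)
})
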