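#' @include AllClasses.R io_datasets.R fusion_cascade.R
NULL

#' Confusion counts of a prediction set
#'
#' Malign is the positive class: \code{tp} counts malign images predicted
#' malign, \code{fn} malign predicted benign, \code{tn} benign predicted
#' benign, \code{fp} benign predicted malign.
#'
#' @param labels ground-truth \code{"benign"}/\code{"malign"} vector.
#' @param predictions parallel predicted labels.
#' @return a \code{\linkS4class{ConfusionCounts}}.
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  if (length(labels) == 0) stop("empty prediction set")
  stopifnot(all(labels %in% .LABELS), all(predictions %in% .LABELS))
  ConfusionCounts(tp = sum(labels == "malign" & predictions == "malign"),
                  fn = sum(labels == "malign" & predictions == "benign"),
                  tn = sum(labels == "benign" & predictions == "benign"),
                  fp = sum(labels == "benign" & predictions == "malign"))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/(TP+TN+FP+FN). A class absent from the ground truth
#' makes its metric undefined; it is reported as \code{NA}, never silently
#' as 0.
#'
#' @param counts a \code{\linkS4class{ConfusionCounts}}.
#' @param foldId optional fold index recorded in the report.
#' @return an \code{\linkS4class{EvalReport}}.
#' @examples
#' evalMetrics(ConfusionCounts(50, 5, 8, 3))
#' @export
evalMetrics <- function(counts, foldId = NA_integer_) {
  stopifnot(is(counts, "ConfusionCounts"))
  pos <- counts@tp + counts@fn
  neg <- counts@tn + counts@fp
  if (pos + neg == 0) stop("all confusion counts are zero")
  new("EvalReport", counts = counts,
      sensitivity = if (pos > 0) counts@tp / pos else NA_real_,
      specificity = if (neg > 0) counts@tn / neg else NA_real_,
      accuracy = (counts@tp + counts@tn) / (pos + neg),
      foldId = as.integer(foldId))
}

## patient table from a manifest: one row per patient with its class
## (majority label over the patient's images; ties go to malign)
.patientClasses <- function(manifest) {
  s <- manifest@samples
  pats <- unique(s$patient_id)
  cls <- vapply(pats, function(p) {
    lab <- s$label[s$patient_id == p]
    if (sum(lab == "malign") >= sum(lab == "benign")) "malign" else "benign"
  }, "")
  data.frame(patient_id = pats, class = cls, stringsAsFactors = FALSE)
}

#' Patient-level fold assignment
#'
#' Shuffles the patients of each class independently (seeded) and deals
#' them round-robin into \code{k} folds, so per-class patient counts differ
#' by at most one across folds and all images of a patient share its fold.
#'
#' @param manifest a \code{\linkS4class{Manifest}}.
#' @param k number of folds (default 5).
#' @param seed integer shuffle seed.
#' @return a \code{\linkS4class{FoldSplit}}.
#' @export
makeFolds <- function(manifest, k = 5L, seed = 1L) {
  stopifnot(is(manifest, "Manifest"))
  k <- as.integer(k)
  pc <- .patientClasses(manifest)
  assignments <- integer(0)
  .withSeed(seed, {
    for (cl in .LABELS) {
      pats <- pc$patient_id[pc$class == cl]
      if (length(pats) < k)
        stop("class '", cl, "' has ", length(pats),
             " patients, fewer than k = ", k)
      pats <- sample(pats)
      a <- (seq_along(pats) - 1L) %% k
      names(a) <- pats
      assignments <- c(assignments, a)
    }
  })
  new("FoldSplit", k = k, assignments = assignments,
      seed = as.integer(seed))
}

#' Patient-level k-fold cross-validation of the cascade
#'
#' For every fold, the coarse thresholds are calibrated, the two heads
#' trained, and the fused decision threshold fitted on the k-1 training
#' folds only; the held-out fold is then classified end-to-end and scored
#' per image. The final metrics are the unweighted mean over folds (not a
#' pooled confusion table).
#'
#' @param manifest a \code{\linkS4class{Manifest}} whose image files exist.
#' @param k number of folds (default 5).
#' @param seed integer seed driving the fold shuffle and, offset per fold,
#'   the training seeds.
#' @param config a \code{\link{cascadeConfig}} list.
#' @return list with \code{folds} (list of \code{\linkS4class{EvalReport}}),
#'   \code{mean} (named numeric: sensitivity, specificity, accuracy),
#'   \code{coarseFraction} (fraction of test images decided by the coarse
#'   stage) and \code{split} (the \code{\linkS4class{FoldSplit}}).
#' @export
crossValidate <- function(manifest, k = 5L, seed = 1L,
                          config = cascadeConfig()) {
  stopifnot(is(manifest, "Manifest"))
  s <- manifest@samples
  split <- makeFolds(manifest, k = k, seed = seed)
  images <- lapply(s$image_path, loadImage)
  folds <- vector("list", split@k)
  nCoarse <- 0L; nTest <- 0L
  for (f in seq_len(split@k) - 1L) {
    testPats <- names(split@assignments)[split@assignments == f]
    testIdx <- which(s$patient_id %in% testPats)
    trainIdx <- setdiff(seq_len(nrow(s)), testIdx)
    ## leakage guard: held-out patients never reach calibration/training
    stopifnot(!any(s$patient_id[trainIdx] %in% testPats))
    cfg <- config
    tc <- config$trainConfig
    cfg$trainConfig <- TrainConfig(
      epochs = tc@epochs, batchSize = tc@batchSize,
      learningRate = tc@learningRate, lossWeights = tc@lossWeights,
      seed = tc@seed + 10L * f, pretrainedBackbone = tc@pretrainedBackbone)
    model <- fitCascade(images[trainIdx], s$label[trainIdx], cfg)
    preds <- character(length(testIdx))
    for (i in seq_along(testIdx)) {
      res <- cascadePredict(images[[testIdx[i]]], model@thresholds,
                            model@models, rule = model@rule,
                            decisionThreshold = model@decisionThreshold,
                            config = cfg)
      preds[i] <- res@label
      if (res@path == "coarse") nCoarse <- nCoarse + 1L
    }
    nTest <- nTest + length(testIdx)
    folds[[f + 1L]] <- evalMetrics(confusionCounts(s$label[testIdx], preds),
                                   foldId = f)
  }
  mean_ <- c(
    sensitivity = mean(vapply(folds, function(r) r@sensitivity, 0)),
    specificity = mean(vapply(folds, function(r) r@specificity, 0)),
    accuracy = mean(vapply(folds, function(r) r@accuracy, 0)))
  list(folds = folds, mean = mean_, coarseFraction = nCoarse / nTest,
       split = split)
}

#' Loss-weighting bias study under class imbalance
#'
#' Reproduces, on synthetic phantoms, the qualitative effect of the
#' class-weighted loss: training on a 9:1 malign:benign set with weights
#' (0.7, 0.3) on the (minority) benign term yields a smaller gap between
#' sensitivity and specificity on a balanced test set than training the same
#' architecture on the same data with equal weights (0.5, 0.5). The study
#' trains one \code{tiny} head per (training seed, weighting) pair and
#' evaluates raw network predictions at threshold 0.5, without the coarse
#' stage, so the loss function is the only moving part.
#'
#' Default conditions: 10 benign / 90 malign training phantoms, 40 + 40 test
#' phantoms, moderate class separation (0.5) so the classes genuinely
#' overlap, and a small seed set over which gaps are averaged.
#'
#' @param params phantom conditions; the default uses a reduced frame so a
#'   study run stays desk-scale.
#' @param nMinority,nMajority benign / malign training images.
#' @param nTestPerClass test images per class.
#' @param dataSeed seed offset for phantom generation.
#' @param trainSeeds integer vector of training seeds; results are averaged
#'   over them.
#' @param weights named list of the two loss weightings to compare.
#' @param epochs,batchSize,learningRate,side training settings for the
#'   \code{tiny} heads.
#' @return list with \code{perRun} (data.frame of sensitivity, specificity,
#'   gap and accuracy per seed and weighting) and \code{meanGap} (named
#'   numeric, mean |sensitivity - specificity| per weighting).
#' @export
imbalanceStudy <- function(params = PhantomParams(frameSize = c(160, 240),
                                                  noduleRadiusRange = c(12, 20),
                                                  classSeparation = 0.5),
                           nMinority = 10L, nMajority = 90L,
                           nTestPerClass = 40L, dataSeed = 1L,
                           trainSeeds = c(101L, 102L, 103L),
                           weights = list(weighted = c(0.7, 0.3),
                                          unweighted = c(0.5, 0.5)),
                           epochs = 16L, batchSize = 16L,
                           learningRate = 0.01, side = 32L) {
  mk <- function(lbl, seed) {
    pp <- params
    pp@seed <- as.integer(seed)
    ph <- generatePhantom(lbl, pp)
    normalizeForCNN(extractThyroidROI(ph@image), side)
  }
  base <- dataSeed * 10000L
  xs <- c(lapply(seq_len(nMinority), function(i) mk("benign", base + i)),
          lapply(seq_len(nMajority), function(i) mk("malign", base + 500L + i)))
  ys <- c(rep("benign", nMinority), rep("malign", nMajority))
  xt <- c(lapply(seq_len(nTestPerClass), function(i)
            mk("benign", base + 2000L + i)),
          lapply(seq_len(nTestPerClass), function(i)
            mk("malign", base + 3000L + i)))
  yt <- rep(.LABELS, each = nTestPerClass)
  arrT <- .stackInputs(xt, side)
  rows <- list()
  for (w in names(weights)) {
    for (s in trainSeeds) {
      cfg <- TrainConfig(epochs = epochs, batchSize = batchSize,
                         learningRate = learningRate,
                         lossWeights = weights[[w]], seed = s)
      m <- trainHead(buildHead(HeadSpec("tiny", inputSide = side)), xs, ys,
                     cfg)
      pred <- ifelse(.predictBatch(m, arrT) > 0.5, "benign", "malign")
      r <- evalMetrics(confusionCounts(yt, pred))
      rows[[length(rows) + 1L]] <- data.frame(
        weighting = w, seed = s, sensitivity = r@sensitivity,
        specificity = r@specificity,
        gap = abs(r@sensitivity - r@specificity), accuracy = r@accuracy,
        stringsAsFactors = FALSE)
    }
  }
  perRun <- do.call(rbind, rows)
  meanGap <- tapply(perRun$gap, perRun$weighting, mean)
  list(perRun = perRun, meanGap = c(meanGap))
}
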