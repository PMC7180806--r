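#' @include AllClasses.R frequency.R cnn_fine.R
NULL

#' Fuse two classification scores
#'
#' Combines the probability-of-benign scores of the two heads by the MIN,
#' MAX or SUM rule; SUM is the arithmetic mean of the two scores (the rule
#' is named after its equation, though it averages). The fused value always
#' lies between \code{min(s1, s2)} and \code{max(s1, s2)} and every rule is
#' symmetric in its arguments.
#'
#' @param s1,s2 scores in [0, 1] (bare numerics or
#'   \code{\linkS4class{ClassScore}} objects).
#' @param rule \code{"max"} (default; the best-performing rule),
#'   \code{"min"} or \code{"sum"}.
#' @return a \code{\linkS4class{FusedScore}}.
#' @examples
#' fuseScores(0.3, 0.8, "sum")   # 0.55
#' @export
fuseScores <- function(s1, s2, rule = c("max", "min", "sum")) {
  rule <- match.arg(rule)
  if (is(s1, "ClassScore")) s1 <- s1@pBenign
  if (is(s2, "ClassScore")) s2 <- s2@pBenign
  if (s1 < 0 || s1 > 1 || s2 < 0 || s2 > 1)
    stop("scores must lie in [0, 1]")
  v <- switch(rule, min = min(s1, s2), max = max(s1, s2),
              sum = (s1 + s2) / 2)
  new("FusedScore", value = v, rule = rule, s1 = s1, s2 = s2)
}

#' Threshold a fused score
#'
#' A fused score strictly larger than the threshold is classified benign;
#' anything else — including exact equality — is malign ("larger than" is
#' strict).
#'
#' @param fused a \code{\linkS4class{FusedScore}} or bare numeric in [0, 1].
#' @param threshold decision threshold in [0, 1]; default 0.5.
#' @return \code{"benign"} or \code{"malign"}.
#' @export
decideFused <- function(fused, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  v <- if (is(fused, "FusedScore")) fused@value else as.numeric(fused)
  if (v > threshold) "benign" else "malign"
}

#' Calibrate the fused decision threshold
#'
#' Training accuracy as a function of the threshold is piecewise constant,
#' changing only at observed score values; the calibrator enumerates the
#' constant intervals within [0, 1], keeps the accuracy-maximizing ones, and
#' returns 0.5 when it is itself optimal, otherwise the midpoint of the
#' widest optimal interval (ties broken towards 0.5).
#'
#' @param values fused training scores in [0, 1].
#' @param labels parallel \code{"benign"}/\code{"malign"} labels.
#' @return the calibrated threshold, a numeric scalar in [0, 1].
#' @export
calibrateDecisionThreshold <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) > 0)
  if (!all(.LABELS %in% labels))
    stop("calibration needs at least one sample of each class")
  if (any(values < 0 | values > 1)) stop("scores must lie in [0, 1]")
  sv <- sort(unique(values))
  lo <- c(0, sv); hi <- c(sv, 1)
  ## drop empty intervals, but keep the degenerate top cut t = 1 (it is a
  ## valid threshold: a score of exactly 1 is then decided malign)
  keep <- hi > lo | (lo == 1 & hi == 1)
  lo <- lo[keep]; hi <- hi[keep]
  acc <- vapply(seq_along(lo), function(i) {
    t <- (lo[i] + hi[i]) / 2
    mean(ifelse(values > t, "benign", "malign") == labels)
  }, 0)
  best <- which(acc == max(acc))
  ## merge adjacent optimal intervals into maximal runs
  runs <- split(best, cumsum(c(1, diff(best) != 1)))
  mlo <- vapply(runs, function(r) lo[r[1]], 0)
  mhi <- vapply(runs, function(r) hi[r[length(r)]], 0)
  ## intervals are half-open [lo, hi): accuracy at t = hi belongs to the
  ## next interval, so 0.5 counts as inside only strictly before hi
  inside <- mlo <= 0.5 & 0.5 < mhi
  if (any(inside)) return(0.5)
  wid <- mhi - mlo
  cand <- which(wid == max(wid))
  mids <- (mlo[cand] + mhi[cand]) / 2
  mids[which.min(abs(mids - 0.5))]
}

#' Pipeline configuration
#'
#' Bundles every tunable setting of the cascade in one named list:
#' preprocessing (\code{minAreaFraction}, \code{connectivity}), the
#' frequency stage (\code{region}, \code{spectrumSide}, \code{purity}), the
#' fine stage (\code{backbone}, \code{cnnSide}, \code{trainConfig}) and the
#' fusion rule.
#'
#' @param region a \code{\linkS4class{FrequencyRegion}}.
#' @param spectrumSide square spectrum grid side (default 256) so scores
#'   are comparable across ROI sizes.
#' @param purity coarse-calibration per-side purity (default 0.95).
#' @param rule fusion rule, default \code{"max"}.
#' @param backbone backbone for the two heads (default \code{"tiny"}).
#' @param cnnSide network input side; defaults to the backbone's native
#'   side (32 for tiny, 224 otherwise).
#' @param trainConfig a \code{\linkS4class{TrainConfig}}.
#' @param minAreaFraction,connectivity see
#'   \code{\link{extractThyroidROI}}.
#' @return named list of settings.
#' @export
cascadeConfig <- function(region = FrequencyRegion(), spectrumSide = 256L,
                          purity = 0.95, rule = "max", backbone = "tiny",
                          cnnSide = NULL, trainConfig = TrainConfig(),
                          minAreaFraction = 0.05, connectivity = 8L) {
  if (is.null(cnnSide)) cnnSide <- if (backbone == "tiny") 32L else 224L
  list(region = region, spectrumSide = as.integer(spectrumSide),
       purity = purity, rule = rule, backbone = backbone,
       cnnSide = as.integer(cnnSide), trainConfig = trainConfig,
       minAreaFraction = minAreaFraction,
       connectivity = as.integer(connectivity))
}

#' Classify one image through the full cascade
#'
#' Preprocesses the frame (thyroid localization and crop), computes the
#' frequency power-ratio score, and applies the coarse ternary rule. A
#' decided coarse outcome is returned directly — the network heads are not
#' invoked. An ambiguous outcome routes the normalized ROI through both
#' heads, fuses their scores, and thresholds the fused score.
#'
#' @param image numeric matrix in [0, 255] (see \code{\link{loadImage}}).
#' @param thresholds a \code{\linkS4class{CoarseThresholds}}.
#' @param models list of the two heads
#'   \code{list(resnet = , inception = )} (any two
#'   \code{\linkS4class{CNNModel}} objects).
#' @param rule fusion rule.
#' @param decisionThreshold fused-score threshold (default 0.5).
#' @param config a \code{\link{cascadeConfig}} list.
#' @return a \code{\linkS4class{CascadeResult}}.
#' @export
cascadePredict <- function(image, thresholds, models,
                           rule = c("max", "min", "sum"),
                           decisionThreshold = 0.5,
                           config = cascadeConfig()) {
  rule <- match.arg(rule)
  roi <- extractThyroidROI(image, minAreaFraction = config$minAreaFraction,
                           connectivity = config$connectivity)
  score <- fftScore(roi@pixels, region = config$region,
                    spectrumSide = config$spectrumSide)
  outcome <- coarseClassify(score, thresholds)
  if (outcome != "ambiguous")
    return(new("CascadeResult", label = outcome, path = "coarse",
               coarse = outcome, fused = NULL))
  xin <- normalizeForCNN(roi, side = config$cnnSide)
  s1 <- predictScore(models[[1L]], xin)
  s2 <- predictScore(models[[2L]], xin)
  fused <- fuseScores(s1, s2, rule)
  new("CascadeResult", label = decideFused(fused, decisionThreshold),
      path = "fine", coarse = outcome, fused = fused)
}

#' Fit the full cascade on training data
#'
#' Calibrates every stage on the supplied training images only: extracts
#' ROIs and frequency scores, fits the dual coarse thresholds at the
#' configured purity, trains the two heads (with seeds derived from
#' \code{config$trainConfig@seed}) on all training ROIs, and calibrates the
#' fused decision threshold on the training fused scores.
#'
#' @param images list of numeric matrices in [0, 255].
#' @param labels parallel \code{"benign"}/\code{"malign"} labels.
#' @param config a \code{\link{cascadeConfig}} list.
#' @return a \code{\linkS4class{CascadeModel}}.
#' @export
fitCascade <- function(images, labels, config = cascadeConfig()) {
  stopifnot(length(images) == length(labels))
  rois <- lapply(images, extractThyroidROI,
                 minAreaFraction = config$minAreaFraction,
                 connectivity = config$connectivity)
  scores <- vapply(rois, function(r)
    fftScore(r@pixels, region = config$region,
             spectrumSide = config$spectrumSide)@value, 0)
  th <- calibrateThresholds(scores, labels, purity = config$purity)
  spec <- HeadSpec(config$backbone, inputSide = config$cnnSide)
  xin <- lapply(rois, normalizeForCNN, side = config$cnnSide)
  cfg1 <- config$trainConfig
  cfg2 <- TrainConfig(epochs = cfg1@epochs, batchSize = cfg1@batchSize,
                      learningRate = cfg1@learningRate,
                      lossWeights = cfg1@lossWeights,
                      seed = cfg1@seed + 1L,
                      pretrainedBackbone = cfg1@pretrainedBackbone)
  m1 <- trainHead(buildHead(spec, modelId = "resnet"), xin, labels, cfg1)
  m2 <- trainHead(buildHead(spec, modelId = "inception"), xin, labels, cfg2)
  arr <- .stackInputs(xin, config$cnnSide)
  p1 <- .predictBatch(m1, arr)
  p2 <- .predictBatch(m2, arr)
  fusedTrain <- vapply(seq_along(p1), function(i)
    fuseScores(p1[i], p2[i], config$rule)@value, 0)
  dt <- calibrateDecisionThreshold(fusedTrain, labels)
  new("CascadeModel", thresholds = th, models = list(resnet = m1,
      inception = m2), rule = config$rule, decisionThreshold = dt,
      config = config)
}
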