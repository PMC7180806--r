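#' @include AllClasses.R
NULL

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox rows [%d, %d) cols [%d, %d)\n",
              object@rowStart, object@rowEnd, object@colStart,
              object@colEnd))
})

setMethod("show", "ThyroidROI", function(object) {
  cat(sprintf("ThyroidROI %dx%d px cropped from a %dx%d frame\n",
              nrow(object@pixels), ncol(object@pixels),
              object@sourceShape[1], object@sourceShape[2]))
  cat(sprintf("  box: rows [%d, %d) cols [%d, %d)\n",
              object@box@rowStart, object@box@rowEnd,
              object@box@colStart, object@box@colEnd))
})

setMethod("show", "FrequencyScore", function(object) {
  cat(sprintf(
    "FrequencyScore %.6f (Ps = %.4g, P = %.4g, circle r = %.2f%s)\n",
    object@value, object@pSelected, object@pTotal,
    object@region@radiusFraction,
    if (object@region@includeDC) ", DC included" else ", DC excluded"))
})

setMethod("show", "CoarseThresholds", function(object) {
  cat(sprintf("CoarseThresholds [thLow = %.6g, thHigh = %.6g]\n",
              object@thLow, object@thHigh))
})

setMethod("show", "FusedScore", function(object) {
  cat(sprintf("FusedScore %.4f (%s rule on s1 = %.4f, s2 = %.4f)\n",
              object@value, object@rule, object@s1, object@s2))
})

setMethod("show", "ClassScore", function(object) {
  cat(sprintf("ClassScore p(benign) = %.4f [%s]\n", object@pBenign,
              object@modelId))
})

setMethod("show", "CascadeResult", function(object) {
  cat(sprintf("CascadeResult: %s (decided by the %s stage)\n",
              object@label, object@path))
  if (!is.null(object@fused))
    cat(sprintf("  fused %.4f (%s rule on s1 = %.4f, s2 = %.4f)\n",
                object@fused@value, object@fused@rule, object@fused@s1,
                object@fused@s2))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts TP = %d, FN = %d, TN = %d, FP = %d\n",
              object@tp, object@fn, object@tn, object@fp))
})

setMethod("show", "EvalReport", function(object) {
  fmt <- function(x) if (is.na(x)) "undefined" else sprintf("%.4f", x)
  if (!is.na(object@foldId)) cat(sprintf("EvalReport (fold %d)\n",
                                         object@foldId))
  else cat("EvalReport\n")
  cat(sprintf("  TP = %d, FN = %d, TN = %d, FP = %d\n", object@counts@tp,
              object@counts@fn, object@counts@tn, object@counts@fp))
  cat(sprintf("  sensitivity %s, specificity %s, accuracy %s\n",
              fmt(object@sensitivity), fmt(object@specificity),
              fmt(object@accuracy)))
})

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit: %d patients into %d folds (seed %d)\n",
              length(object@assignments), object@k, object@seed))
})

setMethod("show", "Manifest", function(object) {
  s <- object@samples
  cat(sprintf("Manifest (%s): %d images, %d patients", object@origin,
              nrow(s), length(unique(s$patient_id))))
  if (nrow(s) > 0)
    cat(sprintf(" (%d benign, %d malign images)",
                sum(s$label == "benign"), sum(s$label == "malign")))
  cat("\n")
})

setMethod("show", "HeadSpec", function(object) {
  cat(sprintf("HeadSpec: %s backbone, input %dx%dx3, dropout %.2f\n",
              object@backbone, object@inputSide, object@inputSide,
              object@dropout))
})

setMethod("show", "CNNModel", function(object) {
  cat(sprintf("CNNModel [%s]: %s backbone, input %dx%dx3, %s\n",
              object@modelId, object@spec@backbone, object@spec@inputSide,
              object@spec@inputSide,
              if (object@trained) "trained" else "untrained"))
  cat(sprintf("  parameters: total %s (backbone %s, head %s)\n",
              format(sum(object@layers$params), big.mark = ","),
              format(sum(object@layers$params[
                object@layers$part == "backbone"]), big.mark = ","),
              format(sum(object@layers$params[
                object@layers$part != "backbone"]), big.mark = ",")))
  if (object@trained)
    cat(sprintf("  final training loss %.4f after %d epochs\n",
                object@lossLog[length(object@lossLog)],
                length(object@lossLog)))
})

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: %s, %d epochs, batch %d, lr %g, weights (%.2f, %.2f), seed %d\n",
    object@optimizer, object@epochs, object@batchSize, object@learningRate,
    object@lossWeights[1], object@lossWeights[2], object@seed))
})

setMethod("show", "PhantomParams", function(object) {
  cat(sprintf("PhantomParams: %dx%d frame, band/background %g/%g,\n",
              object@frameSize[1], object@frameSize[2], object@thyroidMean,
              object@backgroundMean))
  cat(sprintf(
    "  speckle sigma %.2f, separation %.2f, %d artifacts, seed %d\n",
    object@speckleSigma, object@classSeparation, object@nArtifacts,
    object@seed))
})

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf("PhantomSample: %s, %dx%d px, patient %s\n", object@label,
              nrow(object@image), ncol(object@image), object@patientId))
})

setMethod("show", "CascadeModel", function(object) {
  cat("CascadeModel\n")
  cat(sprintf("  coarse: thLow = %.6g, thHigh = %.6g (purity %.2f)\n",
              object@thresholds@thLow, object@thresholds@thHigh,
              object@config$purity))
  cat(sprintf("  fine: 2 x %s backbone, %s rule, decision threshold %.4f\n",
              object@models[[1]]@spec@backbone, object@rule,
              object@decisionThreshold))
})
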