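#' @import methods
NULL

.LABELS <- c("benign", "malign")

#' Bounding box in pixel coordinates
#'
#' Axis-aligned rectangle in source-image coordinates, stored as 0-based
#' half-open index ranges \code{[rowStart, rowEnd) x [colStart, colEnd)}, so
#' an all-true mask of an H x W image has box \code{(0, 0, H, W)} and a single
#' pixel at (r, c) (1-based R indexing) has box \code{(r-1, c-1, r, c)}.
#'
#' @slot rowStart,colStart,rowEnd,colEnd integer scalars, 0-based half-open.
#' @export
setClass("BoundingBox",
  representation(rowStart = "integer", colStart = "integer",
                 rowEnd = "integer", colEnd = "integer"),
  validity = function(object) {
    v <- c(object@rowStart, object@colStart, object@rowEnd, object@colEnd)
    if (any(is.na(v))) return("bounding box indices must not be NA")
    if (object@rowStart < 0L || object@colStart < 0L)
      return("bounding box start indices must be >= 0")
    if (object@rowEnd <= object@rowStart || object@colEnd <= object@colStart)
      return("bounding box must satisfy start < end on both axes")
    TRUE
  })

#' @rdname BoundingBox-class
#' @param rowStart,colStart,rowEnd,colEnd 0-based half-open pixel indices.
#' @return A \code{BoundingBox} object.
#' @examples
#' BoundingBox(2, 3, 5, 7)   # rows 2..4, cols 3..6 (0-based)
#' @export
BoundingBox <- function(rowStart, colStart, rowEnd, colEnd) {
  new("BoundingBox", rowStart = as.integer(rowStart),
      colStart = as.integer(colStart), rowEnd = as.integer(rowEnd),
      colEnd = as.integer(colEnd))
}

#' Cropped thyroid region of interest
#'
#' The grayscale crop of the detected thyroid band together with its bounding
#' box in source-image coordinates and the source frame dimensions.
#'
#' @slot pixels numeric matrix of intensities in [0, 255], the crop itself.
#' @slot box \code{\linkS4class{BoundingBox}} of the crop in the source image.
#' @slot sourceShape integer vector (height, width) of the source image.
#' @export
setClass("ThyroidROI",
  representation(pixels = "matrix", box = "BoundingBox",
                 sourceShape = "integer"),
  validity = function(object) {
    b <- object@box
    if (length(object@sourceShape) != 2L)
      return("sourceShape must be (height, width)")
    if (b@rowEnd > object@sourceShape[1L] || b@colEnd > object@sourceShape[2L])
      return("bounding box exceeds source image extent")
    if (nrow(object@pixels) != b@rowEnd - b@rowStart ||
        ncol(object@pixels) != b@colEnd - b@colStart)
      return("pixel crop dimensions do not match the bounding box")
    TRUE
  })

ThyroidROI <- function(pixels, box, sourceShape) {
  new("ThyroidROI", pixels = pixels, box = box,
      sourceShape = as.integer(sourceShape))
}

#' Frequency-region mask parameters
#'
#' Describes the selected low-frequency region of the centered power spectrum:
#' a circle around the DC (zero-frequency) bin whose radius is
#' \code{radiusFraction} times half the smaller spectrum dimension.
#'
#' @slot shapeKind character, currently only \code{"circle"}.
#' @slot radiusFraction numeric in (0, 1].
#' @slot includeDC logical; whether the DC bin counts towards both the
#'   selected and the total power.
#' @export
setClass("FrequencyRegion",
  representation(shapeKind = "character", radiusFraction = "numeric",
                 includeDC = "logical"),
  validity = function(object) {
    if (!identical(object@shapeKind, "circle"))
      return("only the 'circle' frequency region is supported")
    if (object@radiusFraction <= 0 || object@radiusFraction > 1)
      return("radiusFraction must lie in (0, 1]")
    TRUE
  })

#' @rdname FrequencyRegion-class
#' @param radiusFraction circle radius as a fraction of half the smaller
#'   spectrum dimension; default 0.1.
#' @param includeDC include the DC bin in both numerator and denominator
#'   (default \code{TRUE}).
#' @param shapeKind region shape; only \code{"circle"} is implemented.
#' @return A \code{FrequencyRegion} object.
#' @export
FrequencyRegion <- function(radiusFraction = 0.1, includeDC = TRUE,
                            shapeKind = "circle") {
  new("FrequencyRegion", shapeKind = shapeKind,
      radiusFraction = radiusFraction, includeDC = includeDC)
}

#' Power-spectrum ratio score
#'
#' The fraction of an image's DFT power falling inside the selected
#' low-frequency region: \code{value = pSelected / pTotal}.
#'
#' @slot value numeric in [0, 1].
#' @slot pTotal,pSelected nonnegative total and in-region power.
#' @slot region the \code{\linkS4class{FrequencyRegion}} that produced it.
#' @export
setClass("FrequencyScore",
  representation(value = "numeric", pTotal = "numeric",
                 pSelected = "numeric", region = "FrequencyRegion"),
  validity = function(object) {
    if (object@pTotal < 0 || object@pSelected < 0)
      return("power values must be nonnegative")
    if (object@pSelected > object@pTotal * (1 + 1e-12))
      return("selected power cannot exceed total power")
    if (object@pTotal > 0 &&
        abs(object@value - object@pSelected / object@pTotal) > 1e-9)
      return("value must equal pSelected / pTotal")
    TRUE
  })

#' Dual thresholds of the coarse frequency classifier
#'
#' Scores strictly below \code{thLow} are decided benign, strictly above
#' \code{thHigh} malign, anything else (including ties) is ambiguous and is
#' deferred to the fine classifier. A collapsed side is \code{-Inf} /
#' \code{+Inf} and never fires.
#'
#' @slot thLow,thHigh numeric with \code{thLow <= thHigh}.
#' @export
setClass("CoarseThresholds",
  representation(thLow = "numeric", thHigh = "numeric"),
  validity = function(object) {
    if (is.na(object@thLow) || is.na(object@thHigh))
      return("thresholds must not be NA")
    if (object@thLow > object@thHigh)
      return("thLow must be <= thHigh")
    TRUE
  })

#' @rdname CoarseThresholds-class
#' @param thLow,thHigh lower and upper score thresholds.
#' @return A \code{CoarseThresholds} object.
#' @export
CoarseThresholds <- function(thLow, thHigh) {
  new("CoarseThresholds", thLow = as.numeric(thLow),
      thHigh = as.numeric(thHigh))
}

#' Per-model classification score
#'
#' The probability of the benign class emitted by one network head. All
#' scores in the package are probability-of-benign (benign = 1 encoding).
#'
#' @slot pBenign numeric in [0, 1].
#' @slot modelId character identifying the cascade slot
#'   (\code{"resnet"} or \code{"inception"}).
#' @export
setClass("ClassScore",
  representation(pBenign = "numeric", modelId = "character"),
  validity = function(object) {
    if (is.na(object@pBenign) || object@pBenign < 0 || object@pBenign > 1)
      return("pBenign must lie in [0, 1]")
    TRUE
  })

#' Fused classification score
#'
#' Result of combining the two heads' probability-of-benign scores by one of
#' the MIN, MAX or SUM rules (SUM is the arithmetic mean of the two scores).
#'
#' @slot value fused score in [0, 1], always between min and max of inputs.
#' @slot rule one of \code{"min"}, \code{"max"}, \code{"sum"}.
#' @slot s1,s2 the two input scores.
#' @export
setClass("FusedScore",
  representation(value = "numeric", rule = "character",
                 s1 = "numeric", s2 = "numeric"),
  validity = function(object) {
    if (!object@rule %in% c("min", "max", "sum"))
      return("rule must be one of 'min', 'max', 'sum'")
    lo <- min(object@s1, object@s2); hi <- max(object@s1, object@s2)
    if (object@value < lo - 1e-12 || object@value > hi + 1e-12)
      return("fused value must lie between min(s1,s2) and max(s1,s2)")
    TRUE
  })

setClassUnion("FusedScoreOrNULL", c("FusedScore", "NULL"))

#' End-to-end cascade decision for one image
#'
#' @slot label final decision, \code{"benign"} or \code{"malign"}.
#' @slot path \code{"coarse"} if the frequency stage decided, \code{"fine"}
#'   if the CNN ensemble was invoked.
#' @slot coarse the coarse-stage outcome
#'   (\code{"benign"}, \code{"malign"}, \code{"ambiguous"}).
#' @slot fused the \code{\linkS4class{FusedScore}} when \code{path == "fine"},
#'   otherwise \code{NULL}.
#' @export
setClass("CascadeResult",
  representation(label = "character", path = "character",
                 coarse = "character", fused = "FusedScoreOrNULL"),
  validity = function(object) {
    if (!object@label %in% .LABELS) return("label must be benign or malign")
    if (!object@path %in% c("coarse", "fine"))
      return("path must be 'coarse' or 'fine'")
    if (object@path == "coarse") {
      if (!is.null(object@fused))
        return("coarse-path results carry no fused score")
      if (object@coarse == "ambiguous")
        return("coarse path requires a decided coarse outcome")
    } else {
      if (object@coarse != "ambiguous")
        return("fine path requires an ambiguous coarse outcome")
      if (is.null(object@fused))
        return("fine-path results must carry a fused score")
    }
    TRUE
  })

#' Confusion counts (malign is the positive class)
#'
#' @slot tp,fn,tn,fp nonnegative integers: true positives (malign correctly
#'   called malign), false negatives, true negatives (benign correctly called
#'   benign), false positives.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fn = "integer",
                 tn = "integer", fp = "integer"),
  validity = function(object) {
    v <- c(object@tp, object@fn, object@tn, object@fp)
    if (any(is.na(v)) || any(v < 0L))
      return("confusion counts must be nonnegative integers")
    TRUE
  })

#' @rdname ConfusionCounts-class
#' @param tp,fn,tn,fp nonnegative integer counts.
#' @return A \code{ConfusionCounts} object.
#' @export
ConfusionCounts <- function(tp, fn, tn, fp) {
  new("ConfusionCounts", tp = as.integer(tp), fn = as.integer(fn),
      tn = as.integer(tn), fp = as.integer(fp))
}

#' Evaluation report
#'
#' Confusion counts plus sensitivity = TP/(TP+FN), specificity = TN/(TN+FP)
#' and accuracy = (TP+TN)/N. A metric whose class is absent from the ground
#' truth is \code{NA} (undefined), never silently 0.
#'
#' @slot counts \code{\linkS4class{ConfusionCounts}}.
#' @slot sensitivity,specificity,accuracy numeric in [0, 1] or \code{NA}.
#' @slot foldId integer fold index, \code{NA} outside cross-validation.
#' @export
setClass("EvalReport",
  representation(counts = "ConfusionCounts", sensitivity = "numeric",
                 specificity = "numeric", accuracy = "numeric",
                 foldId = "integer"))

#' Patient-level fold assignment
#'
#' @slot k number of folds.
#' @slot assignments named integer vector mapping patient id to fold index
#'   in \code{0:(k-1)}; all images of a patient share its fold.
#' @slot seed integer seed that produced the shuffle.
#' @export
setClass("FoldSplit",
  representation(k = "integer", assignments = "integer", seed = "integer"),
  validity = function(object) {
    if (object@k < 2L) return("k must be >= 2")
    if (is.null(names(object@assignments)))
      return("assignments must be named by patient id")
    if (any(object@assignments < 0L | object@assignments >= object@k))
      return("fold indices must lie in [0, k)")
    TRUE
  })

#' Dataset manifest
#'
#' Ordered collection of labeled samples: one row per image with its file
#' path, patient id, TI-RADS category and the derived binary label.
#'
#' @slot samples data.frame with columns \code{image_path},
#'   \code{patient_id}, \code{tirads}, \code{label}.
#' @slot origin \code{"real"} or \code{"synthetic"}.
#' @export
setClass("Manifest",
  representation(samples = "data.frame", origin = "character"),
  validity = function(object) {
    need <- c("image_path", "patient_id", "tirads", "label")
    if (!all(need %in% names(object@samples)))
      return(paste("samples must have columns:", paste(need, collapse = ", ")))
    if (!object@origin %in% c("real", "synthetic"))
      return("origin must be 'real' or 'synthetic'")
    if (anyDuplicated(object@samples$image_path))
      return("duplicate image_path entries are not allowed")
    if (nrow(object@samples) > 0 && any(!nzchar(object@samples$patient_id)))
      return("patient_id must be non-empty")
    TRUE
  })

#' Network head specification
#'
#' The classifier head is the fixed sequence global average pooling ->
#' batch normalization -> dropout -> dense layer to 2 softmax outputs, on top
#' of one of three convolutional backbones. \code{resnet50} and
#' \code{inception_v3} are exact layer-by-layer enumerations of the canonical
#' architectures (pooled feature width 2048); \code{tiny} is a compact
#' three-block backbone that is fully trainable inside R and is intended for
#' desk-scale experiments and synthetic data.
#'
#' @slot backbone one of \code{"resnet50"}, \code{"inception_v3"},
#'   \code{"tiny"}.
#' @slot inputSide input image side in pixels.
#' @slot dropout dropout rate of the head, default 0.5.
#' @export
setClass("HeadSpec",
  representation(backbone = "character", inputSide = "integer",
                 dropout = "numeric"),
  validity = function(object) {
    if (!object@backbone %in% c("resnet50", "inception_v3", "tiny"))
      return("backbone must be 'resnet50', 'inception_v3' or 'tiny'")
    if (object@inputSide < 32L) return("inputSide must be >= 32")
    if (object@dropout < 0 || object@dropout >= 1)
      return("dropout must lie in [0, 1)")
    TRUE
  })

#' @rdname HeadSpec-class
#' @param backbone backbone kind.
#' @param inputSide input side in pixels; defaults to 224 for the reference
#'   backbones and 32 for \code{tiny}.
#' @param dropout head dropout rate.
#' @return A \code{HeadSpec} object.
#' @export
HeadSpec <- function(backbone = c("resnet50", "inception_v3", "tiny"),
                     inputSide = NULL, dropout = 0.5) {
  backbone <- match.arg(backbone)
  if (is.null(inputSide))
    inputSide <- if (backbone == "tiny") 32L else 224L
  new("HeadSpec", backbone = backbone, inputSide = as.integer(inputSide),
      dropout = dropout)
}

#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam, 30 epochs, batch
#' size 32, learning rate 1e-4, stop at end of epochs, class weights
#' (w0, w1) = (0.7, 0.3) with w0 on the benign (minority) class.
#'
#' @slot optimizer only \code{"adam"}.
#' @slot epochs,batchSize positive integers.
#' @slot learningRate positive step size.
#' @slot lossWeights numeric (w0, w1), nonnegative, not both zero.
#' @slot seed integer; every source of training randomness derives from it.
#' @slot pretrainedBackbone logical; \code{FALSE} means random backbone init.
#' @export
setClass("TrainConfig",
  representation(optimizer = "character", epochs = "integer",
                 batchSize = "integer", learningRate = "numeric",
                 lossWeights = "numeric", seed = "integer",
                 pretrainedBackbone = "logical"),
  validity = function(object) {
    if (!identical(object@optimizer, "adam"))
      return("only the 'adam' optimizer is supported")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (length(object@lossWeights) != 2L || any(object@lossWeights < 0) ||
        sum(object@lossWeights) <= 0)
      return("lossWeights must be two nonnegative values, not both zero")
    TRUE
  })

#' @rdname TrainConfig-class
#' @param epochs,batchSize,learningRate,lossWeights,seed,pretrainedBackbone
#'   see slots.
#' @param optimizer optimizer name; only \code{"adam"}.
#' @return A \code{TrainConfig} object.
#' @export
TrainConfig <- function(epochs = 30, batchSize = 32, learningRate = 1e-4,
                        lossWeights = c(0.7, 0.3), seed = 1,
                        pretrainedBackbone = FALSE, optimizer = "adam") {
  new("TrainConfig", optimizer = optimizer, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      lossWeights = as.numeric(lossWeights), seed = as.integer(seed),
      pretrainedBackbone = pretrainedBackbone)
}

#' Convolutional network model handle
#'
#' @slot spec the \code{\linkS4class{HeadSpec}} that built it.
#' @slot layers data.frame enumerating every layer with its output shape,
#'   parameter count and part (backbone / pool / batch_norm / dropout /
#'   dense).
#' @slot weights list of weight arrays (empty for the weight-free reference
#'   backbones).
#' @slot modelId cascade slot id.
#' @slot trained logical.
#' @slot lossLog numeric per-epoch mean training loss.
#' @export
setClass("CNNModel",
  representation(spec = "HeadSpec", layers = "data.frame", weights = "list",
                 modelId = "character", trained = "logical",
                 lossLog = "numeric"))

#' Phantom generator parameters
#'
#' Study conditions of the synthetic ultrasound phantoms: a dark border frame
#' with small bright artifact blobs, a large bright speckled thyroid band,
#' and (for malign phantoms) a round hypoechoic nodule carrying bright
#' calcification specks whose contrast scales with \code{classSeparation}.
#'
#' @slot frameSize integer (height, width); default (360, 560), the frame
#'   size of typical clinical ultrasound exports.
#' @slot borderFraction fraction of each dimension taken by the dark border.
#' @slot thyroidMean,backgroundMean mean intensities of band and border;
#'   thyroid must be much brighter.
#' @slot speckleSigma log-sd of the multiplicative log-normal speckle.
#' @slot nArtifacts number of small bright border blobs.
#' @slot noduleRadiusRange (lo, hi) nodule radius in pixels.
#' @slot calcificationCount bright specks per malign nodule.
#' @slot classSeparation nonnegative scale of the benign/malign spectral
#'   contrast; 0 makes the two classes indistinguishable.
#' @slot seed integer seed; phantoms are bitwise reproducible.
#' @export
setClass("PhantomParams",
  representation(frameSize = "integer", borderFraction = "numeric",
                 thyroidMean = "numeric", backgroundMean = "numeric",
                 speckleSigma = "numeric", nArtifacts = "integer",
                 noduleRadiusRange = "numeric", calcificationCount = "integer",
                 classSeparation = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@frameSize) != 2L || any(object@frameSize < 48L))
      return("frameSize must be (height, width), each >= 48")
    if (object@thyroidMean <= object@backgroundMean)
      return("thyroidMean must exceed backgroundMean")
    if (object@borderFraction <= 0 || object@borderFraction >= 0.4)
      return("borderFraction must lie in (0, 0.4)")
    if (object@classSeparation < 0)
      return("classSeparation must be >= 0")
    if (length(object@noduleRadiusRange) != 2L ||
        object@noduleRadiusRange[1] > object@noduleRadiusRange[2])
      return("noduleRadiusRange must be (lo, hi) with lo <= hi")
    TRUE
  })

#' @rdname PhantomParams-class
#' @param frameSize,borderFraction,thyroidMean,backgroundMean,speckleSigma
#'   see slots.
#' @param nArtifacts,noduleRadiusRange,calcificationCount,classSeparation,seed
#'   see slots.
#' @return A \code{PhantomParams} object.
#' @export
PhantomParams <- function(frameSize = c(360, 560), borderFraction = 0.12,
                          thyroidMean = 170, backgroundMean = 12,
                          speckleSigma = 0.18, nArtifacts = 3,
                          noduleRadiusRange = c(25, 45),
                          calcificationCount = 6, classSeparation = 1,
                          seed = 1) {
  new("PhantomParams", frameSize = as.integer(frameSize),
      borderFraction = borderFraction, thyroidMean = thyroidMean,
      backgroundMean = backgroundMean, speckleSigma = speckleSigma,
      nArtifacts = as.integer(nArtifacts),
      noduleRadiusRange = as.numeric(noduleRadiusRange),
      calcificationCount = as.integer(calcificationCount),
      classSeparation = classSeparation, seed = as.integer(seed))
}

#' One synthetic phantom image
#'
#' @slot image numeric matrix in [0, 255].
#' @slot label \code{"benign"} or \code{"malign"}.
#' @slot truthROI ground-truth \code{\linkS4class{BoundingBox}} of the
#'   thyroid band.
#' @slot patientId opaque patient identifier.
#' @export
setClass("PhantomSample",
  representation(image = "matrix", label = "character",
                 truthROI = "BoundingBox", patientId = "character"),
  validity = function(object) {
    if (!object@label %in% .LABELS) return("label must be benign or malign")
    b <- object@truthROI
    if (b@rowStart < 1L || b@colStart < 1L ||
        b@rowEnd > nrow(object@image) - 1L ||
        b@colEnd > ncol(object@image) - 1L)
      return("truthROI must lie strictly inside the frame")
    TRUE
  })

#' Calibrated cascade model
#'
#' Bundles everything the cascade needs at inference time: the coarse
#' thresholds, the two trained network heads, the fusion rule and the fused
#' decision threshold, plus the preprocessing/spectrum configuration used
#' during calibration.
#'
#' @slot thresholds \code{\linkS4class{CoarseThresholds}}.
#' @slot models list of two \code{\linkS4class{CNNModel}} objects.
#' @slot rule fusion rule.
#' @slot decisionThreshold fused-score threshold (benign strictly above).
#' @slot config named list of pipeline settings (see
#'   \code{\link{cascadeConfig}}).
#' @export
setClass("CascadeModel",
  representation(thresholds = "CoarseThresholds", models = "list",
                 rule = "character", decisionThreshold = "numeric",
                 config = "list"))
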