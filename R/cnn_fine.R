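#' @include AllClasses.R architectures.R nnet.R
NULL

#' Build a classifier head
#'
#' Instantiates one of the three network architectures as a
#' \code{\linkS4class{CNNModel}}: the convolutional backbone followed by the
#' fixed head (global average pooling, batch normalization over the pooled
#' features, dropout, and a dense layer to 2 softmax outputs). The
#' \code{resnet50} and \code{inception_v3} backbones are exact layer
#' enumerations with full parameter accounting (backbone totals 23,587,712
#' and 21,802,784 at 224x224x3) but carry no weights; the \code{tiny}
#' backbone is initialized and fully trainable in R.
#'
#' The dense layer is zero-initialized, so an untrained head always returns
#' a probability-of-benign of exactly 0.5.
#'
#' @param spec a \code{\linkS4class{HeadSpec}}.
#' @param modelId cascade slot id recorded in emitted scores
#'   (\code{"resnet"} or \code{"inception"}).
#' @param initSeed seed for backbone weight initialization of the
#'   \code{tiny} backbone (training re-initializes from its own seed).
#' @return a \code{\linkS4class{CNNModel}}.
#' @examples
#' m <- buildHead(HeadSpec("resnet50"))
#' countParameters(m, "backbone")
#' @export
buildHead <- function(spec, modelId = "resnet", initSeed = 0L) {
  stopifnot(is(spec, "HeadSpec"))
  layers <- .architectureTable(spec)
  weights <- if (spec@backbone == "tiny") {
    .withSeed(initSeed, .tinyInitWeights())
  } else list()
  new("CNNModel", spec = spec, layers = layers, weights = weights,
      modelId = modelId, trained = FALSE, lossLog = numeric(0))
}

## evaluate expr under a local RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Count model parameters
#'
#' Sums the per-layer parameter counts of a built model. Counts include
#' bias vectors where the canonical architecture defines them and all
#' per-feature batch-normalization vectors (scale, offset, moving mean,
#' moving variance), the convention under which the reference backbones
#' reproduce their published totals.
#'
#' @param model a \code{\linkS4class{CNNModel}} (or a
#'   \code{\linkS4class{HeadSpec}}).
#' @param part \code{"total"} or one of \code{"backbone"},
#'   \code{"batch_norm"}, \code{"dense"}, \code{"pool"}, \code{"dropout"}.
#' @return integer parameter count.
#' @examples
#' countParameters(buildHead(HeadSpec("inception_v3")), "backbone")
#' @export
countParameters <- function(model, part = c("total", "backbone",
                                            "batch_norm", "dense", "pool",
                                            "dropout")) {
  part <- match.arg(part)
  if (is(model, "HeadSpec")) model <- buildHead(model)
  stopifnot(is(model, "CNNModel"))
  tab <- model@layers
  if (part == "total") return(as.integer(sum(tab$params)))
  sel <- tab$part == part
  if (!any(sel)) stop("architecture has no '", part, "' layers")
  as.integer(sum(tab$params[sel]))
}

.clipP <- function(p) pmin(pmax(p, .EPS_P), 1 - .EPS_P)

#' Binary cross-entropy loss
#'
#' \code{-y log(p) - (1-y) log(1-p)} with natural logarithms, averaged over
#' samples. \code{y = 1} encodes the benign class and \code{p} is the
#' predicted probability-of-benign. Probabilities are clipped to
#' \code{[1e-7, 1 - 1e-7]} before the logarithm.
#'
#' @param y 0/1 ground-truth vector (1 = benign).
#' @param p predicted probability-of-benign, same length.
#' @return nonnegative scalar, the mean loss.
#' @examples
#' bceLoss(1, 0.5)   # log(2)
#' @export
bceLoss <- function(y, p) {
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  p <- .clipP(p)
  mean(-y * log(p) - (1 - y) * log(1 - p))
}

#' Class-weighted binary cross-entropy loss
#'
#' \code{-w0 y log(p) - w1 (1-y) log(1-p)}, averaged over samples. The
#' benign term carries \code{w0} because benign is the minority class in
#' typical thyroid datasets; the default weights are (0.7, 0.3). With
#' \code{w0 = w1 = 1} this reduces to \code{\link{bceLoss}}.
#'
#' @param y 0/1 ground-truth vector (1 = benign).
#' @param p predicted probability-of-benign.
#' @param w0 weight of the benign (y = 1) term.
#' @param w1 weight of the malign (y = 0) term.
#' @return nonnegative scalar, the mean loss.
#' @examples
#' wbceLoss(1, 0.5, 0.7, 0.3)   # 0.7 * log(2)
#' @export
wbceLoss <- function(y, p, w0 = 0.7, w1 = 0.3) {
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  if (w0 < 0 || w1 < 0 || w0 + w1 <= 0)
    stop("weights must be nonnegative and not both zero")
  p <- .clipP(p)
  mean(-w0 * y * log(p) - w1 * (1 - y) * log(1 - p))
}

## coerce a list of side x side x 3 arrays (or a 4-d array) to (H, W, C, B)
.stackInputs <- function(x, side) {
  if (is.list(x)) {
    ok <- vapply(x, function(a) length(dim(a)) == 3L &&
                   all(dim(a) == c(side, side, 3L)), TRUE)
    if (!all(ok))
      stop("input rasters must all be ", side, "x", side, "x3")
    arr <- array(unlist(x, use.names = FALSE), c(side, side, 3L, length(x)))
  } else {
    d <- dim(x)
    if (length(d) != 4L || !all(d[1:3] == c(side, side, 3L)))
      stop("input rasters must be an array ", side, "x", side, "x3xN")
    arr <- x
  }
  arr
}

#' Train a classifier head
#'
#' Minimizes the class-weighted binary cross-entropy with Adam for a fixed
#' number of epochs (the stop criterion is end-of-epochs). All randomness —
#' weight initialization, epoch shuffling, dropout — derives from
#' \code{cfg@seed}, so identical configuration and data give a
#' bitwise-identical loss log. Only the \code{tiny} backbone is trainable;
#' the reference backbones are weight-free architecture enumerations.
#'
#' @param model a \code{\linkS4class{CNNModel}} with the \code{tiny}
#'   backbone.
#' @param x training rasters: list of \code{side x side x 3} arrays (see
#'   \code{\link{normalizeForCNN}}) or a 4-d array with samples last.
#' @param labels character vector of \code{"benign"} / \code{"malign"} (or
#'   a 0/1 vector with 1 = benign).
#' @param cfg a \code{\linkS4class{TrainConfig}}.
#' @return the trained \code{\linkS4class{CNNModel}}; slot \code{lossLog}
#'   holds the per-epoch mean training loss.
#' @export
trainHead <- function(model, x, labels, cfg = TrainConfig()) {
  stopifnot(is(model, "CNNModel"), is(cfg, "TrainConfig"))
  if (model@spec@backbone != "tiny")
    stop("backbone '", model@spec@backbone, "' is a weight-free ",
         "architecture enumeration; training requires backbone = 'tiny'")
  y <- if (is.character(labels)) .labelY(labels) else as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be benign/malign (or 0/1)")
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; the loss is degenerate")
  side <- model@spec@inputSide
  arr <- .stackInputs(x, side)
  n <- dim(arr)[4L]
  if (length(y) != n) stop("labels and rasters differ in length")
  w0 <- cfg@lossWeights[1]; w1 <- cfg@lossWeights[2]
  dropout <- model@spec@dropout
  .withSeed(cfg@seed, {
    w <- .tinyInitWeights()
    state <- .adamInit(w)
    t <- 0L
    lossLog <- numeric(cfg@epochs)
    for (epoch in seq_len(cfg@epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg@batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg@batchSize - 1L, n)]
        a <- arr[, , , idx, drop = FALSE]
        yb <- y[idx]
        B <- length(idx)
        fw <- .tinyForward(w, a, train = TRUE, dropout = dropout)
        P <- fw$probs
        pb <- .clipP(P[, 1L])
        loss <- mean(-w0 * yb * log(pb) - w1 * (1 - yb) * log(1 - pb))
        epochLoss <- epochLoss + loss * B
        target <- cbind(yb, 1 - yb)
        sw <- ifelse(yb == 1, w0, w1)
        dLogits <- (P - target) * sw / B
        gr <- .tinyBackward(w, fw$cache, dLogits)
        t <- t + 1L
        upd <- .adamStep(w, gr, state, t, cfg@learningRate)
        w <- upd$w; state <- upd$state
        ## running batch-norm statistics (momentum 0.9)
        w$bn$rmean <- 0.9 * w$bn$rmean + 0.1 * fw$cache$bn$mu
        w$bn$rvar <- 0.9 * w$bn$rvar + 0.1 * fw$cache$bn$va
      }
      lossLog[epoch] <- epochLoss / n
    }
    ## inference-time batch-norm statistics: re-estimated exactly over the
    ## training set with the final weights (running averages lag badly on
    ## short schedules)
    feat <- matrix(0, n, length(w$bn$rmean))
    for (s in seq(1L, n, by = 64L)) {
      idx <- s:min(s + 63L, n)
      feat[idx, ] <- .tinyFeatures(w, arr[, , , idx, drop = FALSE])
    }
    w$bn$rmean <- colMeans(feat)
    w$bn$rvar <- colMeans(feat^2) - colMeans(feat)^2
    model@weights <- w
    model@trained <- TRUE
    model@lossLog <- lossLog
    model
  })
}

## batched inference; returns probability-of-benign vector
.predictBatch <- function(model, arr) {
  n <- dim(arr)[4L]
  out <- numeric(n)
  for (s in seq(1L, n, by = 64L)) {
    idx <- s:min(s + 63L, n)
    fw <- .tinyForward(model@weights, arr[, , , idx, drop = FALSE],
                       train = FALSE, dropout = 0)
    out[idx] <- fw$probs[, 1L]
  }
  out
}

#' Predict the class score for one raster
#'
#' Runs the head in inference mode (dropout off, batch normalization using
#' its moving statistics) and returns the softmax probability of the benign
#' class. Deterministic: repeated calls on the same input give identical
#' scores.
#'
#' @param model a built (and normally trained) \code{\linkS4class{CNNModel}}
#'   with the \code{tiny} backbone.
#' @param raster a \code{side x side x 3} array in [0, 1].
#' @return a \code{\linkS4class{ClassScore}}.
#' @export
predictScore <- function(model, raster) {
  stopifnot(is(model, "CNNModel"))
  if (model@spec@backbone != "tiny")
    stop("backbone '", model@spec@backbone, "' is a weight-free ",
         "architecture enumeration; prediction requires backbone = 'tiny'")
  side <- model@spec@inputSide
  d <- dim(raster)
  if (is.null(d) || length(d) != 3L || !all(d == c(side, side, 3L)))
    stop("raster must be ", side, "x", side, "x3 for this head")
  arr <- array(raster, c(side, side, 3L, 1L))
  new("ClassScore", pBenign = .predictBatch(model, arr),
      modelId = model@modelId)
}
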