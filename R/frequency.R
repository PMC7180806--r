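#' @include AllClasses.R preprocessing.R
NULL

.fftshiftIdx <- function(n) {
  if (n == 1L) return(1L)
  h <- ceiling(n / 2)
  c((h + 1L):n, 1L:h)
}

## DC position of the centered spectrum (1-based)
.dcPos <- function(n) floor(n / 2) + 1L

#' Centered 2-D power spectrum
#'
#' Squared magnitude of the 2-D discrete Fourier transform with the
#' zero-frequency (DC) component shifted to the array center, at position
#' \code{(floor(H/2)+1, floor(W/2)+1)}. Satisfies Parseval's identity:
#' \code{sum(powerSpectrum(x)) == length(x) * sum(x^2)}.
#'
#' @param x numeric matrix.
#' @return nonnegative numeric matrix of the same shape.
#' @export
powerSpectrum <- function(x) {
  stopifnot(is.matrix(x), length(x) > 0)
  p <- Mod(stats::fft(x))^2
  p[.fftshiftIdx(nrow(p)), .fftshiftIdx(ncol(p)), drop = FALSE]
}

#' Frequency power-ratio score of an ROI
#'
#' The coarse-classifier feature: the ratio \code{Score = Ps / P} between
#' the power spectrum summed inside the selected low-frequency region
#' (\code{Ps}) and the total spectrum power (\code{P}). The region is a
#' circle of radius \code{radiusFraction * min(H, W) / 2} bins around the DC
#' component. The score is invariant to intensity scaling and lies in
#' [0, 1]; it is non-decreasing in the circle radius.
#'
#' When \code{spectrumSide} is given, the raster is first bilinearly resized
#' to that square size so that scores are comparable across ROI sizes and
#' aspect ratios (the pipeline default is 256).
#'
#' @param pixels numeric matrix (an ROI crop), not all zero.
#' @param region a \code{\linkS4class{FrequencyRegion}}.
#' @param spectrumSide optional square size for the spectrum grid;
#'   \code{NULL} computes the spectrum on the raster as-is.
#' @return a \code{\linkS4class{FrequencyScore}}.
#' @export
fftScore <- function(pixels, region = FrequencyRegion(),
                     spectrumSide = NULL) {
  stopifnot(is.matrix(pixels), is(region, "FrequencyRegion"))
  if (!is.null(spectrumSide))
    pixels <- .resizeBilinear(pixels, as.integer(spectrumSide),
                              as.integer(spectrumSide))
  p <- powerSpectrum(pixels)
  H <- nrow(p); W <- ncol(p)
  dr <- seq_len(H) - .dcPos(H)
  dc <- seq_len(W) - .dcPos(W)
  d2 <- outer(dr^2, dc^2, `+`)
  r <- region@radiusFraction * min(H, W) / 2
  sel <- d2 <= r^2
  if (!region@includeDC) {
    p[.dcPos(H), .dcPos(W)] <- 0          # drop DC from both Ps and P
    sel[.dcPos(H), .dcPos(W)] <- FALSE
  }
  total <- sum(p)
  if (total <= 0) stop("zero total power: ROI carries no signal")
  ps <- sum(p[sel])
  new("FrequencyScore", value = ps / total, pTotal = total, pSelected = ps,
      region = region)
}

#' Ternary coarse decision
#'
#' Scores strictly below \code{thLow} are \code{"benign"}, strictly above
#' \code{thHigh} \code{"malign"}; everything else — including exact equality
#' with either threshold — is \code{"ambiguous"} and is deferred to the fine
#' classifier.
#'
#' @param score a \code{\linkS4class{FrequencyScore}} or a bare numeric.
#' @param th a \code{\linkS4class{CoarseThresholds}}.
#' @return \code{"benign"}, \code{"malign"} or \code{"ambiguous"}.
#' @export
coarseClassify <- function(score, th) {
  stopifnot(is(th, "CoarseThresholds"))
  v <- if (is(score, "FrequencyScore")) score@value else as.numeric(score)
  if (v < th@thLow) "benign"
  else if (v > th@thHigh) "malign"
  else "ambiguous"
}

## purity of one tail: fraction of `want` among labels[sel]; empty -> NA
.tailOk <- function(sel, labels, want, purity) {
  n <- sum(sel)
  n > 0 && mean(labels[sel] == want) >= purity
}

#' Calibrate the dual coarse thresholds from training scores
#'
#' Sweeps candidate thresholds (the observed score values and the midpoints
#' of adjacent distinct values) and picks \code{thLow} as the largest cut
#' whose strictly-below tail is at least \code{purity} benign, and
#' \code{thHigh} as the smallest cut whose strictly-above tail is at least
#' \code{purity} malign. A side with no satisfying cut collapses to
#' \code{-Inf} / \code{+Inf} and never fires. If the two independently
#' fitted sides cross (well-separated data), both collapse onto the single
#' cut that maximizes the number of decided training samples subject to both
#' purity constraints, so the thresholds always satisfy
#' \code{thLow <= thHigh}.
#'
#' @param values numeric training scores.
#' @param labels parallel character labels, \code{"benign"}/\code{"malign"}.
#' @param purity per-side purity requirement in (0.5, 1]; default 0.95.
#' @return a \code{\linkS4class{CoarseThresholds}}.
#' @export
calibrateThresholds <- function(values, labels, purity = 0.95) {
  stopifnot(length(values) == length(labels), length(values) > 0)
  if (purity <= 0.5 || purity > 1) stop("purity must lie in (0.5, 1]")
  if (!all(.LABELS %in% labels))
    stop("calibration needs at least one sample of each class")
  sv <- sort(unique(values))
  cand <- sort(unique(c(sv, if (length(sv) > 1)
    (sv[-1] + sv[-length(sv)]) / 2)))
  lowOk <- vapply(cand, function(t)
    .tailOk(values < t, labels, "benign", purity), TRUE)
  highOk <- vapply(cand, function(t)
    .tailOk(values > t, labels, "malign", purity), TRUE)
  thLow <- if (any(lowOk)) max(cand[lowOk]) else -Inf
  thHigh <- if (any(highOk)) min(cand[highOk]) else Inf
  if (thLow > thHigh) {
    ## sides crossed: collapse to one cut, keeping both tails pure
    decided <- vapply(cand, function(t) {
      below <- values < t; above <- values > t
      okB <- sum(below) == 0 || .tailOk(below, labels, "benign", purity)
      okA <- sum(above) == 0 || .tailOk(above, labels, "malign", purity)
      if (!okB || !okA) return(-1)
      sum(below) * .tailOk(below, labels, "benign", purity) +
        sum(above) * .tailOk(above, labels, "malign", purity)
    }, 0)
    if (max(decided) < 0) return(CoarseThresholds(-Inf, Inf))
    best <- cand[decided == max(decided)]
    t <- best[which.min(abs(best - stats::median(values)))]
    thLow <- thHigh <- t
  }
  CoarseThresholds(thLow, thHigh)
}
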