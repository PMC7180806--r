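#' @include AllClasses.R
NULL

#' Otsu threshold of a grayscale raster
#'
#' Computes the integer threshold in [0, 255] that maximizes the
#' between-class variance of the 256-bin intensity histogram. Foreground is
#' defined as pixels strictly greater than the threshold. Ties in the
#' objective are resolved towards the smallest maximizing threshold. A
#' constant image has no between-class variance; the returned threshold then
#' leaves the foreground empty and carries the attribute
#' \code{degenerate = TRUE}.
#'
#' @param gray numeric matrix with values in [0, 255].
#' @return integer threshold, with attribute \code{degenerate} (logical).
#' @examples
#' otsuThreshold(matrix(c(10, 10, 200, 200), 2))
#' @export
otsuThreshold <- function(gray) {
  if (length(gray) == 0) stop("empty raster")
  bins <- pmin(pmax(floor(as.numeric(gray)), 0), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  n <- sum(h)
  ## class 0 = bins 0..t (background), class 1 = bins (t+1)..255 (foreground)
  w0 <- cumsum(h)[1:255]
  w1 <- n - w0
  sum0 <- cumsum(h * (0:255))[1:255]
  mu0 <- ifelse(w0 > 0, sum0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum0[255] + h[256] * 255 - sum0) / w1, 0)
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) {
    t <- as.integer(bins[1])          # constant image: empty foreground
    attr(t, "degenerate") <- TRUE
    return(t)
  }
  sb <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  sb[!valid] <- -Inf
  t <- as.integer(which.max(sb) - 1L) # smallest maximizer, threshold value t
  attr(t, "degenerate") <- FALSE
  t
}

## the threshold is an integer histogram bin, so binarization compares the
## binned intensity: fractional values within one bin never straddle it
.binarize <- function(gray, threshold) floor(gray) > threshold

## neighbor offsets (drow, dcol) for one sweep direction; the reverse pairs
## are implied by edge symmetry
.connOffsets <- function(connectivity) {
  if (connectivity == 4L) list(c(0L, 1L), c(1L, 0L))
  else if (connectivity == 8L)
    list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  else stop("connectivity must be 4 or 8")
}

#' Largest connected foreground component
#'
#' Keeps exactly the connected component of \code{TRUE} pixels with the most
#' pixels and clears everything else. Components are defined under 4- or
#' 8-connectivity (default 8). A size tie is broken in favor of the
#' component whose first pixel in row-major order comes first.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return logical matrix of the same shape with a single component.
#' @export
largestComponent <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  fg <- which(mask)
  if (length(fg) == 0) stop("no foreground object")
  H <- nrow(mask); W <- ncol(mask)
  id <- integer(H * W); id[fg] <- seq_along(fg)   # compact vertex ids
  edges <- integer(0)
  for (off in .connOffsets(as.integer(connectivity))) {
    dr <- off[1]; dc <- off[2]
    r <- ((fg - 1L) %% H) + 1L
    c <- ((fg - 1L) %/% H) + 1L
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- (c2[ok] - 1L) * H + r2[ok]
    ok2 <- mask[nb]
    if (any(ok2))
      edges <- c(edges, rbind(id[fg[ok]][ok2], id[nb][ok2]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    ## row-major linear index of each pixel; first pixel per candidate comp
    rm <- (((fg - 1L) %% H)) * W + ((fg - 1L) %/% H)   # 0-based row-major
    firsts <- vapply(best, function(k) min(rm[comp$membership == k]), 0)
    best <- best[which.min(firsts)]
  }
  out <- matrix(FALSE, H, W)
  out[fg[comp$membership == best]] <- TRUE
  out
}

#' Tight bounding box of a mask
#'
#' @param mask logical matrix with at least one \code{TRUE} pixel.
#' @return a \code{\linkS4class{BoundingBox}} (0-based, half-open).
#' @examples
#' m <- matrix(FALSE, 6, 8); m[3:5, 4:7] <- TRUE
#' boundingBox(m)   # (2, 3, 5, 7)
#' @export
boundingBox <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no bounding box")
  BoundingBox(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L,
              max(idx[, 1]), max(idx[, 2]))
}

.cropBox <- function(image, box) {
  image[(box@rowStart + 1L):box@rowEnd, (box@colStart + 1L):box@colEnd,
        drop = FALSE]
}

#' Localize and crop the thyroid region
#'
#' Runs the preprocessing chain: Otsu binarization, selection of the largest
#' bright connected component (the thyroid band; small bright artifact blobs
#' in the dark border are discarded), tight bounding box, and crop. The
#' detected box must cover at least \code{minAreaFraction} of the frame,
#' otherwise an artifact-only detection is assumed and an error is raised
#' naming the failing stage.
#'
#' @param image numeric matrix in [0, 255] (see \code{\link{loadImage}}).
#' @param minAreaFraction minimum box area as a fraction of the frame area.
#' @param connectivity component connectivity, 4 or 8 (default 8).
#' @return a \code{\linkS4class{ThyroidROI}}.
#' @export
extractThyroidROI <- function(image, minAreaFraction = 0.05,
                              connectivity = 8L) {
  stopifnot(is.matrix(image))
  t <- otsuThreshold(image)
  if (isTRUE(attr(t, "degenerate")))
    stop("binarization stage: image is constant, no threshold separates ",
         "foreground from background")
  mask <- .binarize(image, t)
  if (!any(mask))
    stop("binarization stage: no foreground object")
  comp <- largestComponent(mask, connectivity = connectivity)
  box <- boundingBox(comp)
  area <- (box@rowEnd - box@rowStart) * (box@colEnd - box@colStart)
  if (area < minAreaFraction * length(image))
    stop("roi stage: detected region covers ",
         sprintf("%.3f", area / length(image)),
         " of the frame, below minAreaFraction = ", minAreaFraction)
  ThyroidROI(.cropBox(image, box), box, dim(image))
}

## bilinear resize with half-pixel-center convention (EBImage's filter)
.resizeBilinear <- function(x, outRows, outCols) {
  if (nrow(x) == outRows && ncol(x) == outCols) return(x)
  out <- EBImage::resize(x, w = outRows, h = outCols, filter = "bilinear")
  matrix(as.numeric(EBImage::imageData(out)), outRows, outCols)
}

#' Normalize an ROI for the network input
#'
#' Bilinearly resizes the crop to \code{side x side}, rescales intensities
#' to [0, 1], and replicates the single channel three times, matching the
#' three-channel input contract of the network heads.
#'
#' @param roi a \code{\linkS4class{ThyroidROI}} or a plain numeric matrix
#'   in [0, 255].
#' @param side output side in pixels, >= 32 (default 224).
#' @return numeric array \code{side x side x 3} with values in [0, 1].
#' @export
normalizeForCNN <- function(roi, side = 224L) {
  side <- as.integer(side)
  if (side < 32L) stop("side must be >= 32")
  px <- if (is(roi, "ThyroidROI")) roi@pixels else roi
  stopifnot(is.matrix(px))
  r <- .resizeBilinear(px, side, side) / 255
  r[r < 0] <- 0; r[r > 1] <- 1
  array(r, dim = c(side, side, 3L))
}
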