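## Independent brute-force oracles. These deliberately share no code with
## the implementation: exhaustive sweeps, BFS flood fill, and literal DFT
## summation.

## exhaustive Otsu search: every threshold t in 0:255, between-class
## variance computed from raw class members
otsuOracle <- function(gray) {
  bins <- pmin(pmax(floor(as.numeric(gray)), 0), 255)
  n <- length(bins)
  best <- -Inf
  bestT <- NA_integer_
  for (t in 0:255) {
    g0 <- bins[bins <= t]
    g1 <- bins[bins > t]
    if (length(g0) == 0 || length(g1) == 0) next
    sb <- (length(g0) / n) * (length(g1) / n) * (mean(g0) - mean(g1))^2
    if (sb > best + 1e-12) {
      best <- sb
      bestT <- t
    }
  }
  bestT
}

## BFS flood fill; returns list of components as sorted linear indices
floodFillComponents <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  offs <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  seen <- matrix(FALSE, H, W)
  comps <- list()
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    cells <- integer(0)
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      cells <- c(cells, (cur[2] - 1L) * H + cur[1])
      for (o in offs) {
        r <- cur[1] + o[1]; cc <- cur[2] + o[2]
        if (r >= 1 && r <= H && cc >= 1 && cc <= W &&
            mask[r, cc] && !seen[r, cc]) {
          seen[r, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(cells)
  }
  comps
}

largestComponentOracle <- function(mask, connectivity = 8) {
  comps <- floodFillComponents(mask, connectivity)
  sizes <- lengths(comps)
  cand <- comps[sizes == max(sizes)]
  if (length(cand) > 1) {
    H <- nrow(mask); W <- ncol(mask)
    firstRowMajor <- function(cells)
      min(((cells - 1) %% H) * W + (cells - 1) %/% H)
    cand <- cand[order(vapply(cand, firstRowMajor, 0))]
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[cand[[1]]] <- TRUE
  out
}

## literal O(N^2) 2-D DFT power spectrum with an independent center shift
dftPowerOracle <- function(x) {
  H <- nrow(x); W <- ncol(x)
  P <- matrix(0, H, W)
  for (u in 0:(H - 1)) for (v in 0:(W - 1)) {
    s <- 0 + 0i
    for (m in 0:(H - 1)) for (n in 0:(W - 1))
      s <- s + x[m + 1, n + 1] * exp(-2i * pi * (u * m / H + v * n / W))
    P[u + 1, v + 1] <- Mod(s)^2
  }
  ui <- ((seq_len(H) - 1) - floor(H / 2)) %% H + 1
  vi <- ((seq_len(W) - 1) - floor(W / 2)) %% W + 1
  P[ui, vi]
}

## independent count of spectrum bins inside the circular region
circleBinCountOracle <- function(H, W, radiusFraction) {
  dcR <- floor(H / 2) + 1
  dcC <- floor(W / 2) + 1
  r <- radiusFraction * min(H, W) / 2
  n <- 0L
  for (i in seq_len(H)) for (j in seq_len(W))
    if ((i - dcR)^2 + (j - dcC)^2 <= r^2) n <- n + 1L
  n
}

## sweep oracle for the coarse-threshold purity contract: with thresholds
## (lo, hi), every decided training sample group must meet its purity
thresholdsRespectPurity <- function(values, labels, th, purity) {
  lo <- thresholdBounds(th)["low"]; hi <- thresholdBounds(th)["high"]
  below <- values < lo
  above <- values > hi
  okB <- sum(below) == 0 || mean(labels[below] == "benign") >= purity
  okA <- sum(above) == 0 || mean(labels[above] == "malign") >= purity
  okB && okA
}
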