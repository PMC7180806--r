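## Minimal CNN engine in base R matrix operations.
##
## Activations are stored as arrays with dimensions (H, W, C, B): spatial
## first so that im2col gathers are contiguous, batch last. Convolutions are
## 3x3, stride 1, zero-padded ("same"); pooling is 2x2/2 max. The engine
## exists to make the `tiny` backbone fully trainable without any external
## deep-learning framework; it is deliberately small, not general.

.EPS_BN <- 1e-5
.EPS_P <- 1e-7     # probability clipping inside the losses

.convForward <- function(a, Wm, b) {
  d <- dim(a); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  Fh <- ncol(Wm)
  pad <- array(0, c(H + 2L, W + 2L, C, B))
  pad[2:(H + 1L), 2:(W + 1L), , ] <- a
  cols <- matrix(0, H * W * B, 9L * C)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    block <- pad[(1L + di):(H + di), (1L + dj):(W + dj), , , drop = FALSE]
    cols[, k * C + seq_len(C)] <- matrix(aperm(block, c(1, 2, 4, 3)),
                                         H * W * B, C)
    k <- k + 1L
  }
  out <- cols %*% Wm
  out <- out + matrix(b, nrow(out), Fh, byrow = TRUE)
  list(out = aperm(array(out, c(H, W, B, Fh)), c(1, 2, 4, 3)), cols = cols,
       inDim = d)
}

.convBackward <- function(dOut, cache, Wm) {
  d <- cache$inDim; H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  Fh <- ncol(Wm)
  dOutMat <- matrix(aperm(dOut, c(1, 2, 4, 3)), H * W * B, Fh)
  dW <- crossprod(cache$cols, dOutMat)
  db <- colSums(dOutMat)
  dCols <- dOutMat %*% t(Wm)
  dpad <- array(0, c(H + 2L, W + 2L, C, B))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    dblock <- aperm(array(dCols[, k * C + seq_len(C)], c(H, W, B, C)),
                    c(1, 2, 4, 3))
    dpad[(1L + di):(H + di), (1L + dj):(W + dj), , ] <-
      dpad[(1L + di):(H + di), (1L + dj):(W + dj), , , drop = FALSE] + dblock
    k <- k + 1L
  }
  list(dA = dpad[2:(H + 1L), 2:(W + 1L), , , drop = FALSE], dW = dW, db = db)
}

.poolForward <- function(a) {
  d <- dim(a); H <- d[1]; W <- d[2]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  s <- list(a[ro, co, , , drop = FALSE], a[re, co, , , drop = FALSE],
            a[ro, ce, , , drop = FALSE], a[re, ce, , , drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- array(FALSE, dim(m))
  masks <- vector("list", 4L)
  for (i in 1:4) {
    masks[[i]] <- (s[[i]] == m) & !taken
    taken <- taken | masks[[i]]
  }
  list(out = m, masks = masks, inDim = d)
}

.poolBackward <- function(dOut, cache) {
  d <- cache$inDim; H <- d[1]; W <- d[2]
  ro <- seq(1L, H, 2L); re <- seq(2L, H, 2L)
  co <- seq(1L, W, 2L); ce <- seq(2L, W, 2L)
  dA <- array(0, d)
  dA[ro, co, , ] <- dOut * cache$masks[[1]]
  dA[re, co, , ] <- dOut * cache$masks[[2]]
  dA[ro, ce, , ] <- dOut * cache$masks[[3]]
  dA[re, ce, , ] <- dOut * cache$masks[[4]]
  dA
}

.gapForward <- function(a) {
  d <- dim(a)
  m <- matrix(a, d[1] * d[2], d[3] * d[4])
  feat <- matrix(colMeans(m), d[3], d[4])   # C x B
  list(out = t(feat), inDim = d)            # B x C
}

.gapBackward <- function(dFeat, cache) {
  d <- cache$inDim
  v <- as.vector(t(dFeat)) / (d[1] * d[2])  # C-fastest order
  array(rep(v, each = d[1] * d[2]), d)
}

.bnForward <- function(feat, w, train) {
  if (train) {
    mu <- colMeans(feat)
    va <- colMeans(feat^2) - mu^2
  } else {
    mu <- w$rmean; va <- w$rvar
  }
  xhat <- sweep(sweep(feat, 2L, mu), 2L, sqrt(va + .EPS_BN), "/")
  out <- sweep(sweep(xhat, 2L, w$gamma, "*"), 2L, w$beta, "+")
  list(out = out, xhat = xhat, mu = mu, va = va)
}

.bnBackward <- function(dOut, cache, w, feat) {
  B <- nrow(feat)
  istd <- 1 / sqrt(cache$va + .EPS_BN)
  dxhat <- sweep(dOut, 2L, w$gamma, "*")
  xc <- sweep(feat, 2L, cache$mu)
  dva <- colSums(dxhat * xc) * (-0.5) * istd^3
  dmu <- colSums(dxhat) * (-istd)
  dX <- sweep(dxhat, 2L, istd, "*") +
    sweep(xc, 2L, 2 * dva / B, "*") +
    matrix(dmu / B, B, length(dmu), byrow = TRUE)
  list(dX = dX, dGamma = colSums(dOut * cache$xhat), dBeta = colSums(dOut))
}

.softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## Full forward pass. train=TRUE uses batch statistics and dropout and
## returns caches for the backward pass.
.tinyForward <- function(w, a, train, dropout) {
  c1 <- .convForward(a, w$conv1$W, w$conv1$b)
  r1 <- pmax(c1$out, 0)
  p1 <- .poolForward(r1)
  c2 <- .convForward(p1$out, w$conv2$W, w$conv2$b)
  r2 <- pmax(c2$out, 0)
  p2 <- .poolForward(r2)
  c3 <- .convForward(p2$out, w$conv3$W, w$conv3$b)
  r3 <- pmax(c3$out, 0)
  p3 <- .poolForward(r3)
  g <- .gapForward(p3$out)
  bn <- .bnForward(g$out, w$bn, train)
  if (train && dropout > 0) {
    dmask <- matrix(stats::runif(length(bn$out)) >= dropout,
                    nrow(bn$out), ncol(bn$out)) / (1 - dropout)
    dz <- bn$out * dmask
  } else {
    dmask <- NULL
    dz <- bn$out
  }
  logits <- dz %*% w$dense$W +
    matrix(w$dense$b, nrow(dz), 2L, byrow = TRUE)
  probs <- .softmaxRows(logits)
  list(probs = probs,
       cache = if (train) list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2,
                               p2 = p2, c3 = c3, r3 = r3, p3 = p3, g = g,
                               bn = bn, dmask = dmask, dz = dz,
                               feat = g$out))
}

## dLogits -> gradients for all weights
.tinyBackward <- function(w, cache, dLogits) {
  gr <- list()
  gr$dense <- list(W = crossprod(cache$dz, dLogits), b = colSums(dLogits))
  dDz <- dLogits %*% t(w$dense$W)
  if (!is.null(cache$dmask)) dDz <- dDz * cache$dmask
  bnb <- .bnBackward(dDz, cache$bn, w$bn, cache$feat)
  gr$bn <- list(gamma = bnb$dGamma, beta = bnb$dBeta)
  dA <- .gapBackward(bnb$dX, cache$g)
  dA <- .poolBackward(dA, cache$p3)
  dA <- dA * (cache$r3 > 0)
  cb3 <- .convBackward(dA, cache$c3, w$conv3$W)
  gr$conv3 <- list(W = cb3$dW, b = cb3$db)
  dA <- .poolBackward(cb3$dA, cache$p2)
  dA <- dA * (cache$r2 > 0)
  cb2 <- .convBackward(dA, cache$c2, w$conv2$W)
  gr$conv2 <- list(W = cb2$dW, b = cb2$db)
  dA <- .poolBackward(cb2$dA, cache$p1)
  dA <- dA * (cache$r1 > 0)
  cb1 <- .convBackward(dA, cache$c1, w$conv1$W)
  gr$conv1 <- list(W = cb1$dW, b = cb1$db)
  gr
}

## backbone features (post-GAP, pre-BN) for a batch; used for inference-time
## batch-norm statistics re-estimation after training
.tinyFeatures <- function(w, a) {
  x <- .poolForward(pmax(.convForward(a, w$conv1$W, w$conv1$b)$out, 0))$out
  x <- .poolForward(pmax(.convForward(x, w$conv2$W, w$conv2$b)$out, 0))$out
  x <- .poolForward(pmax(.convForward(x, w$conv3$W, w$conv3$b)$out, 0))$out
  .gapForward(x)$out
}

.tinyInitWeights <- function() {
  he <- function(k, cin, cout)
    matrix(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
           9L * cin, cout)
  ch <- .TINY_CHANNELS
  list(conv1 = list(W = he(3L, 3L, ch[1]), b = numeric(ch[1])),
       conv2 = list(W = he(3L, ch[1], ch[2]), b = numeric(ch[2])),
       conv3 = list(W = he(3L, ch[2], ch[3]), b = numeric(ch[3])),
       bn = list(gamma = rep(1, ch[3]), beta = numeric(ch[3]),
                 rmean = numeric(ch[3]), rvar = rep(1, ch[3])),
       dense = list(W = matrix(0, ch[3], 2L), b = numeric(2L)))
}

## flatten trainable weights for the optimizer (running BN stats excluded)
.trainableNames <- list(c("conv1", "W"), c("conv1", "b"),
                        c("conv2", "W"), c("conv2", "b"),
                        c("conv3", "W"), c("conv3", "b"),
                        c("bn", "gamma"), c("bn", "beta"),
                        c("dense", "W"), c("dense", "b"))

.adamInit <- function(w) {
  lapply(.trainableNames, function(nm) {
    x <- w[[nm[1]]][[nm[2]]]
    list(m = x * 0, v = x * 0)
  })
}

.adamStep <- function(w, gr, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(.trainableNames)) {
    nm <- .trainableNames[[i]]
    g <- gr[[nm[1]]][[nm[2]]]
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    w[[nm[1]]][[nm[2]]] <- w[[nm[1]]][[nm[2]]] - lr * mhat / (sqrt(vhat) + eps)
    state[[i]] <- st
  }
  list(w = w, state = state)
}
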