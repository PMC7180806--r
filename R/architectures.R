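#' @include AllClasses.R
NULL

## Layer-table builders -------------------------------------------------
##
## Each backbone is enumerated layer by layer into a data.frame with the
## output shape and the exact parameter count of every weighted layer.
## Counting convention: convolution biases are counted where the canonical
## architecture defines them (ResNet50 convolutions carry biases,
## Inception-v3 convolutions do not), and batch normalization contributes
## all of its per-feature vectors (scale, offset, moving mean, moving
## variance; Inception-v3's batch norms omit the scale vector). Under this
## convention the backbone totals reproduce the published tables exactly:
## 23,587,712 for ResNet50 and 21,802,784 for Inception-v3 at 224x224x3.

.layerRow <- function(name, h, w, c, params, part) {
  data.frame(layer = name, out_h = h, out_w = w, out_c = c,
             params = params, part = part, stringsAsFactors = FALSE)
}

.convOut <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

.resnet50Layers <- function(side = 224L) {
  rows <- list()
  add <- function(name, h, w, c, params)
    rows[[length(rows) + 1L]] <<- .layerRow(name, h, w, c, params, "backbone")
  conv <- function(k, cin, cout) k * k * cin * cout + cout  # with bias
  bn <- function(c) 4L * c
  s <- .convOut(side, 7L, 2L, 3L)
  add("conv1 7x7/2", s, s, 64L, conv(7L, 3L, 64L))
  add("conv1 bn", s, s, 64L, bn(64L))
  s <- .convOut(s, 3L, 2L, 1L)
  add("maxpool 3x3/2", s, s, 64L, 0L)
  stages <- list(list(n = 3L, f = c(64L, 64L, 256L), cin = 64L, stride = 1L),
                 list(n = 4L, f = c(128L, 128L, 512L), cin = 256L, stride = 2L),
                 list(n = 6L, f = c(256L, 256L, 1024L), cin = 512L, stride = 2L),
                 list(n = 3L, f = c(512L, 512L, 2048L), cin = 1024L,
                      stride = 2L))
  for (si in seq_along(stages)) {
    st <- stages[[si]]
    cin <- st$cin
    for (b in seq_len(st$n)) {
      if (b == 1L && st$stride == 2L) s <- .convOut(s, 1L, 2L, 0L)
      f <- st$f
      tag <- sprintf("conv%d_block%d", si + 1L, b)
      add(paste(tag, "1x1 reduce"), s, s, f[1],
          conv(1L, cin, f[1]) + bn(f[1]))
      add(paste(tag, "3x3"), s, s, f[2], conv(3L, f[1], f[2]) + bn(f[2]))
      add(paste(tag, "1x1 expand"), s, s, f[3],
          conv(1L, f[2], f[3]) + bn(f[3]))
      if (b == 1L)
        add(paste(tag, "shortcut"), s, s, f[3],
            conv(1L, cin, f[3]) + bn(f[3]))
      cin <- f[3]
    }
  }
  do.call(rbind, rows)
}

.inceptionLayers <- function(side = 224L) {
  rows <- list()
  add <- function(name, s, c, params)
    rows[[length(rows) + 1L]] <<- .layerRow(name, s, s, c, params, "backbone")
  ## conv + batch norm without scale: weights + 3 vectors per feature
  cb <- function(k1, k2, cin, cout) k1 * k2 * cin * cout + 3L * cout
  s <- .convOut(side, 3L, 2L, 0L)
  add("stem conv 3x3/2 valid", s, 32L, cb(3L, 3L, 3L, 32L))
  s <- .convOut(s, 3L, 1L, 0L)
  add("stem conv 3x3 valid", s, 32L, cb(3L, 3L, 32L, 32L))
  add("stem conv 3x3 same", s, 64L, cb(3L, 3L, 32L, 64L))
  s <- .convOut(s, 3L, 2L, 0L)
  add("stem maxpool 3x3/2", s, 64L, 0L)
  add("stem conv 1x1 valid", s, 80L, cb(1L, 1L, 64L, 80L))
  s <- .convOut(s, 3L, 1L, 0L)
  add("stem conv 3x3 valid", s, 192L, cb(3L, 3L, 80L, 192L))
  s <- .convOut(s, 3L, 2L, 0L)
  add("stem maxpool 3x3/2", s, 192L, 0L)
  cin <- 192L
  for (i in 0:2) {                      # 35x35-type blocks
    pool <- if (i == 0L) 32L else 64L
    p <- cb(1L, 1L, cin, 64L) + cb(1L, 1L, cin, 48L) + cb(5L, 5L, 48L, 64L) +
      cb(1L, 1L, cin, 64L) + cb(3L, 3L, 64L, 96L) + cb(3L, 3L, 96L, 96L) +
      cb(1L, 1L, cin, pool)
    cin <- 64L + 64L + 96L + pool
    add(sprintf("mixed%d", i), s, cin, p)
  }
  p <- cb(3L, 3L, cin, 384L) + cb(1L, 1L, cin, 64L) + cb(3L, 3L, 64L, 96L) +
    cb(3L, 3L, 96L, 96L)
  cin <- 384L + 96L + cin
  s <- .convOut(s, 3L, 2L, 0L)
  add("mixed3 (reduction)", s, cin, p)
  for (i in 4:7) {                      # 17x17-type blocks, factorized 7x7
    c7 <- c(128L, 160L, 160L, 192L)[i - 3L]
    p <- cb(1L, 1L, cin, 192L) +
      cb(1L, 1L, cin, c7) + cb(1L, 7L, c7, c7) + cb(7L, 1L, c7, 192L) +
      cb(1L, 1L, cin, c7) + cb(7L, 1L, c7, c7) + cb(1L, 7L, c7, c7) +
      cb(7L, 1L, c7, c7) + cb(1L, 7L, c7, 192L) +
      cb(1L, 1L, cin, 192L)
    cin <- 768L
    add(sprintf("mixed%d", i), s, cin, p)
  }
  p <- cb(1L, 1L, cin, 192L) + cb(3L, 3L, 192L, 320L) +
    cb(1L, 1L, cin, 192L) + cb(1L, 7L, 192L, 192L) + cb(7L, 1L, 192L, 192L) +
    cb(3L, 3L, 192L, 192L)
  cin <- 320L + 192L + cin
  s <- .convOut(s, 3L, 2L, 0L)
  add("mixed8 (reduction)", s, cin, p)
  for (i in 9:10) {                     # expanded-filter-bank blocks
    p <- cb(1L, 1L, cin, 320L) +
      cb(1L, 1L, cin, 384L) + cb(1L, 3L, 384L, 384L) + cb(3L, 1L, 384L, 384L) +
      cb(1L, 1L, cin, 448L) + cb(3L, 3L, 448L, 384L) +
      cb(1L, 3L, 384L, 384L) + cb(3L, 1L, 384L, 384L) +
      cb(1L, 1L, cin, 192L)
    cin <- 320L + 768L + 768L + 192L
    add(sprintf("mixed%d", i), s, cin, p)
  }
  do.call(rbind, rows)
}

## tiny backbone: three conv(3x3, same) + relu + maxpool(2) blocks
.TINY_CHANNELS <- c(8L, 16L, 32L)

.tinyLayers <- function(side = 32L) {
  rows <- list()
  cin <- 3L
  s <- side
  for (i in seq_along(.TINY_CHANNELS)) {
    cout <- .TINY_CHANNELS[i]
    rows[[length(rows) + 1L]] <- .layerRow(
      sprintf("conv%d 3x3 + relu", i), s, s, cout,
      3L * 3L * cin * cout + cout, "backbone")
    s <- s %/% 2L
    rows[[length(rows) + 1L]] <- .layerRow(
      sprintf("maxpool%d 2x2/2", i), s, s, cout, 0L, "backbone")
    cin <- cout
  }
  do.call(rbind, rows)
}

## head rows shared by every backbone: GAP -> BN -> dropout -> dense(2)
.headLayers <- function(nfeat) {
  rbind(.layerRow("global average pooling", 1L, 1L, nfeat, 0L, "pool"),
        .layerRow("batch normalization", 1L, 1L, nfeat, 4L * nfeat,
                  "batch_norm"),
        .layerRow("dropout", 1L, 1L, nfeat, 0L, "dropout"),
        .layerRow("dense 2 + softmax", 1L, 1L, 2L, nfeat * 2L + 2L, "dense"))
}

.architectureTable <- function(spec) {
  bb <- switch(spec@backbone,
               resnet50 = .resnet50Layers(spec@inputSide),
               inception_v3 = .inceptionLayers(spec@inputSide),
               tiny = .tinyLayers(spec@inputSide))
  nfeat <- bb$out_c[nrow(bb)]
  rbind(bb, .headLayers(nfeat))
}
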