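## Shared test fixtures, all generated in code.

## reduced-frame phantom conditions used by most tests (full pipeline
## behaviour, fraction of the default frame area for speed)
smallPhantomParams <- function(seed = 1, classSeparation = 1) {
  PhantomParams(frameSize = c(120, 180), borderFraction = 0.15,
                noduleRadiusRange = c(10, 16), seed = seed,
                classSeparation = classSeparation)
}

smallPhantomInput <- function(label, seed, side = 32, classSeparation = 1) {
  ph <- generatePhantom(label, smallPhantomParams(seed, classSeparation))
  normalizeForCNN(extractThyroidROI(phantomImage(ph)), side)
}

## hand-crafted 16-bit grayscale PNG written chunk by chunk (no installed
## writer emits 16-bit); values are 0-based 16-bit sample integers by row
writePNG16 <- function(values16, width, height, path) {
  crcTable <- local({
    tab <- integer(256)
    for (i in 0:255) {
      c <- i
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L) == 1L)
          bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1))  # 0xEDB88320
        else bitwShiftR(bitwAnd(c, -2L), 1)
      tab[i + 1] <- c
    }
    tab
  })
  crc32 <- function(bytes) {
    c <- -1L
    for (b in as.integer(bytes))
      c <- bitwXor(bitwShiftR(bitwAnd(c, -256L), 8),
                   crcTable[bitwAnd(bitwXor(c, b), 255L) + 1])
    bitwXor(c, -1L)
  }
  be32 <- function(x) {
    x <- as.numeric(x) %% 2^32
    as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 2^8) %% 256, x %% 256))
  }
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(be32(length(data)), body, be32(crc32(body)))
  }
  ihdr <- c(be32(width), be32(height),
            as.raw(c(16, 0, 0, 0, 0)))  # 16-bit, grayscale
  rowsRaw <- unlist(lapply(seq_len(height), function(r) {
    v <- values16[((r - 1) * width + 1):(r * width)]
    c(as.raw(0), as.raw(rbind(v %/% 256, v %% 256)))  # filter 0, big-endian
  }))
  idat <- memCompress(rowsRaw, type = "gzip")  # zlib-wrapped deflate
  writeBin(c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
             chunk("IHDR", ihdr), chunk("IDAT", idat),
             chunk("IEND", raw(0))), path)
  invisible(path)
}
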