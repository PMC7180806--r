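#' @include AllClasses.R io_datasets.R preprocessing.R
NULL

## disk stamp helper: TRUE inside a circle of radius r around (cy, cx)
.diskDist <- function(H, W, cy, cx) {
  dr <- seq_len(H) - cy
  dc <- seq_len(W) - cx
  sqrt(outer(dr^2, dc^2, `+`))
}

#' Generate one synthetic ultrasound phantom
#'
#' Emulates the structure the cascade assumes in clinical frames: a dark
#' border carrying a few small bright artifact blobs (annotation marks), a
#' large bright central thyroid band under multiplicative log-normal
#' speckle, and a smooth low-amplitude illumination gradient. A malign
#' phantom additionally receives one round nodule — a bright, homogeneous
#' blob with damped internal speckle — carrying bright calcification
#' specks; nodule contrast and speck brightness scale with
#' \code{classSeparation}, so at separation 0 the two classes are
#' statistically indistinguishable. The nodule is a large low-frequency
#' structure, so malign phantoms concentrate more spectral power near DC
#' and score higher on the frequency ratio, matching the coarse rule's
#' orientation.
#'
#' All randomness derives from \code{params@@seed}: the same label and
#' parameters give a bitwise-identical image.
#'
#' @param label \code{"benign"} or \code{"malign"}.
#' @param params a \code{\linkS4class{PhantomParams}}.
#' @param patientId patient id recorded in the sample.
#' @return a \code{\linkS4class{PhantomSample}}.
#' @export
generatePhantom <- function(label = c("benign", "malign"),
                            params = PhantomParams(), patientId = "P1") {
  label <- match.arg(label)
  stopifnot(is(params, "PhantomParams"))
  H <- params@frameSize[1L]; W <- params@frameSize[2L]
  mr <- round(params@borderFraction * H)
  mc <- round(params@borderFraction * W)
  bh <- H - 2L * mr; bw <- W - 2L * mc
  if (bh < 16L || bw < 16L)
    stop("thyroid band does not fit the frame at this borderFraction")
  .withSeed(params@seed, {
    img <- matrix(pmax(params@backgroundMean +
                         stats::rnorm(H * W, sd = 2), 0), H, W)
    ## thyroid band: multiplicative log-normal speckle, unit mean
    sg <- params@speckleSigma
    z <- matrix(stats::rnorm(bh * bw), bh, bw)
    band <- params@thyroidMean * exp(sg * z - sg^2 / 2)
    if (label == "malign" && params@classSeparation > 0) {
      sep <- min(params@classSeparation, 2)
      rr <- params@noduleRadiusRange
      rmax <- min(bh, bw) / 2 - 8
      if (rmax < 4) stop("nodule does not fit the thyroid band")
      r <- min(stats::runif(1, rr[1], rr[2]), rmax)
      cy <- stats::runif(1, r + 4, bh - r - 4)
      cx <- stats::runif(1, r + 4, bw - r - 4)
      d <- .diskDist(bh, bw, cy, cx)
      rim <- pmin(pmax((r - d) / 4, 0), 1)   # soft 4-px rim
      ## bright, homogeneous nodule blob: raised echogenicity and damped
      ## speckle concentrate its power near DC, so malign phantoms score
      ## higher on the frequency ratio
      sgLoc <- sg * (1 - 0.5 * min(sep, 1) * rim)
      band <- params@thyroidMean * (1 + 0.35 * sep * rim) *
        exp(sgLoc * z - sgLoc^2 / 2)
      ## bright calcification specks inside the nodule
      bright <- params@thyroidMean +
        (255 - params@thyroidMean) * min(1, 0.9 * sep)
      for (i in seq_len(params@calcificationCount)) {
        a <- stats::runif(1, 0, 2 * pi)
        rho <- stats::runif(1, 0, 0.55 * r)
        sy <- cy + rho * cos(a); sx <- cx + rho * sin(a)
        sr <- stats::runif(1, 1, 2)
        sd2 <- .diskDist(bh, bw, sy, sx)
        band[sd2 <= sr] <- bright
      }
    }
    ## smooth illumination gradient (both classes)
    theta <- stats::runif(1, 0, 2 * pi)
    u <- matrix(rep(seq_len(bh) / bh - 0.5, bw), bh, bw)
    v <- matrix(rep(seq_len(bw) / bw - 0.5, each = bh), bh, bw)
    band <- band + 0.08 * params@thyroidMean *
      (cos(theta) * u + sin(theta) * v)
    img[(mr + 1L):(H - mr), (mc + 1L):(W - mc)] <- band
    ## small bright artifact blobs in the border strips
    radMax <- min(4L, (min(mr, mc) - 5L) %/% 2L)
    for (i in seq_len(if (radMax >= 2L) params@nArtifacts else 0L)) {
      rad <- if (radMax == 2L) 2L else sample(2:radMax, 1L)
      strip <- sample(1:4, 1L)
      pos <- switch(strip,
        c(stats::runif(1, rad + 2, mr - rad - 2),        # top
          stats::runif(1, rad + 2, W - rad - 2)),
        c(stats::runif(1, H - mr + rad + 2, H - rad - 2), # bottom
          stats::runif(1, rad + 2, W - rad - 2)),
        c(stats::runif(1, rad + 2, H - rad - 2),          # left
          stats::runif(1, rad + 2, mc - rad - 2)),
        c(stats::runif(1, rad + 2, H - rad - 2),          # right
          stats::runif(1, W - mc + rad + 2, W - rad - 2)))
      d <- .diskDist(H, W, pos[1], pos[2])
      img[d <= rad] <- stats::runif(1, 180, 235)
    }
    img[img < 0] <- 0; img[img > 255] <- 255
    new("PhantomSample", image = img, label = label,
        truthROI = BoundingBox(mr, mc, H - mr, W - mc),
        patientId = patientId)
  })
}

#' Generate a labeled phantom dataset on disk
#'
#' Writes PNG phantom images and a manifest CSV in the package's dataset
#' layout. Each patient contributes \code{imagesPerPatient} images (all
#' sharing the patient id and class); TI-RADS codes are sampled from the
#' class-consistent subset (\{1,2,3\} for benign patients, \{4a,4b,4c,5\}
#' for malign). Per-image seeds are derived deterministically from
#' \code{params@@seed}. The generation parameters are recorded alongside in
#' \code{params.json}.
#'
#' @param nBenign,nMalign number of patients per class.
#' @param imagesPerPatient images per patient (default 1).
#' @param params a \code{\linkS4class{PhantomParams}}.
#' @param dir output directory (created if needed).
#' @return a \code{\linkS4class{Manifest}} (origin \code{"synthetic"}).
#' @export
generateDataset <- function(nBenign, nMalign, imagesPerPatient = 1L,
                            params = PhantomParams(), dir = tempfile()) {
  stopifnot(nBenign >= 1L, nMalign >= 1L, imagesPerPatient >= 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  rows <- list()
  counter <- 0L
  pid <- 0L
  for (cl in c("benign", "malign")) {
    codes <- if (cl == "benign") .TIRADS_BENIGN else .TIRADS_MALIGN
    for (p in seq_len(if (cl == "benign") nBenign else nMalign)) {
      pid <- pid + 1L
      patient <- sprintf("%s%03d", toupper(substr(cl, 1, 1)), pid)
      for (j in seq_len(imagesPerPatient)) {
        counter <- counter + 1L
        pp <- params
        pp@seed <- params@seed + 7919L * counter
        ph <- generatePhantom(cl, pp, patientId = patient)
        fn <- file.path(dir, sprintf("%s_%02d.png", patient, j))
        png::writePNG(ph@image / 255, fn)
        tirads <- .withSeed(pp@seed + 1L, sample(codes, 1L))
        rows[[counter]] <- data.frame(
          image_path = normalizePath(fn), patient_id = patient,
          tirads = tirads, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  df$label <- tiradsToLabel(df$tirads)
  manifest <- new("Manifest", samples = df, origin = "synthetic")
  writeManifest(manifest, file.path(dir, "manifest.csv"))
  jsonlite::write_json(
    list(frame_size = params@frameSize,
         border_fraction = params@borderFraction,
         thyroid_mean = params@thyroidMean,
         background_mean = params@backgroundMean,
         speckle_sigma = params@speckleSigma,
         n_artifacts = params@nArtifacts,
         nodule_radius_range = params@noduleRadiusRange,
         calcification_count = params@calcificationCount,
         class_separation = params@classSeparation,
         seed = params@seed,
         n_benign = nBenign, n_malign = nMalign,
         images_per_patient = imagesPerPatient),
    file.path(dir, "params.json"), auto_unbox = TRUE)
  manifest
}
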