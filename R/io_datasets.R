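#' @include AllClasses.R
NULL

.TIRADS_CODES <- c("1", "2", "3", "4a", "4b", "4c", "5")
.TIRADS_BENIGN <- c("1", "2", "3")
.TIRADS_MALIGN <- c("4a", "4b", "4c", "5")

#' Map TI-RADS categories to binary labels
#'
#' TI-RADS categories 1 (normal), 2 (benign) and 3 (no suspicious features)
#' map to \code{"benign"}; 4a, 4b, 4c and 5 (one to five suspicious
#' features) map to \code{"malign"}. Vectorized.
#'
#' @param code character vector of TI-RADS codes drawn from
#'   \{"1","2","3","4a","4b","4c","5"\}.
#' @return character vector of \code{"benign"} / \code{"malign"}.
#' @examples
#' tiradsToLabel(c("2", "4a", "3"))
#' @export
tiradsToLabel <- function(code) {
  code <- as.character(code)
  bad <- !(code %in% .TIRADS_CODES)
  if (any(bad))
    stop("invalid TI-RADS code(s): ",
         paste(sQuote(unique(code[bad])), collapse = ", "),
         "; valid codes are ", paste(.TIRADS_CODES, collapse = ", "))
  ifelse(code %in% .TIRADS_BENIGN, "benign", "malign")
}

## benign = 1, malign = 0: every score in the package is probability-of-benign
.labelY <- function(label) as.numeric(label == "benign")

#' Read a dataset manifest
#'
#' Reads a CSV manifest with header \code{image_path,patient_id,tirads},
#' derives binary labels from the TI-RADS column and validates every row.
#' Row order is preserved. All offending rows (invalid TI-RADS code, missing
#' image file, empty patient id) are reported in one error.
#'
#' @param path path to the manifest CSV (UTF-8, comma-separated).
#' @param origin dataset origin, \code{"real"} or \code{"synthetic"}.
#' @param checkImages verify that every \code{image_path} exists
#'   (default \code{TRUE}). Relative paths are resolved against the
#'   manifest's directory.
#' @return A \code{\linkS4class{Manifest}}.
#' @seealso \code{\link{writeManifest}}, \code{\link{tiradsToLabel}}
#' @export
readManifest <- function(path, origin = c("real", "synthetic"),
                         checkImages = TRUE) {
  origin <- match.arg(origin)
  if (!file.exists(path)) stop("manifest file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("image_path", "patient_id", "tirads")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, need, drop = FALSE]
  if (nrow(df) == 0) {
    df$label <- character(0)
    return(new("Manifest", samples = df, origin = origin))
  }
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", df$image_path), df$image_path,
                     file.path(dirname(path), df$image_path))
  problems <- character(0)
  badT <- which(!(df$tirads %in% .TIRADS_CODES))
  if (length(badT) > 0)
    problems <- c(problems, paste0("row ", badT, ": invalid tirads ",
                                   sQuote(df$tirads[badT])))
  badP <- which(!nzchar(df$patient_id))
  if (length(badP) > 0)
    problems <- c(problems, paste0("row ", badP, ": empty patient_id"))
  if (checkImages) {
    badI <- which(!file.exists(resolved))
    if (length(badI) > 0)
      problems <- c(problems, paste0("row ", badI, ": image not found ",
                                     sQuote(df$image_path[badI])))
  }
  dup <- which(duplicated(df$image_path))
  if (length(dup) > 0)
    problems <- c(problems, paste0("row ", dup, ": duplicate image_path ",
                                   sQuote(df$image_path[dup])))
  if (length(problems) > 0)
    stop("invalid manifest rows:\n  ", paste(problems, collapse = "\n  "))
  df$image_path <- resolved
  df$label <- tiradsToLabel(df$tirads)
  rownames(df) <- NULL
  new("Manifest", samples = df, origin = origin)
}

#' Write a dataset manifest
#'
#' Writes the three manifest columns \code{image_path,patient_id,tirads} as
#' CSV; labels are derived, not stored. \code{readManifest(writeManifest(m))}
#' is the identity on valid manifests.
#'
#' @param manifest a \code{\linkS4class{Manifest}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "Manifest"))
  utils::write.csv(
    manifest@samples[, c("image_path", "patient_id", "tirads"), drop = FALSE],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load an ultrasound image as a grayscale raster
#'
#' Reads a PNG or JPEG image and returns a numeric height x width matrix of
#' intensities in [0, 255]. Three-channel inputs are reduced by the standard
#' luminance weights (0.299, 0.587, 0.114); a grayscale+alpha or RGBA image
#' drops its alpha channel first. 16-bit PNGs are rescaled to [0, 255] by
#' max-value division.
#'
#' @param path path to an 8- or 16-bit PNG or a JPEG file.
#' @param grayWeights luminance weights for RGB reduction.
#' @return numeric matrix, rows = image height, columns = image width.
#' @export
loadImage <- function(path, grayWeights = c(0.299, 0.587, 0.114)) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' (PNG or JPEG expected): ",
         path))
  ## readers return values in [0, 1] (16-bit already divided by 65535)
  if (length(dim(arr)) == 3L) {
    hw <- dim(arr)[1:2]
    nc <- dim(arr)[3L]
    arr <- if (nc == 2L) arr[, , 1L]                     # gray + alpha
    else arr[, , 1L] * grayWeights[1L] + arr[, , 2L] * grayWeights[2L] +
      arr[, , 3L] * grayWeights[3L]                      # RGB(A): drop alpha
    dim(arr) <- hw
  }
  out <- arr * 255
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}
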