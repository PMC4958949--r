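#' Read a grayscale image
#'
#' Reads TIFF or PNG into a numeric matrix (rows = y, increasing downward;
#' columns = x).  8/16-bit integer images arrive scaled to `[0, 1]` (the
#' underlying readers' convention); float TIFFs pass through unchanged.
#' Multi-channel images are reduced to a single channel by Rec. 709
#' luminance with a warning.  If an affine sidecar written by
#' [write_image()] is present, the stored scale/offset is undone so the
#' original physical values are recovered.
#'
#' @param path a `.tif`/`.tiff` or `.png` file.
#' @return a numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path)
  } else stop("unsupported image format (use TIFF or PNG): ", path)
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    warning("multi-channel image reduced to luminance: ", path)
    if (nch >= 3L) {
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img <- as.matrix(img)
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    sc <- yaml::read_yaml(sidecar)
    if (!is.null(sc$scale))
      img <- img * as.numeric(sc$scale) + as.numeric(sc$offset)
  }
  img
}

#' Write a grayscale image
#'
#' TIFF output stores the matrix in 32-bit fixed point scaled to `[0, 1]`,
#' with the exact affine transform recorded in a `.yaml` sidecar that
#' [read_image()] undoes (round-trip accurate to ~2^-32 of the dynamic
#' range).  Data already inside `[0, 1]` is written directly with no
#' sidecar.  PNG output is an 8- or 16-bit preview, min-max scaled with the
#' scaling recorded in the sidecar.
#'
#' @param img numeric matrix.
#' @param path output file (`.tif`/`.tiff` or `.png`).
#' @param bits bit depth for PNG previews (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  img <- as_image_matrix(img)
  lo <- min(img); hi <- max(img)
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  sidecar <- paste0(path, ".yaml")
  if (!is_png && lo >= 0 && hi <= 1) {
    tiff::writeTIFF(img, path, bits.per.sample = 32L, compression = "none")
    if (file.exists(sidecar)) file.remove(sidecar)
    return(invisible(path))
  }
  scale <- if (hi > lo) hi - lo else 1
  scaled <- (img - lo) / scale
  if (is_png) {
    png::writePNG(scaled, path, dpi = NULL)
  } else {
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none")
  }
  # full-precision strings: yaml rounds bare doubles to ~7 digits
  yaml::write_yaml(list(scale = sprintf("%.17g", scale),
                        offset = sprintf("%.17g", lo)), sidecar)
  invisible(path)
}
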