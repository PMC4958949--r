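#' Average center-line profiles from four directions
#'
#' Extracts the horizontal, vertical and two diagonal line profiles through
#' a point (typically the bead center), resamples the diagonals to the
#' same physical length (their samples are `sqrt(2)` pixels apart) by
#' linear interpolation, and averages the four.  Used to compare a
#' reconstructed bead against the theoretical spherical phase profile.
#'
#' @param recon reconstruction (matrix or `dic_recon`).
#' @param center `c(x, y)` pixel coordinates of the profile center
#'   (column, row); `NULL` picks the centroid of the Otsu-thresholded
#'   normalized reconstruction.
#' @param length half-length of the profile in pixels (all four lines must
#'   fit inside the image).
#' @return numeric vector of length `2 * length + 1`: the averaged
#'   profile, positions `-length .. length` pixels from the center.
#' @export
extract_profiles <- function(recon, center = NULL, length = NULL) {
  r <- recon_image(recon)
  nr <- nrow(r); nc <- ncol(r)
  if (is.null(center)) {
    rng <- range(r)
    rn <- if (diff(rng) > 0) (r - rng[1]) / diff(rng) else r
    th <- otsu_threshold(as.vector(rn))
    fg <- rn > th
    if (!any(fg)) fg <- rn >= mean(rn)
    ys <- row(r)[fg]; xs <- col(r)[fg]
    center <- c(round(mean(xs)), round(mean(ys)))
  }
  cx <- center[1]; cy <- center[2]
  if (is.null(length))
    length <- min(cx - 1, nc - cx, cy - 1, nr - cy)
  L <- as.integer(length)
  if (cx - L < 1 || cx + L > nc || cy - L < 1 || cy + L > nr)
    stop("profile lines do not fit within the image")
  pos <- -L:L
  horiz <- r[cy, cx + pos]
  vert <- r[cy + pos, cx]
  # diagonal samples live at physical distance sqrt(2) * k; resample onto pos
  diag_profile <- function(sy, sx) {
    kmax <- L  # diagonal endpoints stay inside since |pos| <= L
    ks <- -kmax:kmax
    vals <- r[cbind(cy + sy * ks, cx + sx * ks)]
    stats::approx(x = ks * sqrt(2), y = vals, xout = pos, rule = 2)$y
  }
  d1 <- diag_profile(1, 1)
  d2 <- diag_profile(-1, 1)
  (horiz + vert + d1 + d2) / 4
}

#' Fit a calibration scale between measured and theoretical profiles
#'
#' Least-squares affine fit `theoretical ~ scale * measured + offset`
#' (reconstructions are defined only up to scale and background level).
#' The fitted scale converts a unit change of reconstructed intensity into
#' optical path length, which can then be applied to other images from the
#' same calibrated system.  `scale_only = TRUE` suppresses the offset.
#'
#' @param measured averaged reconstructed profile ([extract_profiles()]).
#' @param theoretical matching closed-form profile (e.g. the center line
#'   of [bead_phantom()]); same length, both non-constant.
#' @param scale_only fit without an intercept.
#' @return object of class `calibration_result`: list with `scale`,
#'   `offset`, `correlation`, `averaged_profile`, `theoretical_profile`.
#' @export
fit_scale <- function(measured, theoretical, scale_only = FALSE) {
  measured <- as.numeric(measured); theoretical <- as.numeric(theoretical)
  if (length(measured) != length(theoretical)) stop("profiles differ in length")
  if (stats::sd(measured) == 0 || stats::sd(theoretical) == 0)
    stop("constant profile: fit undefined")
  if (scale_only) {
    fit <- stats::lm(theoretical ~ measured + 0)
    scale <- unname(stats::coef(fit)[1]); offset <- 0
  } else {
    fit <- stats::lm(theoretical ~ measured)
    scale <- unname(stats::coef(fit)[2]); offset <- unname(stats::coef(fit)[1])
  }
  structure(list(scale = scale, offset = offset,
                 correlation = stats::cor(measured, theoretical),
                 averaged_profile = measured,
                 theoretical_profile = theoretical),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> scale = %.6g, offset = %.6g, r = %.4f\n",
              x$scale, x$offset, x$correlation))
  invisible(x)
}

#' Apply a fitted calibration to a reconstruction
#'
#' Affine transform `scale * values + offset`, converting reconstructed
#' intensities to optical path length units.
#'
#' @param recon reconstruction (matrix or `dic_recon`).
#' @param cal a `calibration_result` from [fit_scale()].
#' @param units unit label recorded on the output (attribute `"units"`).
#' @return calibrated matrix.
#' @export
apply_calibration <- function(recon, cal, units = "um") {
  stopifnot(inherits(cal, "calibration_result"))
  out <- cal$scale * recon_image(recon) + cal$offset
  attr(out, "units") <- units
  out
}
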