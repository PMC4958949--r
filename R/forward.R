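#' Simulate a DIC image from an optical path length map
#'
#' Applies the linear DIC image-formation model: the observed contrast
#' `G(x, y)` is the local windowed integral of the optical path length map
#' `I` against a derivative-type kernel `K` on `W = [-d, d]^2`,
#' `G(x, y) = sum_{(xi, eta) in W} K(xi, eta) I(x + xi, y + eta)`,
#' evaluated at every pixel with mirror (symmetric) boundary handling.
#' With a derivative-type (zero-sum) kernel this produces the familiar
#' bipolar bright/dark relief along the shear direction and maps constant
#' backgrounds to zero contrast.  Diffraction and partial coherence are
#' outside the model.
#'
#' @param truth numeric matrix: the optical path length map `I`.
#' @param psf a `dic_kernel` (or plain odd-sided matrix).
#' @return numeric matrix of the same size: the contrast image `G`.
#' @examples
#' k <- make_dirac_difference(shear_spec(0), offset = 1)
#' g <- simulate_dic(matrix(rep(c(0, 1), each = 8), 4, 4), k)
#' @export
simulate_dic <- function(truth, psf) {
  truth <- as_image_matrix(truth, "truth")
  k <- kernel_values(psf)
  if (nrow(k) > min(dim(truth)) || ncol(k) > min(dim(truth)))
    stop("kernel larger than image")
  correlate_mirror(truth, k)
}

#' Add white Gaussian noise at a target SNR
#'
#' Noise power is referenced to the *variance* of the signal: the noise is
#' zero-mean Gaussian with variance `var(g) / 10^(snr_db / 10)`.  DIC
#' images carry a large constant background (bias), so variance-referenced
#' SNR tracks the visible degradation rather than the mean square.
#'
#' @param g contrast image (must be non-constant).
#' @param snr_db target signal-to-noise ratio in dB; `Inf` returns `g`
#'   unchanged.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return noisy image, deterministic given `seed`.
#' @export
add_noise <- function(g, snr_db, seed = 1L) {
  g <- as_image_matrix(g, "g")
  if (is.infinite(snr_db)) return(g)
  v <- stats::var(as.vector(g))
  if (v == 0) stop("constant input: SNR undefined")
  nv <- v / 10^(snr_db / 10)
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(length(g), sd = sqrt(nv)))
  g + matrix(noise, nrow(g), ncol(g))
}

shape_mask <- function(shape, size, rotation_deg = 0, half = size / 4) {
  ctr <- (size + 1) / 2
  th <- -rotation_deg * pi / 180
  xy <- expand.grid(x = seq_len(size) - ctr, y = seq_len(size) - ctr)
  xr <- cos(th) * xy$x - sin(th) * xy$y
  yr <- sin(th) * xy$x + cos(th) * xy$y
  inside <- switch(shape,
    ellipse   = (xr / half)^2 + (yr / (0.6 * half))^2 <= 1,
    circle    = xr^2 + yr^2 <= half^2,
    rectangle = abs(xr) <= half & abs(yr) <= 0.6 * half,
    square    = abs(xr) <= half & abs(yr) <= half,
    cross     = (abs(xr) <= half & abs(yr) <= 0.35 * half) |
                (abs(yr) <= half & abs(xr) <= 0.35 * half),
    triangle  = {
      # equilateral triangle, centroid at origin, circumradius = half * 1.2
      R <- 1.2 * half
      a1 <- yr <= R / 2
      a2 <- (sqrt(3) * xr - yr) <= R
      a3 <- (-sqrt(3) * xr - yr) <= R
      a1 & a2 & a3
    },
    pentagon  = {
      # convex polygon: inside iff all edge cross products share one sign
      R <- 1.1 * half
      ang <- -pi / 2 + (0:4) * 2 * pi / 5
      vx <- R * cos(ang); vy <- R * sin(ang)
      pos <- rep(TRUE, length(xr)); neg <- rep(TRUE, length(xr))
      for (i in 1:5) {
        j <- i %% 5 + 1
        cr <- (vx[j] - vx[i]) * (yr - vy[i]) - (vy[j] - vy[i]) * (xr - vx[i])
        pos <- pos & cr >= 0
        neg <- neg & cr <= 0
      }
      pos | neg
    },
    stop("unknown shape: ", shape)
  )
  matrix(as.numeric(inside), size, size)  # filled by column: rows = y
}

#' Generate the synthetic shape phantom set
#'
#' Builds the package's stand-in for the public synthetic benchmark: 20
#' ground-truth optical path length images of simple geometric shapes and
#' rotated versions, 15 strictly two-valued ("binary", hard edges, no
#' antialiasing) and 5 containing a range of intensities (a radial ramp
#' inside the shape), each paired with its simulated DIC image.  Rotations
#' of the same base shape share a `base_shape` label so evaluation can
#' weight base shapes equally regardless of rotation count.
#'
#' @param config optional list overriding any of: `shapes` (character, base
#'   inventory), `size` (image side, pixels), `rotations_deg` (angles for
#'   the binary variants), `multilevel_rotation_deg`, `snr_db` (`Inf` =
#'   noise free), `psf` (a `dic_kernel`), `shear` (used to build the
#'   default PSF).  The default PSF is the Dirac-difference kernel, the
#'   close grid approximation of the `sigma = 0.5` Gaussian derivative.
#' @param seed integer seed (consumed only by the noise model).
#' @return an object of class `phantom_set`: list with `ground_truths`,
#'   `dic_images` (index-aligned lists of matrices), `labels` (tibble:
#'   `index`, `base_shape`, `rotation_deg`, `mode`), `psf`, `noise_db`,
#'   `seed`.
#' @examples
#' ps <- generate_shape_set(list(size = 32))
#' length(ps$ground_truths)
#' @export
generate_shape_set <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(list(
    shapes = c("ellipse", "rectangle", "pentagon", "triangle", "cross"),
    size = 64L,
    rotations_deg = c(0, 30, 60),
    multilevel_rotation_deg = 15,
    snr_db = Inf,
    shear = shear_spec(45),
    psf = NULL
  ), config)
  if (length(cfg$shapes) == 0L) stop("empty shape list")
  psf <- if (is.null(cfg$psf)) make_dirac_difference(cfg$shear) else cfg$psf
  gts <- list(); labels <- list(); idx <- 0L
  for (sh in cfg$shapes) {
    for (rot in cfg$rotations_deg) {
      idx <- idx + 1L
      gts[[idx]] <- shape_mask(sh, cfg$size, rot)
      labels[[idx]] <- list(base_shape = sh, rotation_deg = rot, mode = "binary")
    }
  }
  for (sh in cfg$shapes) {
    idx <- idx + 1L
    m <- shape_mask(sh, cfg$size, cfg$multilevel_rotation_deg)
    ctr <- (cfg$size + 1) / 2
    rho <- sqrt(outer(seq_len(cfg$size) - ctr, seq_len(cfg$size) - ctr,
                      function(y, x) x^2 + y^2))
    ramp <- 1 - 0.7 * rho / max(rho)
    gts[[idx]] <- m * ramp
    labels[[idx]] <- list(base_shape = sh,
                          rotation_deg = cfg$multilevel_rotation_deg,
                          mode = "multilevel")
  }
  labels <- tibble::tibble(
    index = seq_along(gts),
    base_shape = vapply(labels, `[[`, "", "base_shape"),
    rotation_deg = vapply(labels, `[[`, 0, "rotation_deg"),
    mode = vapply(labels, `[[`, "", "mode")
  )
  dics <- lapply(seq_along(gts), function(i) {
    g <- simulate_dic(gts[[i]], psf)
    if (is.finite(cfg$snr_db)) g <- add_noise(g, cfg$snr_db, seed + i) else g
  })
  structure(list(ground_truths = gts, dic_images = dics, labels = labels,
                 psf = psf, noise_db = cfg$snr_db, seed = seed),
            class = "phantom_set")
}

#' @export
print.phantom_set <- function(x, ...) {
  cat(sprintf("<phantom_set> %d images (%d binary, %d multilevel), %dx%d, snr = %s dB\n",
              length(x$ground_truths),
              sum(x$labels$mode == "binary"), sum(x$labels$mode == "multilevel"),
              nrow(x$ground_truths[[1]]), ncol(x$ground_truths[[1]]),
              format(x$noise_db)))
  invisible(x)
}

#' Spherical-bead phase phantom
#'
#' Optical path length map of a homogeneous sphere immersed in a medium:
#' the chord length through the sphere times the refractive index
#' difference, `OPL(rho) = delta_n * 2 * sqrt(radius^2 - rho^2)` for
#' `rho <= radius` and 0 outside, sampled at pixel centers.  This is the
#' theoretical profile used to calibrate reconstructed intensities to
#' physical path length (see [fit_scale()]).
#'
#' @param radius_um bead radius in micrometers (> 0).
#' @param delta_n refractive index difference bead minus medium (e.g.
#'   polystyrene 1.595 in immersion oil 1.515: 0.08).
#' @param pixel_um pixel size in micrometers.
#' @param size image side in pixels; the bead must fit.
#' @return numeric matrix in the same length unit as `radius_um`.
#' @export
bead_phantom <- function(radius_um, delta_n, pixel_um, size) {
  if (radius_um <= 0) stop("radius must be positive")
  r_px <- radius_um / pixel_um
  if (2 * r_px + 1 > size) stop("bead does not fit in the image")
  ctr <- (size + 1) / 2
  rho2 <- outer(seq_len(size) - ctr, seq_len(size) - ctr,
                function(y, x) x^2 + y^2) * pixel_um^2
  opl <- 2 * delta_n * sqrt(pmax(radius_um^2 - rho2, 0))
  opl
}

#' Write / read a phantom set directory
#'
#' One directory holding `gt_###.tif`, `dic_###.tif`, `psf.tif` and a
#' `manifest.yaml` recording labels, seed, SNR and shear.
#'
#' @param set a `phantom_set`.
#' @param dir output directory (created if needed).
#' @return `dir` (writer) or a `phantom_set` (reader), invisibly/visibly.
#' @export
write_phantom_set <- function(set, dir) {
  stopifnot(inherits(set, "phantom_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(set$ground_truths)
  for (i in seq_len(n)) {
    write_image(set$ground_truths[[i]], file.path(dir, sprintf("gt_%03d.tif", i)))
    write_image(set$dic_images[[i]], file.path(dir, sprintf("dic_%03d.tif", i)))
  }
  write_kernel(set$psf, file.path(dir, "psf.txt"))
  yaml::write_yaml(list(
    n = n,
    labels = lapply(seq_len(n), function(i) as.list(set$labels[i, ])),
    seed = set$seed,
    snr_db = if (is.finite(set$noise_db)) set$noise_db else "none",
    shear = list(u = set$psf$shear$u, v = set$psf$shear$v)
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_phantom_set
#' @export
read_phantom_set <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  n <- man$n
  gts <- lapply(seq_len(n), function(i)
    read_image(file.path(dir, sprintf("gt_%03d.tif", i))))
  dics <- lapply(seq_len(n), function(i)
    read_image(file.path(dir, sprintf("dic_%03d.tif", i))))
  shear <- shear_spec(u = man$shear$u, v = man$shear$v)
  psf <- load_kernel(file.path(dir, "psf.txt"), shear = shear)
  labels <- tibble::tibble(
    index = vapply(man$labels, `[[`, 1L, "index"),
    base_shape = vapply(man$labels, `[[`, "", "base_shape"),
    rotation_deg = vapply(man$labels, function(l) as.numeric(l$rotation_deg), 0),
    mode = vapply(man$labels, `[[`, "", "mode")
  )
  snr <- if (identical(man$snr_db, "none")) Inf else as.numeric(man$snr_db)
  structure(list(ground_truths = gts, dic_images = dics, labels = labels,
                 psf = psf, noise_db = snr, seed = man$seed),
            class = "phantom_set")
}
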