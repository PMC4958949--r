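#' Shear direction of a DIC microscope
#'
#' The two sheared beams of a DIC microscope are displaced along a unit
#' vector `u = (u, v)` in image coordinates (`x` rightward along columns,
#' `y` downward along rows).  All kernels and reconstruction algorithms in
#' the package take their orientation from a `shear_spec`.
#'
#' @param angle_deg shear angle in degrees, measured from the +x axis
#'   towards +y.  `0` is horizontal, `90` vertical, `45` the common
#'   diagonal configuration (the package default throughout).
#' @param u,v alternatively, explicit vector components (normalized
#'   internally; must not both be zero).
#' @return an object of class `shear_spec` with fields `u` and `v`
#'   (`u^2 + v^2 == 1`).
#' @examples
#' shear_spec(45)
#' shear_spec(u = 1, v = 0)
#' @export
shear_spec <- function(angle_deg = NULL, u = NULL, v = NULL) {
  if (!is.null(angle_deg)) {
    u <- cos(angle_deg * pi / 180)
    v <- sin(angle_deg * pi / 180)
  }
  if (is.null(u) || is.null(v)) stop("give either angle_deg or both u and v")
  nrm <- sqrt(u^2 + v^2)
  if (nrm == 0) stop("shear vector must be nonzero")
  structure(list(u = u / nrm, v = v / nrm), class = "shear_spec")
}

#' @export
print.shear_spec <- function(x, ...) {
  cat(sprintf("<shear_spec> u = %.6f, v = %.6f (%.1f deg)\n",
              x$u, x$v, atan2(x$v, x$u) * 180 / pi))
  invisible(x)
}

as_shear <- function(shear) {
  if (inherits(shear, "shear_spec")) return(shear)
  if (is.numeric(shear) && length(shear) == 2L)
    return(shear_spec(u = shear[1], v = shear[2]))
  if (is.numeric(shear) && length(shear) == 1L)
    return(shear_spec(angle_deg = shear))
  stop("shear must be a shear_spec, an angle in degrees, or a length-2 vector")
}

# nearest lattice step to the shear direction: one of the 4 axis/diagonal
# unit cells.  Integral (K0) kernels and the dirac-difference default
# offset are defined along this step.
shear_lattice_step <- function(shear) {
  s <- as_shear(shear)
  ang <- atan2(s$v, s$u)
  oct <- ((round(ang / (pi / 4)) %% 8) + 8) %% 8
  steps <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L),
                c(-1L, 0L), c(-1L, -1L), c(0L, -1L), c(1L, -1L))
  steps[[oct + 1L]]  # (dx, dy)
}

new_kernel <- function(values, shear, kind) {
  values <- as_image_matrix(values, "kernel")
  if (nrow(values) != ncol(values) || nrow(values) %% 2L == 0L)
    stop("kernel side must be odd and square")
  structure(list(values = values,
                 half_width = (nrow(values) - 1L) %/% 2L,
                 shear = as_shear(shear),
                 kind = kind),
            class = "dic_kernel")
}

#' @export
print.dic_kernel <- function(x, ...) {
  cat(sprintf("<dic_kernel> kind = %s, half_width = %d (%dx%d), shear = (%.3f, %.3f)\n",
              x$kind, x$half_width, nrow(x$values), ncol(x$values),
              x$shear$u, x$shear$v))
  invisible(x)
}

kernel_values <- function(k) {
  if (inherits(k, "dic_kernel")) k$values else as_image_matrix(k, "kernel")
}

#' Gaussian-derivative DIC point spread function
#'
#' The classical linear DIC model uses the first derivative of an isotropic
#' Gaussian along the shear direction as the point spread function.  The
#' kernel is sampled so that correlating an image with it approximates the
#' Gaussian-smoothed directional derivative of the image along +shear
#' (positive lobe on the +shear side); it is zero-sum (DC-free), so a
#' constant optical path produces no contrast.
#'
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param shear a [shear_spec()], angle in degrees, or length-2 vector.
#' @param half_width window half-width `d` in pixels; the kernel is sampled
#'   on `[-d, d]^2` (side `2 d + 1`).  Must satisfy `d >= ceil(3 sigma)` so
#'   the truncated tails are negligible.
#' @return a `dic_kernel` of kind `"gaussian_derivative"`.
#' @examples
#' k <- make_gaussian_derivative(0.5, shear_spec(0), half_width = 2)
#' sum(k$values)  # ~0: derivative kernels are DC-free
#' @export
make_gaussian_derivative <- function(sigma, shear = shear_spec(45),
                                     half_width = ceiling(3 * sigma)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive number")
  shear <- as_shear(shear)
  half_width <- as.integer(half_width)
  if (half_width < ceiling(3 * sigma))
    stop("half_width must be at least ceiling(3 * sigma)")
  xs <- -half_width:half_width
  g1 <- function(t) exp(-t^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  # d/dh G(p - h u) at h = 0 equals +(p.u)/sigma^2 G(p)
  vals <- outer(xs, xs, function(y, x) {
    s <- x * shear$u + y * shear$v
    s / sigma^2 * g1(x) * g1(y)
  })
  vals <- vals - mean(vals)  # exact DC-free despite truncation
  new_kernel(vals, shear, "gaussian_derivative")
}

#' Dirac-difference DIC point spread function
#'
#' The difference of two Dirac impulses at `+offset` and `-offset` along the
#' shear direction: `+1` on the +shear side, `-1` on the other, zero
#' elsewhere.  This is the standard coarse approximation of the
#' Gaussian-derivative PSF (close to `sigma = 0.5`) and is the kernel used
#' for the synthetic phantom set.  Offsets that do not land on the pixel
#' grid are realized by bilinear interpolation onto the four nearest pixels.
#'
#' @param shear a [shear_spec()], angle in degrees, or length-2 vector.
#' @param offset impulse displacement in pixels (> 0).  The default is the
#'   length of the lattice step nearest the shear direction (1 for an axis
#'   shear, `sqrt(2)` for a diagonal shear), which places the impulses
#'   exactly on the grid.
#' @param half_width window half-width; defaults to the smallest window
#'   containing the impulses.
#' @return a `dic_kernel` of kind `"dirac_difference"`.
#' @examples
#' k <- make_dirac_difference(shear_spec(0), offset = 1)
#' which(k$values != 0)
#' @export
make_dirac_difference <- function(shear = shear_spec(45), offset = NULL,
                                  half_width = NULL) {
  shear <- as_shear(shear)
  step <- shear_lattice_step(shear)
  if (is.null(offset)) offset <- sqrt(sum(step^2))
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0)
    stop("offset must be a positive number")
  px <- offset * shear$u; py <- offset * shear$v
  need <- ceiling(max(abs(px), abs(py)) - 1e-9)
  if (is.null(half_width)) half_width <- max(1L, as.integer(need))
  if (need > half_width) stop("offset larger than half_width")
  side <- 2L * half_width + 1L
  vals <- matrix(0, side, side)
  put <- function(vals, x, y, w) {
    x0 <- floor(x + 1e-12); y0 <- floor(y + 1e-12)
    fx <- x - x0; fy <- y - y0
    for (dd in list(c(0, 0, (1 - fx) * (1 - fy)), c(1, 0, fx * (1 - fy)),
                    c(0, 1, (1 - fx) * fy), c(1, 1, fx * fy))) {
      if (dd[3] > 1e-15) {
        r <- half_width + 1L + y0 + dd[2]; c <- half_width + 1L + x0 + dd[1]
        vals[r, c] <- vals[r, c] + w * dd[3]
      }
    }
    vals
  }
  vals <- put(vals, px, py, +1)
  vals <- put(vals, -px, -py, -1)
  new_kernel(vals, shear, "dirac_difference")
}

#' Integral (K0) form of a derivative-type kernel
#'
#' Builds the kernel `K0` whose discrete forward difference along the shear
#' lattice direction reproduces the input PSF on the interior of the window,
#' and whose first differences vanish identically on the window boundary.
#' Summation by parts then gives the exact identity
#' `correlate(I, K) == -correlate(backward_diff_shear(I), K0)`,
#' which lets the Euler-Lagrange data term move the derivative from the
#' image onto the kernel (the `kernel_form` scheme of
#' [el_data_term()]): the reconstruction then only ever differentiates the
#' image once, regardless of the PSF.
#'
#' The construction is an exclusive cumulative sum of the PSF along each
#' line parallel to the shear lattice step, embedded in a window enlarged by
#' two zero rings.  It is exact whenever each such line of the PSF sums to
#' zero, which holds for the axis/diagonal Gaussian-derivative and
#' Dirac-difference kernels by symmetry.
#'
#' @param psf a derivative-type (zero-sum) `dic_kernel` or matrix.
#' @param shear shear direction (taken from `psf` when it is a
#'   `dic_kernel`).
#' @return a `dic_kernel` of kind `"integral_K0"` with half-width
#'   `d + 2` and the lattice step used stored in field `step`.
#' @export
make_integral_kernel <- function(psf, shear = NULL) {
  if (inherits(psf, "dic_kernel") && is.null(shear)) shear <- psf$shear
  if (is.null(shear)) stop("shear must be given when psf is a plain matrix")
  shear <- as_shear(shear)
  k <- kernel_values(psf)
  if (abs(sum(k)) > 1e-10)
    stop("psf must be derivative-type (sum to 0); integral would not close on W")
  d <- (nrow(k) - 1L) %/% 2L
  step <- shear_lattice_step(shear)  # (dx, dy)
  d0 <- d + 2L
  side0 <- 2L * d0 + 1L
  k0 <- matrix(0, side0, side0)
  # exclusive cumsum: K0(p) = sum_{j >= 1} K(p - j * step)
  for (r in seq_len(side0)) for (c in seq_len(side0)) {
    y <- r - d0 - 1L; x <- c - d0 - 1L
    acc <- 0
    j <- 1L
    repeat {
      xx <- x - j * step[1]; yy <- y - j * step[2]
      if (abs(xx) > d || abs(yy) > d) break
      acc <- acc + k[yy + d + 1L, xx + d + 1L]
      j <- j + 1L
    }
    k0[r, c] <- acc
  }
  out <- new_kernel(k0, shear, "integral_K0")
  out$step <- step
  out
}

#' @rdname make_integral_kernel
#' @param k0 an `integral_K0` kernel.
#' @details `kernel_from_integral()` recovers the effective PSF (forward
#'   difference of `K0` along the lattice step); it equals the original PSF
#'   up to the two zero rings added by the embedding.
#' @export
kernel_from_integral <- function(k0) {
  stopifnot(inherits(k0, "dic_kernel"), k0$kind == "integral_K0")
  step <- k0$step
  v <- k0$values
  n <- nrow(v)
  shifted <- matrix(0, n, n)
  # K(p) = K0(p + step) - K0(p)
  rs <- seq_len(n) + step[2]; cs <- seq_len(n) + step[1]
  ok_r <- rs >= 1L & rs <= n; ok_c <- cs >= 1L & cs <= n
  shifted[ok_r, ok_c] <- v[rs[ok_r], cs[ok_c]]
  new_kernel(shifted - v, k0$shear, "custom")
}

#' Read and write kernel files
#'
#' Kernels are exchanged either as whitespace/comma-delimited text matrices
#' (full double precision, exact round-trip) or as single-plane TIFF files
#' (float TIFFs are read natively; written TIFFs store the values scaled to
#' fixed point with the exact affine transform in a `.yaml` sidecar, which
#' `load_kernel` undoes).
#'
#' @param path file to read (`.txt`/`.csv`/`.dat` text matrix or `.tif`).
#' @param shear shear direction to attach to the loaded kernel.
#' @return `load_kernel`: a `dic_kernel` of kind `"custom"`.
#' @examples
#' psf <- load_kernel(system.file("extdata", "psf_dirac_45deg.txt",
#'                                package = "dicrecon"))
#' psf$values
#' @export
load_kernel <- function(path, shear = shear_spec(45)) {
  if (!file.exists(path)) stop("kernel file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- read_image(path)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(strsplit(trimws(lines), "[,[:space:]]+"), as.numeric)
    if (length(unique(lengths(rows))) != 1L) stop("ragged kernel text matrix")
    m <- do.call(rbind, rows)
  }
  if (nrow(m) != ncol(m) || nrow(m) %% 2L == 0L)
    stop("kernel side must be odd")
  new_kernel(m, shear, "custom")
}

#' @rdname load_kernel
#' @param kernel a `dic_kernel` or numeric matrix.
#' @param format `"text"` or `"tiff"` (chosen from the file extension when
#'   omitted).
#' @export
write_kernel <- function(kernel, path, format = NULL) {
  v <- kernel_values(kernel)
  if (is.null(format))
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "text"
  if (format == "tiff") {
    write_image(v, path)
  } else {
    txt <- apply(v, 1L, function(r) paste(formatC(r, format = "g", digits = 17),
                                          collapse = " "))
    writeLines(txt, path)
  }
  invisible(path)
}
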