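# Internal discrete linear operators shared by the forward model and all
# reconstruction algorithms.  Every image-domain operator used in an energy
# is a windowed correlation under mirror (symmetric) padding; gradients are
# computed with the *exact* discrete adjoint (pad -> shift-sum -> crop has
# adjoint zero-embed -> flipped shift-sum -> fold), so analytic gradients
# match finite differences of the discrete energies to machine precision.

mirror_index <- function(n, m) {
  if (m == 0L) return(seq_len(n))
  c(rev(seq_len(m)), seq_len(n), n:(n - m + 1L))
}

# symmetric (edge-repeating) mirror padding; mr/mc must not exceed the
# corresponding image dimension
pad_mirror <- function(x, mr, mc = mr) {
  nr <- nrow(x); nc <- ncol(x)
  if (mr > nr || mc > nc)
    stop("padding exceeds image size (kernel larger than image)")
  x[mirror_index(nr, mr), mirror_index(nc, mc), drop = FALSE]
}

# adjoint of pad_mirror: accumulate padded entries back onto their sources
fold_mirror <- function(xp, mr, mc = mr) {
  nr <- nrow(xp) - 2L * mr; nc <- ncol(xp) - 2L * mc
  ri <- mirror_index(nr, mr); ci <- mirror_index(nc, mc)
  tmp <- rowsum(xp, ri)                    # groups 1..nr come out sorted
  out <- t(rowsum(t(tmp), ci))
  dimnames(out) <- NULL
  out
}

# correlation: out(i,j) = sum_{a,b} k(a,b) x(i + a - cr, j + b - cc),
# mirror boundary.  Kernel may be rectangular with odd sides.
correlate_mirror <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  if (kr %% 2L == 0L || kc %% 2L == 0L) stop("kernel sides must be odd")
  mr <- (kr - 1L) %/% 2L; mc <- (kc - 1L) %/% 2L
  xp <- pad_mirror(x, mr, mc)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) for (b in seq_len(kc)) {
    w <- k[a, b]
    if (w != 0)
      out <- out + w * xp[(a - 1L) + seq_len(nr), (b - 1L) + seq_len(nc), drop = FALSE]
  }
  out
}

# exact adjoint of correlate_mirror in its first argument
adjoint_correlate_mirror <- function(r, k) {
  kr <- nrow(k); kc <- ncol(k)
  mr <- (kr - 1L) %/% 2L; mc <- (kc - 1L) %/% 2L
  nr <- nrow(r); nc <- ncol(r)
  z <- matrix(0, nr + 2L * mr, nc + 2L * mc)
  for (a in seq_len(kr)) for (b in seq_len(kc)) {
    w <- k[a, b]
    if (w != 0) {
      ii <- (a - 1L) + seq_len(nr); jj <- (b - 1L) + seq_len(nc)
      z[ii, jj] <- z[ii, jj] + w * r
    }
  }
  fold_mirror(z, mr, mc)
}

# small difference kernels, (row, col) = (y, x), x rightward, y downward
kern_dx  <- function() matrix(c(-0.5, 0, 0.5), 1, 3)          # central d/dx
kern_dy  <- function() matrix(c(-0.5, 0, 0.5), 3, 1)          # central d/dy
kern_dxx <- function() matrix(c(1, -2, 1), 1, 3)
kern_dyy <- function() matrix(c(1, -2, 1), 3, 1)
kern_dxy <- function() {
  m <- matrix(0, 3, 3); m[1, 1] <- 0.25; m[3, 3] <- 0.25
  m[1, 3] <- -0.25; m[3, 1] <- -0.25
  m
}
kern_laplace <- function() matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)

# embed a smaller odd kernel in a larger odd square window (centers aligned)
embed_kernel <- function(k, half_width) {
  side <- 2L * half_width + 1L
  out <- matrix(0, side, side)
  rr <- half_width + 1L - (nrow(k) - 1L) %/% 2L
  cc <- half_width + 1L - (ncol(k) - 1L) %/% 2L
  out[rr:(rr + nrow(k) - 1L), cc:(cc + ncol(k) - 1L)] <- k
  out
}

# linear combination of difference kernels as one embedded square kernel
combine_kernels <- function(kernels, weights) {
  hw <- max(vapply(kernels, function(k) max(nrow(k), ncol(k)), 1L)) %/% 2L
  out <- matrix(0, 2L * hw + 1L, 2L * hw + 1L)
  for (i in seq_along(kernels))
    if (weights[i] != 0) out <- out + weights[i] * embed_kernel(kernels[[i]], hw)
  out
}

# central difference along an arbitrary unit direction via its components
kern_dir <- function(u, v) combine_kernels(list(kern_dx(), kern_dy()), c(u, v))

# Otsu's threshold on a numeric vector (maximize between-class variance)
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p); mu <- cumsum(p * mids); mu_t <- mu[nbins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

as_image_matrix <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a numeric matrix", arg))
  if (any(!is.finite(x))) stop(sprintf("%s contains non-finite values", arg))
  x
}
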