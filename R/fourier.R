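# Fourier-domain reconstruction baselines.  All three operate on the
# periodic (FFT) extension of the image: the Hilbert operator is a pure
# phase filter, and the Wiener/Yin inverse filters divide spectra
# elementwise with an additive regularizer in the denominator.

fft2 <- function(x) stats::fft(x)
ifft2_re <- function(X) Re(stats::fft(X, inverse = TRUE)) / length(X)

# kernel zero-padded to image size, 180-degree flipped, center wrapped to
# (1, 1): the forward model is a windowed *correlation*, so the transfer
# function FK with F(simulate) = FK * FI is the spectrum of the flipped
# kernel.  With this embedding the textbook inverse-filter formulas
# (Conj(FK) in the numerator, |FK|^2 in the denominator) invert
# simulate_dic exactly on periodic content.
embed_kernel_fft <- function(k, nr, nc) {
  kv <- kernel_values(k)
  if (nrow(kv) > nr || ncol(kv) > nc) stop("kernel larger than image")
  mr <- (nrow(kv) - 1L) %/% 2L; mc <- (ncol(kv) - 1L) %/% 2L
  ke <- matrix(0, nr, nc)
  for (a in seq_len(nrow(kv))) for (b in seq_len(ncol(kv))) {
    r <- ((mr + 1L - a) %% nr) + 1L
    c <- ((mc + 1L - b) %% nc) + 1L
    ke[r, c] <- ke[r, c] + kv[a, b]
  }
  ke
}

fft_freqs <- function(n) {
  f <- seq_len(n) - 1L
  f[f >= n / 2] <- f[f >= n / 2] - n
  f / n
}

#' Hilbert-transform DIC reconstruction
#'
#' Multiplies the 2D spectrum of the contrast image by `-i * sgn(s)`, where
#' `s` is the signed projection of the spatial frequency vector onto the
#' shear direction (zero frequency passes unchanged), and returns the real
#' part of the inverse transform.  This integration-like phase rotation
#' turns the bipolar DIC edge doublets into single-signed ridges.  The
#' operator preserves the image mean and is an isometry on the zero-mean
#' part.
#'
#' @param g DIC contrast image.
#' @param shear a [shear_spec()] (or angle/vector).
#' @param invert flip the sign of the signum filter (both signs are valid
#'   reconstructions with inverted contrast).
#' @return reconstruction matrix.
#' @export
hilbert_reconstruct <- function(g, shear = shear_spec(45), invert = FALSE) {
  g <- as_image_matrix(g, "g")
  shear <- as_shear(shear)
  nr <- nrow(g); nc <- ncol(g)
  fy <- fft_freqs(nr); fx <- fft_freqs(nc)
  s <- outer(fy, fx, function(fy, fx) fx * shear$u + fy * shear$v)
  mult <- -1i * sign(s)
  if (invert) mult <- -mult
  mult[s == 0] <- 0
  # self-conjugate (Nyquist) frequencies of even sizes have no well-defined
  # frequency sign; zero them so the operator maps real images to real
  # images consistently (H then squares to -1 off its null set)
  ny_y <- abs(fy + 0.5) < 1e-12; ny_x <- abs(fx + 0.5) < 1e-12
  if (abs(shear$v) > 1e-12) mult[ny_y, ] <- 0
  if (abs(shear$u) > 1e-12) mult[, ny_x] <- 0
  spec <- fft2(g) * mult
  out <- ifft2_re(spec)
  out + mean(g)  # DC passes unchanged
}

#' Wiener-filter DIC reconstruction
#'
#' Direct spectral division by the PSF, regularized by a constant
#' noise-to-signal term:
#' `I_hat = F^-1[ Conj(F K) F g / (|F K|^2 + ns_ratio) ]`.
#' Frequencies where the PSF spectrum vanishes (always including DC for a
#' derivative-type kernel) are suppressed rather than amplified.
#'
#' @param g DIC contrast image.
#' @param k the PSF (`dic_kernel`).
#' @param ns_ratio the noise-to-signal regularizer (>= 0; 0 is refused if
#'   the kernel spectrum has zeros).
#' @return reconstruction matrix.
#' @export
wiener_reconstruct <- function(g, k, ns_ratio = 1e-3) {
  g <- as_image_matrix(g, "g")
  stopifnot(ns_ratio >= 0)
  FK <- fft2(embed_kernel_fft(k, nrow(g), ncol(g)))
  p2 <- Mod(FK)^2
  if (ns_ratio == 0 && any(p2 < 1e-14 * max(p2)))
    stop("ns_ratio = 0 with zeros in the kernel spectrum: unregularized division")
  ifft2_re(Conj(FK) * fft2(g) / (p2 + ns_ratio))
}

#' Regularized inverse filtering (Yin) DIC reconstruction
#'
#' Single-image form of the multi-shear inverse filter: spectral division
#' with a Laplacian smoothness penalty and a constant sparsity penalty in
#' the denominator,
#' `I_hat = F^-1[ Conj(F K) F g / (|F K|^2 + smooth_weight |A|^2 +
#' sparse_weight) ]`,
#' where `A` is the spectrum of the 5-point discrete Laplacian.  With
#' `smooth_weight = 0` this reduces to [wiener_reconstruct()] with
#' `ns_ratio = sparse_weight`.
#'
#' @inheritParams wiener_reconstruct
#' @param smooth_weight weight of the Laplacian smoothness term (>= 0).
#' @param sparse_weight constant regularizer (>= 0).
#' @return reconstruction matrix.
#' @export
yin_reconstruct <- function(g, k, smooth_weight = 1e-3, sparse_weight = 1e-4) {
  g <- as_image_matrix(g, "g")
  stopifnot(smooth_weight >= 0, sparse_weight >= 0)
  nr <- nrow(g); nc <- ncol(g)
  FK <- fft2(embed_kernel_fft(k, nr, nc))
  FA <- fft2(embed_kernel_fft(kern_laplace(), nr, nc))
  p2 <- Mod(FK)^2
  denom <- p2 + smooth_weight * Mod(FA)^2 + sparse_weight
  if (any(denom < 1e-14 * max(denom)))
    stop("all regularizer weights zero with spectral zeros in the kernel")
  ifft2_re(Conj(FK) * fft2(g) / denom)
}
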