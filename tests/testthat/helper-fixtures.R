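# Shared fixtures and independent oracles.  Oracles are deliberately
# naive (explicit loops, closed forms) and never call the code paths they
# check.

# naive windowed correlation with mirror (symmetric) boundary: explicit
# per-pixel double sum with index reflection
oracle_correlate <- function(img, k) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(k); kc <- ncol(k)
  mr <- (kr - 1) / 2; mc <- (kc - 1) / 2
  reflect <- function(i, n) {
    # symmetric (edge-repeating): 0 -> 1, -1 -> 2, n+1 -> n, n+2 -> n-1
    while (i < 1 || i > n) i <- if (i < 1) 1 - i else 2 * n + 1 - i
    i
  }
  out <- matrix(0, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    acc <- 0
    for (a in seq_len(kr)) for (b in seq_len(kc)) {
      yy <- reflect(y + a - 1 - mr, nr)
      xx <- reflect(x + b - 1 - mc, nc)
      acc <- acc + k[a, b] * img[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

# central finite difference gradient of a scalar energy functional
oracle_fd_gradient <- function(efn, i, h = 1e-6) {
  gm <- matrix(0, nrow(i), ncol(i))
  for (p in seq_along(i)) {
    ip <- i; im <- i
    ip[p] <- ip[p] + h; im[p] <- im[p] - h
    gm[p] <- (efn(ip) - efn(im)) / (2 * h)
  }
  gm
}

# Mann-Whitney formulation of the AUC: probability that a random
# foreground pixel outranks a random background pixel, ties counted 1/2
oracle_auc_mann_whitney <- function(values, mask) {
  fg <- values[mask == 1]; bg <- values[mask == 0]
  tot <- 0
  for (f in fg) for (b in bg)
    tot <- tot + if (f > b) 1 else if (f == b) 0.5 else 0
  tot / (length(fg) * length(bg))
}

# zero-sum kernel whose spectrum vanishes only at DC (difference of two
# normalized Gaussians): invertible test kernel for the inverse filters
dog_kernel <- function(s1 = 0.5, s2 = 3, hw = 9) {
  xs <- -hw:hw
  g <- function(s) {
    v <- exp(-xs^2 / (2 * s^2)); m <- outer(v, v); m / sum(m)
  }
  k <- g(s1) - g(s2)
  k - mean(k)
}

# random zero-sum kernel of half-width d
random_zero_sum_kernel <- function(d, seed = 1) {
  withr::with_seed(seed, {
    k <- matrix(stats::rnorm((2 * d + 1)^2), 2 * d + 1)
    k - mean(k)
  })
}

# small phantom with constant border (padding-insensitive forward model)
square_phantom <- function(n = 32, lo = 9, hi = 24, value = 1) {
  ph <- matrix(0, n, n)
  ph[lo:hi, lo:hi] <- value
  ph
}

# materialize the transfer matrix H column by column (tiny instances only)
materialize_forward <- function(k, nr, nc) {
  kv <- if (inherits(k, "dic_kernel")) k$values else k
  H <- matrix(0, nr * nc, nr * nc)
  for (j in seq_len(nr * nc)) {
    e <- matrix(0, nr, nc); e[j] <- 1
    H[, j] <- as.vector(simulate_dic(e, kv))
  }
  H
}

# a non-square phantom shape for descent fixtures
shape_mask_fixture <- function() dicrecon:::shape_mask("ellipse", 24, 20)
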