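# Matrix-form baselines.  The transfer matrix H of the image-formation
# model is never materialized (it would be npixels^2); both solvers work
# matrix-free through the forward correlation and its exact adjoint.
# Tiny-instance cross-checks in the test suite materialize H explicitly.

#' Matrix-free system operator of the DIC image-formation model
#'
#' Wraps [simulate_dic()] and its exact adjoint as the pair `H f` / `H^T r`
#' acting on vectorized images, the form the algebraic solvers pose the
#' reconstruction in.  The pair satisfies the adjoint identity
#' `<H f, r> == <f, H^T r>` to machine precision.
#'
#' @param k the PSF (`dic_kernel`).
#' @param dims image dimensions `c(rows, cols)`.
#' @return list with functions `forward(f)`, `adjoint(r)` (both matrix in,
#'   matrix out) and `dims`.
#' @export
system_operator <- function(k, dims) {
  kv <- kernel_values(k)
  list(forward = function(f) correlate_mirror(f, kv),
       adjoint = function(r) adjoint_correlate_mirror(r, kv),
       dims = as.integer(dims))
}

#' Parameters of the SEMU reconstruction
#'
#' @param smooth_weight weight of the squared Laplacian smoothness term
#'   `||R f||^2`.
#' @param sparse_weight weight of the weighted L1 sparsity term
#'   `||W f||_1` (diagonal `W`, positive weights).
#' @param update_weights reweight the sparsity diagonal each iteration by
#'   the log-sum rule `w_i <- 1 / (f_i + weight_eps)`.
#' @param weight_eps reweighting floor; `NULL` means `1e-2 * max(f)` at
#'   reweighting time.
#' @param max_iter,rel_tol iteration cap and relative objective-decrease
#'   stopping threshold.
#' @export
semu_params <- function(smooth_weight = 1e-2, sparse_weight = 1e-3,
                        update_weights = FALSE, weight_eps = NULL,
                        max_iter = 500L, rel_tol = 1e-7) {
  structure(list(smooth_weight = smooth_weight, sparse_weight = sparse_weight,
                 update_weights = update_weights, weight_eps = weight_eps,
                 max_iter = as.integer(max_iter), rel_tol = rel_tol),
            class = "semu_params")
}

# autocorrelation kernel: (K star K)(delta) = sum_w K(w) K(w + delta);
# correlating an image with it equals H^T H under periodic/interior
# conditions, and it splits cleanly into nonnegative parts
kernel_autocorr <- function(kv) {
  d <- (nrow(kv) - 1L) %/% 2L
  side <- 4L * d + 1L
  out <- matrix(0, side, side)
  for (dy in (-2L * d):(2L * d)) for (dx in (-2L * d):(2L * d)) {
    acc <- 0
    for (y in max(-d, -d - dy):min(d, d - dy)) {
      xs <- max(-d, -d - dx):min(d, d - dx)
      acc <- acc + sum(kv[y + d + 1L, xs + d + 1L] *
                         kv[y + dy + d + 1L, xs + dx + d + 1L])
    }
    out[dy + 2L * d + 1L, dx + 2L * d + 1L] <- acc
  }
  out
}

#' Sparseness-enhanced multiplicative update (SEMU) reconstruction
#'
#' Nonnegativity-constrained quadratic program
#' `min_{f >= 0} ||H f - g||^2 + smooth_weight ||R f||^2 +
#'  sparse_weight ||W f||_1`
#' (`R` = discrete Laplacian, `W` = diagonal positive weights), solved by a
#' multiplicative update: the gradient is split into nonnegative parts
#' `D - N` (positive parts of the quadratic kernel and of the linear term
#' in `D`, negative parts in `N`) and the iterate is scaled by `(N / D)^gamma`.
#' Every iterate is nonnegative by construction (zeros are absorbing), and
#' the exponent `gamma` is halved whenever a step would raise the
#' objective, so the logged trace is monotone non-increasing.  Optional
#' log-sum reweighting accelerates sparsification.
#'
#' @param g DIC contrast image (used as-is; the model output may be
#'   negative, nonnegativity applies to the reconstruction only).
#' @param k the PSF (`dic_kernel`).
#' @param params a [semu_params()] list.
#' @param f0 optional nonnegative starting image (default: flat positive).
#' @return a `dic_recon` object (trace columns: total objective, data
#'   term, regularizer).
#' @export
semu_reconstruct <- function(g, k, params = semu_params(), f0 = NULL) {
  g <- as_image_matrix(g, "g")
  kv <- kernel_values(k)
  sw <- params$smooth_weight; sp <- params$sparse_weight
  lap <- kern_laplace()
  # composite quadratic kernel Q with Q f ~ 2 (H^T H + sw R^T R) f
  Q <- combine_kernels(list(kernel_autocorr(kv), kernel_autocorr(lap)),
                       c(2, 2 * sw))
  Qp <- pmax(Q, 0); Qn <- pmax(-Q, 0)
  htg <- adjoint_correlate_mirror(g, kv)    # exact H^T g
  f <- if (is.null(f0)) {
    matrix(max(mean(abs(g)), 1e-3), nrow(g), ncol(g))
  } else {
    if (any(f0 < 0)) stop("f0 must be nonnegative")
    f0
  }
  w <- matrix(1, nrow(g), ncol(g))
  obj <- function(f, w) {
    r <- correlate_mirror(f, kv) - g
    data <- sum(r^2)
    reg <- sw * sum(correlate_mirror(f, lap)^2) + sp * sum(w * f)
    c(data + reg, data, reg)
  }
  e <- obj(f, w)
  trace <- matrix(NA_real_, params$max_iter, 3)
  done <- 0L
  for (it in seq_len(params$max_iter)) {
    if (params$update_weights) {
      eps_w <- if (is.null(params$weight_eps)) 1e-2 * max(f, 1e-12)
               else params$weight_eps
      w <- 1 / (f + eps_w)
      e <- obj(f, w)
    }
    b <- sp * w - 2 * htg                       # linear term of the gradient
    D <- correlate_mirror(f, Qp) + pmax(b, 0) + 1e-300
    N <- correlate_mirror(f, Qn) + pmax(-b, 0)
    ratio <- N / D
    gamma <- 1
    accepted <- FALSE
    for (h in 0:20) {
      cand <- f * ratio^gamma
      ec <- obj(cand, w)
      if (ec[1] <= e[1]) { accepted <- TRUE; break }
      gamma <- gamma / 2
    }
    if (!accepted) break                        # stationary under the update
    rel <- (e[1] - ec[1]) / max(abs(e[1]), 1e-30)
    f <- cand; e <- ec
    trace[it, ] <- e
    done <- it
    if (rel < params$rel_tol) break
  }
  tr <- tibble::tibble(iter = seq_len(done), total = trace[seq_len(done), 1],
                       data = trace[seq_len(done), 2],
                       tv = trace[seq_len(done), 3])
  new_recon(f, tr, "semu", params)
}

#' Parameters of the SOCP reconstruction
#'
#' @param tv_weight isotropic total-variation weight.
#' @param sparse_weight L1 weight (unweighted; the sparsity reweighting of
#'   SEMU is dropped in this formulation).
#' @param max_iter,rel_tol primal-dual iteration cap and residual
#'   threshold.
#' @param max_pixels refuse images with more pixels than this (the
#'   formulation is reserved for small instances; see `force`).
#' @export
socp_params <- function(tv_weight = 1e-2, sparse_weight = 1e-3,
                        max_iter = 5000L, rel_tol = 1e-9,
                        max_pixels = 4096L) {
  structure(list(tv_weight = tv_weight, sparse_weight = sparse_weight,
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 max_pixels = as.integer(max_pixels)),
            class = "socp_params")
}

# forward differences with replicated edge (last difference 0); adjoint pair
fdiff_x <- function(f) cbind(f[, -1, drop = FALSE] - f[, -ncol(f), drop = FALSE], 0)
fdiff_y <- function(f) rbind(f[-1, , drop = FALSE] - f[-nrow(f), , drop = FALSE], 0)
# adjoint of fdiff_x: (D^T p)_j = p_{j-1} - p_j, with p_0 = 0 and the
# last column of p ignored (it multiplies the zero difference)
fdiff_x_adj <- function(p) {
  nc <- ncol(p)
  q <- matrix(0, nrow(p), nc)
  q[, 1] <- -p[, 1]
  if (nc > 1) q[, 2:nc] <- p[, 1:(nc - 1), drop = FALSE] - p[, 2:nc, drop = FALSE]
  q[, nc] <- p[, nc - 1]
  q
}

socp_objective <- function(f, g, kv, tvw, spw) {
  r <- correlate_mirror(f, kv) - g
  px <- fdiff_x(f); py <- fdiff_y(f)
  sum(r^2) + tvw * sum(sqrt(px^2 + py^2)) + spw * sum(abs(f))
}

#' Second-order cone program (SOCP) reconstruction
#'
#' Global minimizer of the convex program
#' `min_{f >= 0} ||H f - g||^2 + tv_weight TV_iso(f) + sparse_weight ||f||_1`
#' (isotropic discrete TV, forward differences), computed matrix-free by
#' Chambolle-Pock primal-dual splitting.  The iteration stops when the
#' primal-dual residual norms fall below `rel_tol` (relative) or at
#' `max_iter`.  Intended for small images; larger inputs are refused
#' unless `force = TRUE`.
#'
#' @inheritParams semu_reconstruct
#' @param params a [socp_params()] list.
#' @param force solve anyway when the image exceeds `max_pixels`.
#' @return reconstruction matrix.
#' @export
socp_reconstruct <- function(g, k, params = socp_params(), force = FALSE) {
  g <- as_image_matrix(g, "g")
  if (length(g) > params$max_pixels && !force)
    stop("image exceeds max_pixels = ", params$max_pixels,
         " (use force = TRUE to override)")
  kv <- kernel_values(k)
  tvw <- params$tv_weight; spw <- params$sparse_weight
  # operator norm bound: ||H|| <= sum |K|, ||grad|| <= sqrt(8)
  L <- sqrt(sum(abs(kv))^2 + 8)
  tau <- 1 / L; sigma <- 1 / L
  f <- matrix(0, nrow(g), ncol(g)); fbar <- f
  y <- matrix(0, nrow(g), ncol(g))           # dual of the data term
  px <- matrix(0, nrow(g), ncol(g)); py <- px  # dual of TV
  scale_g <- max(sqrt(sum(g^2)), 1e-30)
  for (it in seq_len(params$max_iter)) {
    f_old <- f; y_old <- y; px_old <- px; py_old <- py
    # dual ascent for the data term F(q) = ||q - g||^2:
    # prox_{sigma F*}(z) = (z - sigma g) / (1 + sigma / 2)
    y <- (y_old + sigma * correlate_mirror(fbar, kv) - sigma * g) / (1 + sigma / 2)
    if (tvw > 0) {
      qx <- px_old + sigma * fdiff_x(fbar)
      qy <- py_old + sigma * fdiff_y(fbar)
      nrm <- pmax(1, sqrt(qx^2 + qy^2) / tvw)
      px <- qx / nrm; py <- qy / nrm
    }
    # primal descent + prox of sparse_weight * sum(f) + indicator(f >= 0)
    div <- adjoint_correlate_mirror(y, kv)
    if (tvw > 0) div <- div + fdiff_x_adj(px) + fdiff_y_adj(py)
    f <- pmax(f_old - tau * div - tau * spw, 0)
    fbar <- 2 * f - f_old
    if (it %% 20L == 0L || it == params$max_iter) {
      # Chambolle-Pock residuals (primal/dual optimality violations)
      pres <- sqrt(sum(((f_old - f) / tau -
                          adjoint_correlate_mirror(y_old - y, kv) -
                          (if (tvw > 0) fdiff_x_adj(px_old - px) +
                             fdiff_y_adj(py_old - py) else 0))^2))
      dres <- sqrt(sum(((y_old - y) / sigma -
                          correlate_mirror(f_old - f, kv))^2) +
                     (if (tvw > 0)
                        sum(((px_old - px) / sigma - fdiff_x(f_old - f))^2 +
                              ((py_old - py) / sigma - fdiff_y(f_old - f))^2)
                      else 0))
      if ((pres + dres) / scale_g < params$rel_tol) break
    }
  }
  if (it == params$max_iter && (pres + dres) / scale_g > 1e-3)
    warning("socp_reconstruct: residuals above rel_tol at max_iter")
  f
}

fdiff_y_adj <- function(p) {
  nr <- nrow(p)
  q <- matrix(0, nr, ncol(p))
  q[1, ] <- -p[1, ]
  if (nr > 1) q[2:nr, ] <- p[1:(nr - 1), , drop = FALSE] - p[2:nr, , drop = FALSE]
  q[nr, ] <- p[nr - 1, ]
  q
}
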