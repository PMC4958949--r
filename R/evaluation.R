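#' Normalize a reconstruction/ground-truth pair for comparison
#'
#' Meaningless negative reconstruction values are clipped to zero first,
#' then each image is independently min-max scaled to `[0, 1]`.  MSE and
#' the other metrics are computed on images normalized this way, so the
#' comparison is invariant to the (arbitrary) overall scale of a
#' reconstruction.
#'
#' @param recon reconstruction (matrix or `dic_recon`).
#' @param truth ground-truth image (non-constant).
#' @return list with matrices `recon` and `truth`, both in `[0, 1]`.
#' @export
normalize_pair <- function(recon, truth) {
  r <- pmax(recon_image(recon), 0)
  t_ <- as_image_matrix(truth, "truth")
  scale01 <- function(x, what) {
    rng <- range(x)
    if (diff(rng) == 0) stop("constant ", what, " after clipping: scaling undefined")
    (x - rng[1]) / (rng[2] - rng[1])
  }
  list(recon = scale01(r, "reconstruction"), truth = scale01(t_, "ground truth"))
}

#' Mean squared error
#'
#' @param a,b equal-shaped numeric matrices.
#' @return mean of squared pixel differences (lower is better).
#' @export
mse <- function(a, b) {
  a <- recon_image(a); b <- recon_image(b)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  mean((a - b)^2)
}

#' Pearson correlation between two images
#'
#' @param a,b equal-shaped non-constant numeric matrices.
#' @return correlation over all pixels, in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  a <- recon_image(a); b <- recon_image(b)
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant input")
  stats::cor(as.vector(a), as.vector(b))
}

#' Threshold-sweep ROC curve and AUC against a binary mask
#'
#' The normalized reconstruction is thresholded at every unique value it
#' contains (plus sentinels below the minimum and above the maximum);
#' pixels `>= threshold` count as predicted foreground.  True/false
#' positive rates per threshold define the ROC curve; AUC is the
#' trapezoidal area under it.  With this tie convention the AUC equals the
#' Mann-Whitney statistic (probability that a random foreground pixel
#' outranks a random background pixel, ties counted one half).  AUC 1
#' means the reconstruction is threshold-equivalent to the ground truth.
#'
#' @param recon grayscale reconstruction (matrix or `dic_recon`).
#' @param mask binary ground-truth mask containing both classes.
#' @return object of class `roc_result`: list with `thresholds` (sorted
#'   increasing), `fpr`, `tpr` (same order) and `auc`.
#' @export
roc_auc <- function(recon, mask) {
  r <- recon_image(recon)
  m <- as_image_matrix(mask, "mask")
  if (!all(dim(r) == dim(m))) stop("shape mismatch")
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  pos <- sum(m == 1); neg <- sum(m == 0)
  if (pos == 0 || neg == 0) stop("mask contains a single class")
  rng <- range(r)
  rn <- if (diff(rng) > 0) (r - rng[1]) / diff(rng) else r * 0 + 0.5
  th <- sort(unique(as.vector(rn)))
  th <- c(th[1] - 1, th, th[length(th)] + 1)
  tpr <- fpr <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- rn >= th[i]
    tpr[i] <- sum(pred & m == 1) / pos
    fpr[i] <- sum(pred & m == 0) / neg
  }
  ord <- order(th)
  auc <- -sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = th[ord], fpr = fpr[ord], tpr = tpr[ord],
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

algorithm_registry <- function(psf, shear) {
  list(
    proposed  = function(g) reconstruct_proposed(g, psf)$image,
    feineigle = function(g) reconstruct_feineigle(g, psf)$image,
    hilbert   = function(g) hilbert_reconstruct(g, shear),
    wiener    = function(g) wiener_reconstruct(g, psf),
    yin       = function(g) yin_reconstruct(g, psf),
    semu      = function(g) semu_reconstruct(g, psf)$image,
    socp      = function(g) socp_reconstruct(g, psf)
  )
}

#' Benchmark reconstruction algorithms on a phantom set
#'
#' Runs each named algorithm on every DIC image of the set and scores it
#' against the paired ground truth with normalized MSE (or ROC/AUC against
#' a binarized truth).  Rotated variants of one base shape are averaged
#' first, then base shapes are averaged with equal weight, so a shape's
#' score does not depend on how many rotations of it are present.
#'
#' @param set a `phantom_set` (see [generate_shape_set()]).
#' @param algorithms character vector of algorithm names among
#'   `"proposed"`, `"feineigle"`, `"hilbert"`, `"wiener"`, `"yin"`,
#'   `"semu"`, `"socp"`, or a named list of functions `g -> matrix`.
#' @param metric `"mse"` (on [normalize_pair()] output) or `"auc"`
#'   (ground truths binarized at half range).
#' @return list with tibbles `per_image` (algorithm, index, base_shape,
#'   metric, value) and `summary` (algorithm, mean_value, rotation-weighted
#'   as described).
#' @export
benchmark <- function(set,
                      algorithms = c("proposed", "hilbert", "wiener",
                                     "feineigle", "yin", "semu"),
                      metric = c("mse", "auc")) {
  stopifnot(inherits(set, "phantom_set"))
  metric <- match.arg(metric)
  if (is.character(algorithms)) {
    reg <- algorithm_registry(set$psf, set$psf$shear)
    unknown <- setdiff(algorithms, names(reg))
    if (length(unknown))
      stop("unknown algorithm name(s): ", paste(unknown, collapse = ", "),
           "; valid: ", paste(names(reg), collapse = ", "))
    algorithms <- reg[algorithms]
  }
  rows <- list()
  for (alg in names(algorithms)) {
    fn <- algorithms[[alg]]
    for (i in seq_along(set$dic_images)) {
      rec <- fn(set$dic_images[[i]])
      truth <- set$ground_truths[[i]]
      val <- if (metric == "mse") {
        np <- normalize_pair(rec, truth)
        mse(np$recon, np$truth)
      } else {
        roc_auc(rec, (truth >= mean(range(truth))) * 1)$auc
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        algorithm = alg, index = i,
        base_shape = set$labels$base_shape[i],
        metric = metric, value = val)
    }
  }
  per_image <- do.call(rbind, rows)
  # rotation-equal weighting: average within base shape, then across shapes
  agg1 <- stats::aggregate(value ~ algorithm + base_shape, per_image, mean)
  agg2 <- stats::aggregate(value ~ algorithm, agg1, mean)
  summary <- tibble::tibble(algorithm = agg2$algorithm,
                            metric = metric, mean_value = agg2$value)
  summary <- summary[order(match(summary$algorithm, names(algorithms))), ]
  list(per_image = per_image, summary = summary)
}
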