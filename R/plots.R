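#' Plot an energy trace
#'
#' Per-iteration total, data and regularizer energy of an iterative
#' reconstruction, on a log10 y-axis.
#'
#' @param recon a `dic_recon` with a non-empty trace, or the trace tibble
#'   itself.
#' @return a ggplot object.
#' @export
plot_energy_trace <- function(recon) {
  tr <- if (inherits(recon, "dic_recon")) recon$trace else recon
  long <- rbind(
    data.frame(iter = tr$iter, term = "total", energy = tr$total),
    data.frame(iter = tr$iter, term = "data", energy = tr$data),
    data.frame(iter = tr$iter, term = "regularizer", energy = tr$tv)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = iter, y = energy, colour = term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "energy", colour = NULL)
}

#' Plot an ROC curve
#'
#' @param roc a `roc_result` from [roc_auc()].
#' @return a ggplot object.
#' @export
plot_roc <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  df <- data.frame(fpr = roc$fpr, tpr = roc$tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.4f", roc$auc))
}

#' Display an image matrix
#'
#' Convenience raster display with the package's (row = y downward)
#' convention.
#'
#' @param img numeric matrix or `dic_recon`.
#' @param ... passed to [graphics::image()].
#' @export
show_image <- function(img, ...) {
  m <- recon_image(img)
  graphics::image(t(m)[, nrow(m):1], asp = nrow(m) / ncol(m), axes = FALSE,
                  col = grDevices::gray.colors(256, 0, 1), ...)
  invisible(img)
}

utils::globalVariables(c("iter", "energy", "term", "fpr", "tpr"))
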