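# Basic vector-graphic exports of the comparative profiles. Cosmetics are
# out of scope; these produce readable PDFs for inspection.

#' Export a log2 fold-change heatmap as PDF
#'
#' Infinite log ratios (zero cells over a positive column mean) are floored
#' to `floor` for display only; the numeric fold-change object keeps the
#' sentinel.
#'
#' @param fc a [fold_change()] object.
#' @param path output PDF path.
#' @param floor display floor for `-Inf` log ratios (default -10).
#' @return Invisibly, `path`.
#' @export
export_fold_change_heatmap <- function(fc, path, floor = -10) {
  m <- fc$log2
  m[is.infinite(m)] <- floor
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(m, filename = path, cluster_cols = FALSE)
  } else {
    grDevices::pdf(path)
    graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                    axes = FALSE, main = "log2 fold change vs column mean")
    grDevices::dev.off()
  }
  invisible(path)
}

#' Export a PCA score scatter as PDF
#'
#' @param pca a [pca_profiles()] object.
#' @param path output PDF path.
#' @param groups optional factor coloring the samples.
#' @return Invisibly, `path`.
#' @export
export_pca_plot <- function(pca, path, groups = NULL) {
  grDevices::pdf(path)
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  ev <- pca$explained_variance
  graphics::plot(pca$scores[, 1], pca$scores[, 2], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * ev[2]))
  graphics::text(pca$scores[, 1], pca$scores[, 2],
                 labels = rownames(pca$scores), pos = 3, cex = 0.8)
  grDevices::dev.off()
  invisible(path)
}
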