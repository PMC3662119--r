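# Figure-style exports: scatter vs identity, Bland-Altman, per-category
# box-and-whisker, and the 4-panel mask overlay.  Base graphics, PNG files.

open_png <- function(path, width = 900, height = 700) {
  type <- if (capabilities("cairo")) "cairo" else NULL
  if (is.null(type)) png(path, width = width, height = height)
  else png(path, width = width, height = height, type = type)
}

#' Scatter plot of algorithm vs reference densities
#'
#' Algorithm on the x axis, reference standard on the y axis, with the
#' identity (perfect agreement) line and the ordinary-least-squares fit of
#' reference on algorithm.
#'
#' @param reference,algorithm numeric vectors of percent densities.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_agreement_scatter <- function(reference, algorithm, path) {
  open_png(path)
  on.exit(dev.off())
  plot(algorithm, reference, xlim = c(0, 100), ylim = c(0, 100),
       xlab = "Algorithm percent density", ylab = "Reference percent density",
       pch = 19, col = "grey30",
       main = "Algorithm vs reference standard")
  abline(0, 1, col = "blue", lwd = 2)
  fit <- stats::lm(reference ~ algorithm)
  abline(fit, col = "red", lwd = 2)
  legend("topleft", legend = c("identity", "least squares"),
         col = c("blue", "red"), lwd = 2, bty = "n")
  invisible(path)
}

#' Bland-Altman difference plot
#'
#' Difference (reference minus algorithm) against the pairwise mean, with the
#' bias line and the 1.96-sd limits of agreement.
#'
#' @param ba a [bland_altman()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_bland_altman <- function(ba, path) {
  stopifnot(inherits(ba, "bland_altman"))
  open_png(path)
  on.exit(dev.off())
  ylim <- range(c(ba$differences, ba$loa_low, ba$loa_high)) + c(-2, 2)
  plot(ba$means, ba$differences, pch = 19, col = "grey30", ylim = ylim,
       xlab = "Mean of reference and algorithm (%)",
       ylab = "Reference - algorithm (%)",
       main = "Bland-Altman agreement")
  abline(h = 0, col = "grey70")
  abline(h = ba$bias, col = "orange", lwd = 2)
  abline(h = c(ba$loa_low, ba$loa_high), col = "red", lty = 2, lwd = 2)
  invisible(path)
}

#' Box-and-whisker plot of reference densities per algorithm category
#'
#' Reference-standard densities grouped by the algorithm-derived BI-RADS
#' category, over shaded bands marking each category's density range.
#'
#' @param reference numeric vector of reference densities (percent).
#' @param algorithm_categories integer vector of categories 1..4.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_category_boxes <- function(reference, algorithm_categories, path) {
  open_png(path)
  on.exit(dev.off())
  plot(NULL, xlim = c(0.5, 4.5), ylim = c(0, 100), xaxt = "n",
       xlab = "Algorithm BI-RADS density category",
       ylab = "Reference percent density",
       main = "Reference densities per algorithm category")
  bands <- rbind(c(0, 25), c(25, 50), c(50, 75), c(75, 100))
  cols <- c("#dcf0dc", "#fdf3d0", "#fde3c8", "#f6d0d0")
  for (i in 1:4) {
    rect(i - 0.5, bands[i, 1], i + 0.5, bands[i, 2], col = cols[i],
         border = NA)
  }
  groups <- factor(algorithm_categories, levels = 1:4)
  boxplot(reference ~ groups, add = TRUE, at = 1:4, col = "white",
          xaxt = "n", yaxt = "n")
  axis(1, at = 1:4, labels = 1:4)
  invisible(path)
}

#' Four-panel mask overlay figure
#'
#' (a) the input image, (b) the image restricted to the breast envelope,
#' (c) dense pixels highlighted, (d) the binary region-of-interest map --
#' the visual audit trail of one density computation.
#'
#' @param image a [mammogram_image()].
#' @param masks a [build_envelope()] result.
#' @param result a [compute_density()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
export_figure_panels <- function(image, masks, result, path) {
  open_png(path, width = 1200, height = 1200)
  on.exit(dev.off())
  op <- par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(par(op), add = TRUE)
  show <- function(m, main, col = gray(seq(0, 1, length.out = 256))) {
    # transpose/reverse so the matrix displays in row/column image order
    image(t(m[nrow(m):1, , drop = FALSE]), col = col, axes = FALSE,
          main = main, useRaster = TRUE)
    box()
  }
  px <- image$pixels
  show(px, "(a) input")
  masked <- px
  masked[!masks$envelope] <- 0L
  show(masked, "(b) breast envelope")
  dense <- masks$envelope & px > result$threshold_final
  overlay <- matrix(1L, nrow(px), ncol(px))
  overlay[masks$envelope] <- 2L
  overlay[dense] <- 3L
  show(overlay, sprintf("(c) dense tissue: %.1f%%", result$percent_density),
       col = c("black", "grey55", "red"))
  show(ifelse(masks$envelope, 1L, 0L), "(d) ROI binary map",
       col = c("black", "white"))
  invisible(path)
}
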