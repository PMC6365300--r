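#' Manhattan plot of a genome scan
#'
#' -log10(P) by cumulative genomic position, chromosomes in alternating
#' shades, with the Bonferroni line at `alpha / M`.
#'
#' @param scan a `blink_scan` data.frame with >= 1 defined P value.
#' @param alpha significance level for the Bonferroni line.
#' @param M number of tests (defaults to scanned markers).
#' @param highlight optional marker row indices drawn emphasized (e.g. the
#'   pseudo-QTNs).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plot-data data.frame (scan columns plus the
#'   cumulative x coordinate).
#' @export
manhattan_plot <- function(scan, alpha = 0.01, M = nrow(scan),
                           highlight = NULL, ...) {
  if (all(is.na(scan$p))) stop("no defined P values to plot")
  chroms <- unique(scan$chromosome)
  offset <- 0
  x <- numeric(nrow(scan))
  mids <- numeric(length(chroms))
  for (i in seq_along(chroms)) {
    rows <- scan$chromosome == chroms[i]
    x[rows] <- offset + scan$position[rows]
    mids[i] <- offset + max(scan$position[rows]) / 2
    offset <- offset + max(scan$position[rows])
  }
  logp <- -log10(pmax(scan$p, 1e-300))
  cutline <- -log10(alpha / M)
  shade <- c("grey35", "steelblue")[(match(scan$chromosome, chroms) %% 2L) + 1L]
  graphics::plot(x, logp, pch = 20, cex = 0.6, col = shade,
                 xlab = "genomic position", ylab = expression(-log[10](P)),
                 xaxt = "n", ylim = c(0, max(logp, cutline, na.rm = TRUE) * 1.05),
                 ...)
  graphics::axis(1, at = mids, labels = chroms)
  graphics::abline(h = cutline, col = "red", lty = 2)
  if (!is.null(highlight))
    graphics::points(x[highlight], logp[highlight], pch = 1, cex = 1.4,
                     col = "red")
  invisible(cbind(scan, x = x))
}

#' @export
plot.blink <- function(x, ...) {
  manhattan_plot(x$final_scan, alpha = x$config$alpha,
                 M = nrow(x$final_scan), highlight = x$pseudo_qtns, ...)
}

#' Render a Manhattan plot to an image file with a sidecar table
#'
#' Writes a PNG plus a tab-separated sidecar (`<out>.tsv`) holding the
#' exact plotted values.
#'
#' @param scan a `blink_scan`.
#' @param out image path (`.png`).
#' @param alpha,M as in [manhattan_plot()].
#' @param width,height device size in pixels.
#' @return `out`, invisibly.
#' @export
write_manhattan <- function(scan, out, alpha = 0.01, M = nrow(scan),
                            width = 1200, height = 400) {
  grDevices::png(out, width = width, height = height)
  on.exit(grDevices::dev.off())
  pd <- manhattan_plot(scan, alpha = alpha, M = M)
  utils::write.table(pd, paste0(out, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
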