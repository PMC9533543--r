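#' Synteny dot plot of collinear blocks
#'
#' Anchors of each block are drawn in a chromosome-by-chromosome grid,
#' colored by orientation (black +, red -).
#'
#' @param blocks a `collinear_blocks` object (one species pair).
#' @param main plot title.
#' @export
plot_dotplot <- function(blocks, main = NULL) {
  if (!length(blocks)) stop("no blocks to plot")
  ca <- sort(unique(vapply(blocks, `[[`, "", "chrom_a")))
  cb <- sort(unique(vapply(blocks, `[[`, "", "chrom_b")))
  la <- vapply(ca, function(ch) max(unlist(lapply(blocks, function(b)
    if (b$chrom_a == ch) max(b$anchors$index_a) else 0))), numeric(1)) + 1
  lb <- vapply(cb, function(ch) max(unlist(lapply(blocks, function(b)
    if (b$chrom_b == ch) max(b$anchors$index_b) else 0))), numeric(1)) + 1
  offa <- cumsum(c(0, la[-length(la)])); names(offa) <- ca
  offb <- cumsum(c(0, lb[-length(lb)])); names(offb) <- cb
  graphics::plot(NA, xlim = c(0, sum(la)), ylim = c(0, sum(lb)),
                 xlab = blocks[[1]]$species_a, ylab = blocks[[1]]$species_b,
                 main = main)
  graphics::abline(v = offa, h = offb, col = "grey85")
  for (b in blocks)
    graphics::points(offa[b$chrom_a] + b$anchors$index_a,
                     offb[b$chrom_b] + b$anchors$index_b,
                     pch = ".", cex = 2,
                     col = if (b$orientation > 0) "black" else "red")
  invisible(NULL)
}

#' Karyotype ideogram of a painted genome
#'
#' Draws each target chromosome as a horizontal bar of segments colored
#' by ancestral chromosome, the standard way karyotype projections are
#' displayed.
#'
#' @param segments segment table from [segment_painting()] /
#'   [label_copies()].
#' @param main plot title.
#' @export
plot_ideogram <- function(segments, main = NULL) {
  chroms <- unique(segments$chrom)
  ncol_ <- max(segments$aek_chrom)
  cols <- grDevices::hcl.colors(max(ncol_, 3), "Dark 3")
  graphics::plot(NA, xlim = c(0, max(segments$target_end)),
                 ylim = c(0, length(chroms) + 1), xlab = "gene order",
                 ylab = "", yaxt = "n", main = main)
  graphics::axis(2, at = seq_along(chroms), labels = chroms, las = 1)
  for (i in seq_along(chroms)) {
    d <- segments[segments$chrom == chroms[i], ]
    for (r in seq_len(nrow(d)))
      graphics::rect(d$target_start[r], i - 0.3, d$target_end[r], i + 0.3,
                     col = cols[d$aek_chrom[r]], border = NA)
  }
  graphics::legend("topright", legend = seq_len(ncol_), fill = cols,
                   title = "ancestral", cex = 0.7, bty = "n")
  invisible(NULL)
}
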