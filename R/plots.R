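# Optional base-graphics conveniences mirroring the two standard figures
# of a tracker validation report.

#' Bland-Altman plot
#'
#' @param ba result of [bland_altman()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `ba`.
#' @export
plot_bland_altman <- function(ba, ...) {
  graphics::plot(ba$table$mean, ba$table$diff,
                 xlab = "Pair mean HR (bpm)",
                 ylab = "Tracker - criterion (bpm)",
                 pch = 16, cex = 0.4, col = "grey40", ...)
  graphics::abline(h = ba$mean_diff, col = "navy", lty = 2)
  graphics::abline(h = ba$loa, col = "steelblue", lty = 3)
  invisible(ba)
}

#' By-decile box plot of criterion and tracker heart rates
#'
#' @param pairs pooled `matched_pairs` for one phase and tracker.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the decile assignment.
#' @export
plot_decile_box <- function(pairs, ...) {
  dec <- assign_deciles(pairs$criterion_bpm)
  vals <- c(split(pairs$criterion_bpm, dec), split(pairs$tracker_bpm, dec))
  ord <- order(rep(1:10, 2), rep(1:2, each = 10))
  graphics::boxplot(vals[ord], col = rep(c("white", "grey80"), 10),
                    names = rep(1:10, each = 2), outline = FALSE,
                    xlab = "Criterion HR decile", ylab = "HR (bpm)", ...)
  invisible(dec)
}
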