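# Base-graphics figures mirroring the standard displays of this analysis.

#' Bar plot of per-tissue transcription-state proportions
#'
#' @param props data.frame from [state_proportions()].
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_state_proportions <- function(props, ...) {
  m <- rbind(props$fraction_transcribing, 1 - props$fraction_transcribing)
  graphics::barplot(m, names.arg = props$tissue, col = c("firebrick", "steelblue"),
                    las = 2, ylab = "proportion of enhancers",
                    legend.text = c("eRNA", "no-eRNA"), ...)
  graphics::abline(h = 0.5, lwd = 2)
  invisible(NULL)
}

#' Bar plot of the correlation profile
#'
#' One bar per region class per tissue (Pearson r of eRNA BPKM with the
#' class's region BPKM).
#'
#' @param corr data.frame from [correlation_profile()].
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_correlation_profile <- function(corr, ...) {
  tab <- tapply(corr$r, list(corr$label, corr$tissue), mean)
  graphics::barplot(tab, beside = TRUE, las = 2, ylab = "Pearson r",
                    legend.text = rownames(tab), ...)
  invisible(NULL)
}

#' Scatter of group mean z-scores with the least-rectangles line
#'
#' Each point is one cross-tissue group: mean target z-score over
#' non-transcribing members (x) against transcribing members (y); the
#' least-rectangles regression line is drawn in red, the unit diagonal in
#' grey.
#'
#' @param paired data.frame from [group_paired_means()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_group_scatter <- function(paired, ...) {
  x <- paired$mean_z_no_eRNA; y <- paired$mean_z_eRNA
  graphics::plot(x, y, xlab = "mean z (no-eRNA tissues)",
                 ylab = "mean z (eRNA tissues)", pch = 16,
                 col = grDevices::adjustcolor("black", 0.5), ...)
  graphics::abline(0, 1, col = "grey", lwd = 2)
  lr <- least_rectangles_line(x, y)
  graphics::abline(lr$intercept, lr$slope, col = "red", lwd = 2)
  invisible(lr)
}

#' Scatter of per-family hit ratios by class
#'
#' Significant families only: control-hit ratio (x) against eRNA-hit ratio
#' (y), miRNA families as red circles and other families as blue triangles,
#' with a least-rectangles trend line per class.
#'
#' @param cmp A `mirna_comparison` from [mirna_vs_other()].
#' @param xlim,ylim Axis limits.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_family_scatter <- function(cmp, xlim = c(0, 0.35), ylim = c(0, 0.35),
                                ...) {
  pts <- cmp$points
  if (is.null(pts) || nrow(pts) == 0) stop("no significant families to plot")
  mi <- pts$family_class == "miRNA"
  graphics::plot(pts$control_ratio, pts$real_ratio, type = "n",
                 xlim = xlim, ylim = ylim,
                 xlab = "ratio of hits (random controls)",
                 ylab = "ratio of hits (eRNAs)", ...)
  graphics::points(pts$control_ratio[mi], pts$real_ratio[mi], col = "red", pch = 1)
  graphics::points(pts$control_ratio[!mi], pts$real_ratio[!mi], col = "blue", pch = 2)
  if (!is.null(cmp$trend)) {
    for (i in seq_len(nrow(cmp$trend)))
      graphics::abline(cmp$trend$intercept[i], cmp$trend$slope[i],
                       col = ifelse(cmp$trend$family_class[i] == "miRNA",
                                    "red", "blue"))
  }
  invisible(NULL)
}
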