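# Statistics over ncRNA-family hit tables: length-matched random controls,
# per-family one-sided pooled two-proportion tests, and the miRNA-vs-other
# class comparison.

#' Sample length-matched random intergenic controls
#'
#' Draws as many control intervals as there are eRNAs; each control's length
#' is drawn with replacement from the eRNA length multiset and its position
#' uniformly from intergenic space (gene spans expanded by `margin`
#' excluded). Deterministic under `rng_seed`.
#'
#' @param ernas eRNA interval data.frame.
#' @param genes Gene-model data.frame.
#' @param chrom_sizes data.frame with `chrom`, `length`.
#' @param rng_seed Integer seed.
#' @param margin Gene margin excluded from intergenic space (bp).
#' @param max_tries Bounded retries per control before erroring.
#' @return Interval data.frame with `length(controls) == nrow(ernas)` and a
#'   `name` column `ctrl<i>`.
#' @export
sample_matched_controls <- function(ernas, genes, chrom_sizes, rng_seed = 1L,
                                    margin = 3000, max_tries = 100) {
  with_seed(rng_seed, {
    lens <- ernas$end - ernas$start
    segs <- intergenic_segments(genes, chrom_sizes, margin)
    out <- vector("list", nrow(ernas))
    for (i in seq_len(nrow(ernas))) {
      ok <- FALSE
      for (k in seq_len(max_tries)) {
        L <- sample(lens, 1)
        fit <- segs$end - segs$start >= L
        if (!any(fit)) next
        sf <- segs[fit, , drop = FALSE]
        w <- sf$end - sf$start - L + 1
        j <- sample.int(nrow(sf), 1, prob = w)
        s <- sf$start[j] + sample.int(w[j], 1) - 1
        out[[i]] <- data.frame(chrom = sf$chrom[j], start = s, end = s + L,
                               strand = "*", name = sprintf("ctrl%05d", i),
                               stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place control ", i,
                    " in intergenic space after ", max_tries, " tries")
    }
    do.call(rbind, out)
  })
}

#' One-sided pooled two-proportion z-test
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled proportion
#' `p = (k1 + k2)/(n1 + n2)`; the default alternative is `p1 > p2`. When the
#' pooled proportion is 0 or 1 the test is degenerate and reports p = 0.5
#' under the equality convention, flagged.
#'
#' @param k1,n1 Hits and total among eRNAs.
#' @param k2,n2 Hits and total among random controls.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return List with `k1`, `n1`, `k2`, `n2`, `z`, `p`, `degenerate`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, alternative = "greater") {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  pool <- (k1 + k2) / (n1 + n2)
  if (pool <= 0 || pool >= 1)
    return(list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, z = 0, p = 0.5,
                degenerate = TRUE))
  z <- (k1 / n1 - k2 / n2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
              stop("bad alternative"))
  list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, z = z, p = p, degenerate = FALSE)
}

#' Per-family enrichment of eRNA annotations over random controls
#'
#' Hit tables are deduplicated per (query, family) so each query contributes
#' an indicator; for every family present in either table, the proportion of
#' annotated eRNAs is tested against the proportion of annotated controls
#' with a one-sided pooled two-proportion z-test. `n1`/`n2` default to the
#' total numbers of queries (all eRNAs / all controls).
#'
#' @param hits_real,hits_control Family-hit data.frames
#'   (see [read_family_hits()]).
#' @param n_real,n_control Total numbers of real and control queries.
#' @param alpha Significance threshold (the selection rule is p < alpha).
#' @return data.frame with one row per family: counts, `z`, `p`,
#'   `significant`, `family_class`.
#' @export
family_enrichment <- function(hits_real, hits_control, n_real, n_control,
                              alpha = 0.001) {
  dedup <- function(h) h[!duplicated(paste(h$query_id, h$family_id)), ,
                         drop = FALSE]
  hr <- dedup(hits_real); hc <- dedup(hits_control)
  fams <- unique(rbind(hr[c("family_id", "family_class")],
                       hc[c("family_id", "family_class")]))
  fams <- fams[order(fams$family_id), , drop = FALSE]
  k1 <- as.integer(table(factor(hr$family_id, levels = fams$family_id)))
  k2 <- as.integer(table(factor(hc$family_id, levels = fams$family_id)))
  out <- fams
  out$k1 <- k1; out$n1 <- n_real; out$k2 <- k2; out$n2 <- n_control
  res <- mapply(function(a, b) {
    tp <- two_proportion_test(a, n_real, b, n_control)
    c(tp$z, tp$p, tp$degenerate)
  }, k1, k2)
  out$z <- res[1, ]; out$p <- res[2, ]; out$degenerate <- res[3, ] > 0
  out$significant <- !out$degenerate & out$p < alpha
  rownames(out) <- NULL
  out
}

#' miRNA-versus-other-family class comparison
#'
#' Aggregates significant families by class and asks whether eRNA hits are
#' over-represented relative to control hits more strongly for miRNA families
#' than for other ncRNA families: among hits to significant miRNA families,
#' the fraction that come from eRNAs (vs controls) is compared to the same
#' fraction for significant other families with a one-sided pooled
#' two-proportion z-test. Also emits the per-family scatter coordinates
#' (ratio of the family's hits to the total significant hits, separately for
#' eRNAs and controls) and a least-rectangles trend line per class.
#'
#' @param enrichment Per-family results from [family_enrichment()].
#' @return An object of class `mirna_comparison`: `test` (the class-level
#'   comparison, or NULL when a class has no significant family, reported as
#'   undefined), `points` (per significant family: `family_id`,
#'   `family_class`, `real_ratio`, `control_ratio`), `trend` (per class slope
#'   and intercept, where defined) and `defined`.
#' @export
mirna_vs_other <- function(enrichment) {
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  tot_real <- sum(sig$k1); tot_ctrl <- sum(sig$k2)
  points <- NULL
  if (nrow(sig) > 0) {
    points <- data.frame(
      family_id = sig$family_id, family_class = sig$family_class,
      real_ratio = if (tot_real > 0) sig$k1 / tot_real else 0,
      control_ratio = if (tot_ctrl > 0) sig$k2 / tot_ctrl else 0,
      stringsAsFactors = FALSE)
  }
  k_mi_r <- sum(sig$k1[sig$family_class == "miRNA"])
  k_mi_c <- sum(sig$k2[sig$family_class == "miRNA"])
  k_ot_r <- sum(sig$k1[sig$family_class != "miRNA"])
  k_ot_c <- sum(sig$k2[sig$family_class != "miRNA"])
  defined <- (k_mi_r + k_mi_c) > 0 && (k_ot_r + k_ot_c) > 0
  test <- if (defined)
    two_proportion_test(k_mi_r, k_mi_r + k_mi_c, k_ot_r, k_ot_r + k_ot_c)
  else NULL
  trend <- NULL
  for (cls in unique(points$family_class)) {
    pc <- points[points$family_class == cls, , drop = FALSE]
    if (nrow(pc) >= 2 && stats::sd(pc$control_ratio) > 0 &&
        stats::sd(pc$real_ratio) > 0) {
      lr <- least_rectangles_line(pc$control_ratio, pc$real_ratio)
      trend <- rbind(trend, data.frame(family_class = cls, slope = lr$slope,
                                       intercept = lr$intercept,
                                       stringsAsFactors = FALSE))
    }
  }
  structure(list(test = test, points = points, trend = trend,
                 defined = defined),
            class = "mirna_comparison")
}

#' @export
print.mirna_comparison <- function(x, ...) {
  if (!x$defined) {
    cat("miRNA-vs-other comparison undefined (a class has no significant family)\n")
    return(invisible(x))
  }
  cat(sprintf("miRNA vs other families (significant hits): z = %.3f, p = %.4g\n",
              x$test$z, x$test$p))
  cat(sprintf("  miRNA: %d eRNA / %d control hits; other: %d / %d\n",
              x$test$k1, x$test$n1 - x$test$k1,
              x$test$k2, x$test$n2 - x$test$k2))
  invisible(x)
}
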