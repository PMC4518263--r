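# Group same-positioned enhancers across tissues, standardize expression and
# run the paired and unpaired state comparisons.

#' Group same-positioned enhancers across tissues
#'
#' Per target gene, enhancer midpoints from all tissues are clustered by
#' single linkage at a 1000 bp threshold (adjacent midpoints within `window`
#' are chained). Candidate groups must contain at least one transcribing and
#' one non-transcribing member; among valid groups for the same gene, the
#' group(s) with the maximum number of enhancers are kept — ties between
#' groups sharing an enhancer are resolved by a seeded uniform choice, groups
#' with entirely disjoint enhancer sets are kept as separate groups.
#'
#' @param calls Calls data.frame across all tissues (needs `enhancer_id`,
#'   `tissue`, `state`, `gene_id`, `start`, `end`).
#' @param window Midpoint clustering threshold (bp).
#' @param rng_seed Integer seed for tie-breaking.
#' @return data.frame with one row per group member: `group_id`, `gene_id`,
#'   `enhancer_id`, `tissue`, `state`, `midpoint`, `anchor_start`,
#'   `anchor_end` (the representative interval spanned by the members).
#' @export
build_groups <- function(calls, window = 1000, rng_seed = 1L) {
  with_seed(rng_seed, {
    out <- NULL
    gid_counter <- 0L
    for (gene in sort(unique(calls$gene_id[!is.na(calls$gene_id)]))) {
      m <- calls[!is.na(calls$gene_id) & calls$gene_id == gene, , drop = FALSE]
      if (nrow(m) < 2) next
      mid <- (m$start + m$end) / 2
      o <- order(mid)
      m <- m[o, , drop = FALSE]; mid <- mid[o]
      # single linkage in 1D: cut where adjacent gap exceeds window
      cl <- cumsum(c(1, diff(mid) > window))
      groups <- split(seq_len(nrow(m)), cl)
      valid <- Filter(function(ix) {
        length(ix) >= 2 && any(m$state[ix] == "eRNA") &&
          any(m$state[ix] == "no-eRNA")
      }, groups)
      if (length(valid) == 0) next
      sizes <- vapply(valid, length, integer(1))
      best <- valid[sizes == max(sizes)]
      if (length(best) > 1) {
        # groups sharing an enhancer: keep one at random; disjoint groups are
        # separate (single-linkage clusters are disjoint, so this only fires
        # for externally supplied overlapping groupings)
        keep <- rep(TRUE, length(best))
        for (a in seq_along(best)) for (b in seq_along(best)) {
          if (a < b && keep[a] && keep[b] &&
              length(intersect(m$enhancer_id[best[[a]]],
                               m$enhancer_id[best[[b]]])) > 0) {
            drop <- sample(c(a, b), 1)
            keep[drop] <- FALSE
          }
        }
        best <- best[keep]
      }
      for (ix in best) {
        gid_counter <- gid_counter + 1L
        out <- rbind(out, data.frame(
          group_id = sprintf("grp%04d", gid_counter), gene_id = gene,
          enhancer_id = m$enhancer_id[ix], tissue = m$tissue[ix],
          state = m$state[ix], midpoint = (m$start[ix] + m$end[ix]) / 2,
          anchor_start = min(m$start[ix]), anchor_end = max(m$end[ix]),
          stringsAsFactors = FALSE))
      }
    }
    out
  })
}

#' Standardize BPKM to per-tissue z-scores
#'
#' `(x - mean) / sd` with the sample (n - 1) standard deviation within each
#' tissue's set of values.
#'
#' @param bpkm_table Long BPKM table (`region_id`, `tissue`, `bpkm`).
#' @return The table with a `z` column; per-tissue mean 0 and sd 1.
#' @export
zscore_by_tissue <- function(bpkm_table) {
  out <- bpkm_table
  out$z <- NA_real_
  for (t in unique(out$tissue)) {
    i <- out$tissue == t
    x <- out$bpkm[i]
    if (length(x) < 2) stop("tissue ", t, ": need >= 2 values for z-scores")
    s <- stats::sd(x)
    if (s == 0) stop("tissue ", t, ": constant values, z-scores undefined")
    out$z[i] <- (x - mean(x)) / s
  }
  out
}

#' Per-group mean z-scores by state
#'
#' For each group, the target gene's z-score is averaged over the member
#' tissues, separately for transcribing and non-transcribing members.
#'
#' @param groups Group membership data.frame from [build_groups()].
#' @param ztable z-score table from [zscore_by_tissue()] whose `region_id`
#'   holds gene ids.
#' @return data.frame with `group_id`, `gene_id`, `mean_z_eRNA`,
#'   `mean_z_no_eRNA`, `n_eRNA`, `n_no_eRNA`.
#' @export
group_paired_means <- function(groups, ztable) {
  zkey <- paste(ztable$region_id, ztable$tissue)
  groups$z <- ztable$z[match(paste(groups$gene_id, groups$tissue), zkey)]
  out <- NULL
  for (g in unique(groups$group_id)) {
    m <- groups[groups$group_id == g, , drop = FALSE]
    ze <- m$z[m$state == "eRNA"]; zn <- m$z[m$state == "no-eRNA"]
    out <- rbind(out, data.frame(
      group_id = g, gene_id = m$gene_id[1],
      mean_z_eRNA = mean(ze, na.rm = TRUE),
      mean_z_no_eRNA = mean(zn, na.rm = TRUE),
      n_eRNA = sum(!is.na(ze)), n_no_eRNA = sum(!is.na(zn)),
      stringsAsFactors = FALSE))
  }
  out
}

#' Paired t-test on group mean z-scores
#'
#' One-sample t on the differences `mean_z_eRNA - mean_z_no_eRNA`, one-sided
#' by default in the direction transcribing > non-transcribing.
#'
#' @param pairs data.frame from [group_paired_means()] (or any data.frame
#'   with `mean_z_eRNA` and `mean_z_no_eRNA` columns).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return An object of class `erna_test`: `statistic`, `df`, `p`,
#'   `alternative`, `n`, `method`, `estimate` (mean difference).
#' @export
paired_t_test <- function(pairs, alternative = "greater") {
  d <- pairs$mean_z_eRNA - pairs$mean_z_no_eRNA
  d <- d[is.finite(d)]
  if (length(d) < 2) stop("need at least 2 complete pairs")
  if (stats::sd(d) == 0) stop("zero variance in paired differences")
  tt <- stats::t.test(d, alternative = alternative)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 alternative = alternative, n = length(d),
                 estimate = mean(d), method = "paired t-test"),
            class = "erna_test")
}

#' One-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact enumeration for small tie-free samples (both n <= 20), otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors; the default alternative is `x` greater.
#' @param alternative Test direction.
#' @return An `erna_test` with the Mann-Whitney U statistic.
#' @export
rank_sum_test <- function(x, y, alternative = "greater") {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 20 && length(y) <= 20
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), df = NA_real_,
                 p = wt$p.value, alternative = alternative,
                 n = length(x) + length(y),
                 estimate = stats::median(x) - stats::median(y),
                 method = if (exact) "exact Wilcoxon rank-sum"
                          else "Wilcoxon rank-sum (normal approximation)"),
            class = "erna_test")
}

#' Least-rectangles (geometric-mean) regression line
#'
#' Symmetric regression: slope `sign(r) * sd(y) / sd(x)`, intercept through
#' the means.
#'
#' @param x,y Numeric vectors (n >= 2), both nonconstant.
#' @return List with `slope` and `intercept`.
#' @export
least_rectangles_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("least-rectangles line undefined for constant input")
  r <- stats::cor(x, y)
  slope <- sign(r) * sy / sx
  if (slope == 0) slope <- sy / sx  # r exactly 0: conventionally positive
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' @export
print.erna_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4f%s, n = %d, alternative = %s\n",
              x$statistic,
              if (is.finite(x$df)) sprintf(" (df = %g)", x$df) else "",
              x$n, x$alternative))
  cat(sprintf("  estimate = %.4f, p = %.4g\n", x$estimate, x$p))
  invisible(x)
}
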