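# BPKM quantification, matched target-gene regions, flanking and background
# regions, and Pearson correlation profiles of eRNA vs region expression.

#' BPKM: bases per kilobase of region per million mapped bases
#'
#' @param covered_bases Bases of the region covered by uniquely aligned reads.
#' @param region_length Region length (bp, > 0).
#' @param total_mapped_bases Library size in mapped bases (> 0).
#' @return `covered_bases / (region_length/1e3) / (total_mapped_bases/1e6)`.
#' @export
bpkm <- function(covered_bases, region_length, total_mapped_bases) {
  if (any(region_length <= 0)) stop("region_length must be > 0")
  if (any(total_mapped_bases <= 0)) stop("total_mapped_bases must be > 0")
  if (any(covered_bases < 0)) stop("covered_bases must be >= 0")
  covered_bases / (region_length / 1e3) / (total_mapped_bases / 1e6)
}

#' Target-gene region matched to the paired eRNA's length
#'
#' The region starts at the strand-aware gene start site (TSS) and spans the
#' eRNA's length into the gene body, truncated at the transcript end.
#'
#' @param gene One gene-model row.
#' @param erna_length Length of the paired eRNA (bp, > 0).
#' @return A single-row interval data.frame.
#' @export
matched_gene_region <- function(gene, erna_length) {
  stopifnot(erna_length > 0)
  len <- min(erna_length, gene$end[1] - gene$start[1])
  if (gene$strand[1] == "+")
    genomic_intervals(gene$chrom[1], gene$start[1], gene$start[1] + len,
                      gene$strand[1])
  else
    genomic_intervals(gene$chrom[1], gene$end[1] - len, gene$end[1],
                      gene$strand[1])
}

#' Enhancer flanking bins
#'
#' On each side of the enhancer's `window` region, three 1-kb bins starting
#' at the window boundary; if the eRNA extends past that boundary on a side,
#' the eRNA's far end is used as the starting boundary instead. Bins that
#' overlap a gene (or would start below 0) are discarded.
#'
#' @param enhancer One enhancer row (`chrom`, `start`, `end`).
#' @param erna The attached eRNA contig row (`start`, `end`).
#' @param window Window half-width (bp).
#' @param genes Gene-model data.frame.
#' @return Interval data.frame with columns `side` (`up`/`dn`) and `bin`
#'   (`0_1k`, `1_2k`, `2_3k`); up to 6 rows.
#' @export
flanking_regions <- function(enhancer, erna, window = 3000, genes) {
  fb <- flank_bins_all(
    enhancer_id = if ("enhancer_id" %in% names(enhancer))
      enhancer$enhancer_id[1] else "enh",
    chrom = enhancer$chrom[1], enh_start = enhancer$start[1],
    enh_end = enhancer$end[1],
    erna_start = if (!is.null(erna)) erna$start[1] else NA_real_,
    erna_end = if (!is.null(erna)) erna$end[1] else NA_real_,
    window = window, genes = genes)
  fb[c("chrom", "start", "end", "strand", "side", "bin")]
}

# vectorized flank-bin construction for many enhancers at once
flank_bins_all <- function(enhancer_id, chrom, enh_start, enh_end,
                           erna_start, erna_end, window, genes) {
  b_up <- enh_start - window
  b_dn <- enh_end + window
  b_up <- ifelse(!is.na(erna_start) & erna_start < b_up, erna_start, b_up)
  b_dn <- ifelse(!is.na(erna_end) & erna_end > b_dn, erna_end, b_dn)
  n <- length(b_up)
  k <- rep(1:3, each = n)
  bins <- rep(c("0_1k", "1_2k", "2_3k"), each = n)
  out <- data.frame(
    enhancer_id = rep(enhancer_id, 6),
    chrom = rep(chrom, 6),
    start = c(rep(b_up, 3) - k * 1000, rep(b_dn, 3) + (k - 1) * 1000),
    end = c(rep(b_up, 3) - (k - 1) * 1000, rep(b_dn, 3) + k * 1000),
    strand = "*",
    side = rep(c("up", "dn"), each = 3 * n),
    bin = c(bins, bins), stringsAsFactors = FALSE)
  out <- out[out$start >= 0, , drop = FALSE]
  if (nrow(out) > 0 && nrow(genes) > 0)
    out <- out[!overlaps_any(out, genes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region immediately upstream of a gene's TSS
#'
#' @param gene One gene-model row.
#' @param length Region length (bp).
#' @return A single-row interval data.frame 5' of the strand-aware TSS.
#' @export
gene_upstream_region <- function(gene, length) {
  if (gene$strand[1] == "+")
    genomic_intervals(gene$chrom[1], max(0, gene$start[1] - length),
                      gene$start[1])
  else
    genomic_intervals(gene$chrom[1], gene$end[1], gene$end[1] + length)
}

#' Sample a length-matched intergenic interval
#'
#' Uniform over all start positions of intergenic space (gene spans expanded
#' by `margin` are excluded).
#'
#' @param length Interval length (bp).
#' @param genes Gene-model data.frame.
#' @param chrom_sizes data.frame with `chrom`, `length`.
#' @param margin Gene margin excluded from intergenic space (bp).
#' @return A single-row interval data.frame, or an error if no intergenic
#'   segment can hold `length`.
#' @export
sample_intergenic_region <- function(length, genes, chrom_sizes,
                                     margin = 3000) {
  segs <- intergenic_segments(genes, chrom_sizes, margin)
  fit <- segs$end - segs$start >= length
  if (!any(fit)) stop("no intergenic segment can hold length ", length)
  segs <- segs[fit, , drop = FALSE]
  w <- segs$end - segs$start - length + 1
  i <- sample.int(nrow(segs), 1, prob = w)
  s <- segs$start[i] + sample.int(w[i], 1) - 1
  genomic_intervals(segs$chrom[i], s, s + length)
}

# complement of margin-expanded gene spans within chromosome bounds
intergenic_segments <- function(genes, chrom_sizes, margin = 3000) {
  out <- NULL
  for (k in seq_len(nrow(chrom_sizes))) {
    ch <- chrom_sizes$chrom[k]
    region <- genomic_intervals(ch, 0, chrom_sizes$length[k])
    g <- genes[genes$chrom == ch, , drop = FALSE]
    cutters <- if (nrow(g) > 0)
      genomic_intervals(ch, pmax(0, g$start - margin), g$end + margin)
    else genomic_intervals(ch, 0, 1)[0, ]
    out <- rbind(out, subtract_intervals(region, cutters))
  }
  out
}

#' Pearson correlation with a directional p-value
#'
#' Sample Pearson r with the t-transform p-value on n - 2 degrees of freedom
#' (one-sided, positive alternative by default).
#'
#' @param x,y Numeric vectors of equal length (n >= 3), both nonconstant.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y, alternative = "greater") {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, alternative = alternative, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation profile of eRNA expression against region classes
#'
#' For each tissue and region class, pairs each transcribing enhancer's eRNA
#' BPKM with the BPKM of the class region and computes Pearson r with a
#' one-sided (positive) p. Region values are looked up in the long BPKM table
#' by region id: the target-gene class uses the target `gene_id` (the table
#' value is the BPKM of the TSS-anchored region matched to the eRNA length,
#' see [matched_gene_region()]); flank classes use
#' `<enhancer_id>:flank_<side>_<bin>` for the bins that survive the
#' gene-overlap exclusion (both sides pooled within a bin class); the
#' background classes use `<enhancer_id>:gene_upstream` and
#' `<enhancer_id>:random_intergenic`. Pairs with no table row are dropped
#' listwise per class; classes with fewer than 3 usable pairs are flagged
#' undefined (NA r and p).
#'
#' @param calls Calls data.frame from [call_erna_states()] (needs `gene_id`).
#' @param genes Gene-model data.frame (for the flank gene-exclusion rule).
#' @param bpkm_table Long BPKM table (`region_id`, `tissue`, `bpkm`).
#' @param classes Region classes to profile.
#' @param window Enhancer window half-width used for flank geometry (bp).
#' @return data.frame with `tissue`, `label`, `n`, `r`, `p`.
#' @export
correlation_profile <- function(calls, genes, bpkm_table,
                                classes = c("target_gene", "flank_0_1k",
                                            "flank_1_2k", "flank_2_3k",
                                            "gene_upstream",
                                            "random_intergenic"),
                                window = 3000) {
  er <- calls[calls$state == "eRNA" & !is.na(calls$gene_id), , drop = FALSE]
  if (!"tissue" %in% names(er)) er$tissue <- "all"
  bkey <- paste(bpkm_table$region_id, bpkm_table$tissue)
  lookup <- function(ids, tissue) bpkm_table$bpkm[match(paste(ids, tissue), bkey)]
  out <- NULL
  for (t in unique(er$tissue)) {
    et <- er[er$tissue == t, , drop = FALSE]
    # flank-bin survival per enhancer, computed once (vectorized)
    flank_ids <- NULL
    if (any(grepl("^flank_", classes)) && nrow(et) > 0) {
      fb <- flank_bins_all(et$enhancer_id, et$chrom, et$start, et$end,
                           et$contig_start, et$contig_end, window, genes)
      if (nrow(fb) > 0) {
        flank_ids <- data.frame(
          enhancer_id = fb$enhancer_id,
          erna = et$contig_bpkm[match(fb$enhancer_id, et$enhancer_id)],
          bin = fb$bin, side = fb$side, stringsAsFactors = FALSE)
      }
    }
    for (cl in classes) {
      if (grepl("^flank_", cl)) {
        bin <- sub("^flank_", "", cl)
        fb <- if (is.null(flank_ids)) NULL
              else flank_ids[flank_ids$bin == bin, , drop = FALSE]
        if (is.null(fb) || nrow(fb) == 0) { xs <- numeric(0); ys <- numeric(0) }
        else {
          ids <- paste0(fb$enhancer_id, ":flank_", fb$side, "_", fb$bin)
          xs <- fb$erna; ys <- lookup(ids, t)
        }
      } else if (cl == "target_gene") {
        xs <- et$contig_bpkm; ys <- lookup(et$gene_id, t)
      } else {
        xs <- et$contig_bpkm; ys <- lookup(paste0(et$enhancer_id, ":", cl), t)
      }
      ok <- !is.na(xs) & !is.na(ys)
      xs <- xs[ok]; ys <- ys[ok]
      if (length(xs) >= 3 && stats::sd(xs) > 0 && stats::sd(ys) > 0) {
        pc <- pearson_cor(xs, ys)
        row <- data.frame(tissue = t, label = cl, n = pc$n, r = pc$r, p = pc$p,
                          stringsAsFactors = FALSE)
      } else {
        row <- data.frame(tissue = t, label = cl, n = length(xs),
                          r = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
      }
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}
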