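# End-to-end analysis: state calling per tissue, correlation profile,
# cross-tissue grouped comparison, family-annotation enrichment and
# miRNA-like promoter target discovery with the shuffle bootstrap.

#' Run the full eRNA analysis on a world of inputs
#'
#' Applies the whole pipeline to an input bundle (typically a synthetic world
#' from [generate_world()], or any list with the same components): filters
#' intergenic enhancers and gene-overlapping contigs, calls per-tissue
#' transcription states, computes per-tissue state proportions, the
#' eRNA-target correlation profile against flank/upstream/intergenic
#' backgrounds, cross-tissue same-positioned groups with the paired t-test
#' and least-rectangles line, per-tissue one-sided rank-sum tests of target
#' z-scores by state (deduplicated by gene and state), family-annotation
#' enrichment with the miRNA-vs-other comparison, and the shuffle-bootstrap
#' miRNA-like target analysis on a subset of eRNA sequences.
#'
#' @param world Input bundle (see [generate_world()] for the components).
#' @param window State-calling window (bp).
#' @param margin Intergenic margin (bp).
#' @param group_window Cross-tissue grouping window (bp).
#' @param bootstrap_B Shuffle-bootstrap replicates per eRNA.
#' @param n_bootstrap_ernas Number of eRNA sequences taken through the
#'   bootstrap (in input order; 0 skips the stage).
#' @param rng_seed Integer seed for grouping tie-breaks and the bootstrap.
#' @return An object of class `erna_analysis`.
#' @export
erna_analysis <- function(world, window = 3000, margin = 3000,
                          group_window = 1000, bootstrap_B = 100,
                          n_bootstrap_ernas = 10, rng_seed = 1L) {
  genes <- world$genes
  enh <- filter_intergenic_enhancers(world$enhancers, genes, margin)
  ctg <- filter_gene_overlapping_contigs(world$contigs, genes)
  calls <- call_erna_states(enh, ctg, window)
  props <- state_proportions(calls)
  corr <- correlation_profile(calls, genes, world$bpkm, window = window)

  # z-scores over each tissue's target-gene BPKMs
  target_genes <- unique(calls$gene_id[!is.na(calls$gene_id)])
  gz <- world$bpkm[world$bpkm$region_id %in% target_genes, , drop = FALSE]
  ztab <- zscore_by_tissue(gz)

  groups <- build_groups(calls, window = group_window, rng_seed = rng_seed)
  paired <- NULL; paired_test <- NULL; lr_line <- NULL
  if (!is.null(groups) && length(unique(groups$group_id)) >= 2) {
    paired <- group_paired_means(groups, ztab)
    paired_test <- paired_t_test(paired)
    if (nrow(paired) >= 2 && stats::sd(paired$mean_z_no_eRNA) > 0 &&
        stats::sd(paired$mean_z_eRNA) > 0)
      lr_line <- least_rectangles_line(paired$mean_z_no_eRNA,
                                       paired$mean_z_eRNA)
  }

  # per-tissue unpaired comparison, deduplicated by (gene, state)
  zkey <- paste(ztab$region_id, ztab$tissue)
  ranksum <- NULL
  for (t in unique(calls$tissue)) {
    ct <- calls[calls$tissue == t & !is.na(calls$gene_id), , drop = FALSE]
    ct <- ct[!duplicated(paste(ct$gene_id, ct$state)), , drop = FALSE]
    z <- ztab$z[match(paste(ct$gene_id, t), zkey)]
    x <- z[ct$state == "eRNA" & !is.na(z)]
    y <- z[ct$state == "no-eRNA" & !is.na(z)]
    if (length(x) > 0 && length(y) > 0) {
      rs <- rank_sum_test(x, y)
      ranksum <- rbind(ranksum, data.frame(
        tissue = t, n_eRNA = length(x), n_no_eRNA = length(y),
        U = rs$statistic, p = rs$p, stringsAsFactors = FALSE))
    }
  }

  enrich <- NULL; mir_cmp <- NULL
  if (!is.null(world$family_hits)) {
    fh <- world$family_hits
    enrich <- family_enrichment(fh$real, fh$control, fh$n_real, fh$n_control)
    mir_cmp <- mirna_vs_other(enrich)
  }

  bootstrap <- NULL
  if (n_bootstrap_ernas > 0 && length(world$sequences$erna) > 0) {
    # candidate targets per eRNA: the calling enhancer's target gene
    ctg2enh <- calls[calls$state == "eRNA", c("contig_name", "gene_id")]
    boot_rows <- NULL
    taken <- 0L
    for (id in names(world$sequences$erna)) {
      if (taken >= n_bootstrap_ernas) break
      gid <- ctg2enh$gene_id[match(id, ctg2enh$contig_name)]
      if (is.na(gid)) next
      prom <- world$sequences$promoter[intersect(gid, names(world$sequences$promoter))]
      if (length(prom) == 0) next
      utr <- world$sequences$utr3[intersect(gid, names(world$sequences$utr3))]
      stat_fn <- function(s)
        nrow(mir_like_targets(s, world$seed_families, prom, utr))
      # bootstrap only the resulting miR-like eRNAs: those with at least one
      # retained promoter-unique match on the real sequence
      if (stat_fn(world$sequences$erna[[id]]) == 0) next
      taken <- taken + 1L
      sb <- shuffle_bootstrap(world$sequences$erna[[id]], stat_fn,
                              B = bootstrap_B, rng_seed = rng_seed + taken)
      boot_rows <- rbind(boot_rows, data.frame(
        erna = id, observed = sb$observed, p = sb$p, stringsAsFactors = FALSE))
    }
    bootstrap <- boot_rows
  }

  structure(list(calls = calls, proportions = props, correlation = corr,
                 groups = groups, paired_means = paired,
                 paired_test = paired_test, least_rectangles = lr_line,
                 rank_sum = ranksum, enrichment = enrich,
                 mirna_comparison = mir_cmp, bootstrap = bootstrap,
                 zscores = ztab,
                 params = list(window = window, margin = margin,
                               group_window = group_window,
                               bootstrap_B = bootstrap_B,
                               rng_seed = rng_seed)),
            class = "erna_analysis")
}

#' @export
print.erna_analysis <- function(x, ...) {
  cat("eRNA analysis\n")
  cat(sprintf("  %d enhancers called in %d tissue(s); overall transcribing fraction %.3f\n",
              nrow(x$calls), length(unique(x$calls$tissue)),
              mean(x$calls$state == "eRNA")))
  tg <- x$correlation[x$correlation$label == "target_gene", , drop = FALSE]
  if (nrow(tg) > 0)
    cat(sprintf("  eRNA-target correlation (mean over tissues): r = %.3f\n",
                mean(tg$r, na.rm = TRUE)))
  if (!is.null(x$paired_test))
    cat(sprintf("  %d cross-tissue groups; paired t = %.3f, one-sided p = %.3g\n",
                nrow(x$paired_means), x$paired_test$statistic,
                x$paired_test$p))
  if (!is.null(x$enrichment))
    cat(sprintf("  %d/%d ncRNA families significantly enriched (p < 0.001)\n",
                sum(x$enrichment$significant), nrow(x$enrichment)))
  if (!is.null(x$bootstrap))
    cat(sprintf("  shuffle bootstrap on %d eRNAs: median p = %.4f\n",
                nrow(x$bootstrap), stats::median(x$bootstrap$p)))
  invisible(x)
}

#' @method summary erna_analysis
#' @export
summary.erna_analysis <- function(object, ...) {
  print(object)
  cat("\nPer-tissue state proportions:\n")
  print(object$proportions, row.names = FALSE)
  cat("\nCorrelation profile:\n")
  print(object$correlation, row.names = FALSE)
  if (!is.null(object$rank_sum)) {
    cat("\nPer-tissue rank-sum tests (target z by state):\n")
    print(object$rank_sum, row.names = FALSE)
  }
  if (!is.null(object$mirna_comparison)) {
    cat("\n")
    print(object$mirna_comparison)
  }
  invisible(object)
}

#' Write analysis outputs as plain-text tables
#'
#' Byte-deterministic for a fixed analysis object: calls, proportions,
#' correlation profile, groups, paired means, test results and bootstrap
#' table as TSV/JSON under `dir`.
#'
#' @param x An `erna_analysis`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(x$calls, "calls.tsv")
  wt(x$proportions, "proportions.tsv")
  wt(x$correlation, "correlation.tsv")
  if (!is.null(x$groups)) wt(x$groups, "groups.tsv")
  if (!is.null(x$paired_means)) wt(x$paired_means, "paired_means.tsv")
  if (!is.null(x$rank_sum)) wt(x$rank_sum, "rank_sum.tsv")
  if (!is.null(x$enrichment)) wt(x$enrichment, "enrichment.tsv")
  if (!is.null(x$bootstrap)) wt(x$bootstrap, "bootstrap.tsv")
  tests <- list()
  if (!is.null(x$paired_test))
    tests$paired_t <- x$paired_test[c("statistic", "df", "p", "n")]
  if (!is.null(x$least_rectangles)) tests$least_rectangles <- x$least_rectangles
  if (!is.null(x$mirna_comparison) && x$mirna_comparison$defined)
    tests$mirna_vs_other <- x$mirna_comparison$test[c("z", "p")]
  jsonlite::write_json(tests, file.path(dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
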