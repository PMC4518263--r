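# Classify intergenic enhancers into transcribing (En_eRNA) and
# non-transcribing (En_no-eRNA) states from strand-aware RNA-seq contigs.

#' 5' start of strand-aware contigs
#'
#' The transcript start is the leftmost coordinate on the plus strand and the
#' last covered base (`end - 1`) on the minus strand.
#'
#' @param contigs Interval data.frame with a `strand` column (`+` or `-`).
#' @return Numeric vector of 5'-start coordinates.
#' @export
five_prime_start <- function(contigs) {
  if (any(!contigs$strand %in% c("+", "-")))
    stop("5' start is undefined for unstranded contigs")
  ifelse(contigs$strand == "+", contigs$start, contigs$end - 1)
}

#' Keep intergenic enhancers
#'
#' Retains enhancers that overlap no gene and whose gap to every gene
#' transcript boundary is at least `margin` bp.
#'
#' @param enhancers Enhancer data.frame (`chrom`, `start`, `end`, ...).
#' @param genes Gene-model data.frame.
#' @param margin Minimum gap to any gene transcript start/end (bp).
#' @return The qualifying subset of `enhancers`.
#' @export
filter_intergenic_enhancers <- function(enhancers, genes, margin = 3000) {
  if (nrow(enhancers) == 0) return(enhancers)
  gap <- distance_to_nearest_gene_boundary(enhancers, genes)
  enhancers[gap >= margin, , drop = FALSE]
}

#' Remove contigs overlapping any gene
#'
#' @param contigs Contig data.frame.
#' @param genes Gene-model data.frame.
#' @return Contigs whose span shares no base with any gene transcript span.
#' @export
filter_gene_overlapping_contigs <- function(contigs, genes) {
  if (nrow(contigs) == 0) return(contigs)
  gi <- genomic_intervals(genes$chrom, genes$start, genes$end)
  contigs[!overlaps_any(contigs, gi), , drop = FALSE]
}

#' Call enhancer transcription states
#'
#' An enhancer is transcribing (state `eRNA`) when some contig's 5' start
#' falls in the half-open window `[start - window, end + window)`; the
#' qualifying contig with the highest BPKM is attached as the eRNA. Inputs
#' are expected to be pre-filtered ([filter_intergenic_enhancers()],
#' [filter_gene_overlapping_contigs()]); enhancers and contigs are matched
#' within each tissue when both carry a `tissue` column.
#'
#' @param enhancers Enhancer data.frame (`enhancer_id`, `chrom`, `start`,
#'   `end`, optionally `tissue`, `gene_id`).
#' @param contigs Contig data.frame (`chrom`, `start`, `end`, `strand`,
#'   `name`, `score` = BPKM, optionally `tissue`).
#' @param window Window half-width around the enhancer locus (bp).
#' @return A calls data.frame: one row per enhancer with `state` and the
#'   attached contig's `contig_name`, `contig_start`, `contig_end`,
#'   `contig_strand`, `contig_bpkm` (NA for `no-eRNA`), plus `n_qualifying`.
#' @export
call_erna_states <- function(enhancers, contigs, window = 3000) {
  has_tissue <- "tissue" %in% names(enhancers) && "tissue" %in% names(contigs)
  n <- nrow(enhancers)
  out <- enhancers
  out$state <- rep("no-eRNA", n)
  out$contig_name <- NA_character_
  out$contig_start <- NA_real_; out$contig_end <- NA_real_
  out$contig_strand <- NA_character_; out$contig_bpkm <- NA_real_
  out$n_qualifying <- 0L
  if (n == 0 || nrow(contigs) == 0) return(out)
  s5 <- five_prime_start(contigs)
  groups <- if (has_tissue)
    split(seq_len(n), enhancers$tissue) else list(all = seq_len(n))
  for (g in groups) {
    ci <- if (has_tissue)
      which(contigs$tissue == enhancers$tissue[g[1]]) else seq_len(nrow(contigs))
    if (length(ci) == 0) next
    for (i in g) {
      qual <- ci[contigs$chrom[ci] == enhancers$chrom[i] &
                   s5[ci] >= enhancers$start[i] - window &
                   s5[ci] < enhancers$end[i] + window]
      out$n_qualifying[i] <- length(qual)
      if (length(qual) > 0) {
        best <- qual[which.max(contigs$score[qual])]
        out$state[i] <- "eRNA"
        out$contig_name[i] <- contigs$name[best]
        out$contig_start[i] <- contigs$start[best]
        out$contig_end[i] <- contigs$end[best]
        out$contig_strand[i] <- contigs$strand[best]
        out$contig_bpkm[i] <- contigs$score[best]
      }
    }
  }
  out
}

#' Per-tissue state proportions
#'
#' @param calls Calls data.frame from [call_erna_states()].
#' @return data.frame with per-tissue `n_eRNA`, `n_no_eRNA` and
#'   `fraction_transcribing`.
#' @export
state_proportions <- function(calls) {
  tissues <- if ("tissue" %in% names(calls)) calls$tissue else "all"
  tab <- table(tissues, factor(calls$state, levels = c("eRNA", "no-eRNA")))
  data.frame(tissue = rownames(tab),
             n_eRNA = as.integer(tab[, "eRNA"]),
             n_no_eRNA = as.integer(tab[, "no-eRNA"]),
             fraction_transcribing = as.numeric(tab[, "eRNA"] / rowSums(tab)),
             stringsAsFactors = FALSE, row.names = NULL)
}
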