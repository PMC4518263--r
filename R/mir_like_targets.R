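# Confirm miRNA-like regions inside eRNAs, build promoter and 3'UTR regions,
# scan for canonical seed sites (8mer / 7mer-m8 / 7mer-A1) and for
# complementarity-scored alignment sites on both strands, apply the
# promoter-unique filter, and compute the shuffle-bootstrap p-value.

# all 0-based start offsets of fixed pattern in subject (both DNA-normalized)
find_all <- function(subject, pattern) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

#' Confirm a miRNA-like region inside an eRNA sequence
#'
#' Searches for the leftmost exact (100%-identity) occurrence of the family's
#' mature sequence or of its 7-nt seed within the eRNA, in both orientations
#' (U and T interchangeable).
#'
#' @param erna_seq eRNA sequence (non-empty).
#' @param family One seed-family row (`seed7`, `mature`).
#' @return NULL when absent, otherwise a list with `position` (0-based),
#'   `orientation` (`sense`/`antisense`), `matched` (`mature`/`seed`) and
#'   `length`.
#' @export
confirm_mir_region <- function(erna_seq, family) {
  s <- normalize_dna(erna_seq)
  pats <- list(mature = normalize_dna(family$mature[1]),
               seed = normalize_dna(family$seed7[1]))
  best <- NULL
  for (what in names(pats)) {
    for (orient in c("sense", "antisense")) {
      pat <- if (orient == "sense") pats[[what]]
             else reverse_complement(pats[[what]])
      h <- find_all(s, pat)
      if (length(h) > 0) {
        cand <- list(position = h[1], orientation = orient, matched = what,
                     length = nchar(pat))
        if (is.null(best) || cand$position < best$position ||
            (cand$position == best$position && what == "mature" &&
             best$matched == "seed"))
          best <- cand
      }
    }
  }
  best
}

#' Promoter region of a gene
#'
#' The strand-aware window from 1000 bp upstream to 200 bp downstream of the
#' gene start site, with any segment overlapping another gene's transcript
#' span removed; may be empty.
#'
#' @param gene One gene-model row.
#' @param all_genes Gene-model data.frame (the gene itself is excluded from
#'   the cutters).
#' @return Interval data.frame (0 or more rows).
#' @export
build_promoter <- function(gene, all_genes) {
  if (gene$strand[1] == "+") {
    lo <- max(0, gene$start[1] - 1000); hi <- gene$start[1] + 200
  } else {
    lo <- max(0, gene$end[1] - 200); hi <- gene$end[1] + 1000
  }
  region <- genomic_intervals(gene$chrom[1], lo, hi, gene$strand[1])
  others <- all_genes[all_genes$gene_id != gene$gene_id[1] &
                        all_genes$chrom == gene$chrom[1], , drop = FALSE]
  cutters <- if (nrow(others) > 0)
    genomic_intervals(others$chrom, others$start, others$end)
  else genomic_intervals("x", 0, 1)[0, ]
  subtract_intervals(region, cutters)
}

#' 3' untranslated region of a coding gene
#'
#' From the end of the coding region to the transcript end (strand-aware);
#' NULL for noncoding genes or when the coding region reaches the gene end.
#'
#' @param gene One gene-model row (`cds_end` may be NA).
#' @return A single-row interval data.frame, or NULL.
#' @export
build_utr3 <- function(gene) {
  ce <- gene$cds_end[1]
  if (is.na(ce)) return(NULL)
  if (gene$strand[1] == "+") {
    if (ce >= gene$end[1]) return(NULL)
    genomic_intervals(gene$chrom[1], ce, gene$end[1], "+")
  } else {
    if (ce <= gene$start[1]) return(NULL)
    genomic_intervals(gene$chrom[1], gene$start[1], ce, "-")
  }
}

# classify seed-complement occurrences on one strand of a target sequence
scan_seed_one_strand <- function(seq, seed7, strand_label, L) {
  rc7 <- reverse_complement(seed7)          # complement of positions 8..2
  rc6 <- reverse_complement(substr(seed7, 1, 6))  # complement of 7..2
  m8c <- substr(rc7, 1, 1)                  # complement of seed position 8
  out <- NULL
  for (pos in find_all(seq, rc7)) {         # full 7-nt seed match
    nxt <- if (pos + 7 < nchar(seq)) substr(seq, pos + 8, pos + 8) else ""
    type <- if (nxt == "A") "8mer" else "7mer-m8"
    out <- rbind(out, data.frame(position = pos, site_type = type,
                                 strand_scanned = strand_label,
                                 stringsAsFactors = FALSE))
  }
  for (pos in find_all(seq, paste0(rc6, "A"))) {  # positions 2-7 match + A1
    prev <- if (pos > 0) substr(seq, pos, pos) else ""
    if (prev == m8c) next                    # part of an 8mer, already typed
    out <- rbind(out, data.frame(position = pos, site_type = "7mer-A1",
                                 strand_scanned = strand_label,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Scan a target sequence for canonical miRNA seed sites
#'
#' Finds all occurrences of the reverse complement of the 7-nt seed (mature
#' positions 2-8) and types them by the TargetScan nomenclature: `8mer`
#' (seed match plus A immediately 3' in target coordinates), `7mer-m8` (seed
#' match, no A), `7mer-A1` (match to positions 2-7 plus A, with no position-8
#' match). The antisense scan applies the same rule to the reverse complement
#' of the target with positions mapped back to target coordinates; duplicate
#' (position, type, strand) rows are collapsed.
#'
#' @param region_seq Target sequence (>= 8 nt).
#' @param family One seed-family row (`seed7`).
#' @param scan_antisense Also scan the antisense orientation.
#' @return data.frame with `position` (0-based offset of the matched
#'   substring in the input sequence), `site_type`, `strand_scanned`.
#' @export
seed_site_scan <- function(region_seq, family, scan_antisense = TRUE) {
  s <- normalize_dna(region_seq)
  stopifnot(nchar(s) >= 8)
  seed7 <- normalize_dna(family$seed7[1])
  L <- nchar(s)
  out <- scan_seed_one_strand(s, seed7, "sense", L)
  if (scan_antisense) {
    anti <- scan_seed_one_strand(reverse_complement(s), seed7, "antisense", L)
    if (!is.null(anti)) {
      site_len <- ifelse(anti$site_type == "8mer", 8L, 7L)
      anti$position <- L - (anti$position + site_len)
      out <- rbind(out, anti)
    }
  }
  if (is.null(out))
    return(data.frame(position = integer(0), site_type = character(0),
                      strand_scanned = character(0)))
  out <- out[!duplicated(out[c("position", "site_type", "strand_scanned")]), ,
             drop = FALSE]
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-position pair score: +5 Watson-Crick, +1 G:U(T) wobble, -3 mismatch
pair_score <- function(mir_base, tgt_base) {
  wc <- (mir_base == "A" & tgt_base == "T") |
        (mir_base == "T" & tgt_base == "A") |
        (mir_base == "C" & tgt_base == "G") |
        (mir_base == "G" & tgt_base == "C")
  wobble <- (mir_base == "G" & tgt_base == "T") |
            (mir_base == "T" & tgt_base == "G")
  ifelse(wc, 5, ifelse(wobble, 1, -3))
}

#' Complementarity-scored alignment scan
#'
#' Slides the mature miRNA (3' to 5') along each window of the target
#' sequence without gaps; per aligned position +5 for a Watson-Crick pair,
#' +1 for a G:U wobble, -3 for a mismatch, with miRNA positions 2-8 weighted
#' x2; windows scoring at least `threshold` are reported. Both strands are
#' scanned; antisense positions are mapped back to target coordinates. A
#' perfect 22-nt complement scores 145.
#'
#' @param region_seq Target sequence.
#' @param mature Mature miRNA sequence (>= 15 nt).
#' @param threshold Minimum reported score.
#' @param scan_antisense Also scan the antisense orientation.
#' @return data.frame with `position` (0-based window start), `score`,
#'   `strand_scanned`.
#' @export
alignment_site_scan <- function(region_seq, mature, threshold = 80,
                                scan_antisense = TRUE) {
  s <- normalize_dna(region_seq)
  m <- normalize_dna(mature)
  stopifnot(nchar(m) >= 15)
  L <- nchar(s); n <- nchar(m)
  scan_one <- function(seq, strand_label) {
    if (L < n) return(NULL)
    seq_chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    mir_chars <- strsplit(m, "", fixed = TRUE)[[1]]
    # target window position k (1-based) pairs miRNA position n + 1 - k
    mir_aln <- rev(mir_chars)
    w <- ifelse(rev(seq_len(n)) >= 2 & rev(seq_len(n)) <= 8, 2, 1)
    n_win <- L - n + 1
    scores <- numeric(n_win)
    for (k in seq_len(n)) {
      tgt <- seq_chars[(k):(k + n_win - 1)]
      scores <- scores + w[k] * pair_score(mir_aln[k], tgt)
    }
    hit <- which(scores >= threshold)
    if (length(hit) == 0) return(NULL)
    data.frame(position = hit - 1L, score = scores[hit],
               strand_scanned = strand_label, stringsAsFactors = FALSE)
  }
  out <- scan_one(s, "sense")
  if (scan_antisense) {
    anti <- scan_one(reverse_complement(s), "antisense")
    if (!is.null(anti)) {
      anti$position <- L - (anti$position + n)
      out <- rbind(out, anti)
    }
  }
  if (is.null(out))
    return(data.frame(position = integer(0), score = numeric(0),
                      strand_scanned = character(0)))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter-unique filter
#'
#' A (eRNA, gene, family) triple is retained iff it has at least one promoter
#' site and no 3'UTR site.
#'
#' @param promoter_sites,utr3_sites Site data.frames for the same triple
#'   (possibly 0 rows or NULL).
#' @return Logical: retain the triple.
#' @export
promoter_unique_filter <- function(promoter_sites, utr3_sites) {
  n_prom <- if (is.null(promoter_sites)) 0L else nrow(promoter_sites)
  n_utr <- if (is.null(utr3_sites)) 0L else nrow(utr3_sites)
  n_prom > 0 && n_utr == 0
}

#' miRNA-like promoter target discovery for one eRNA
#'
#' The full identification procedure: confirm which families have an exact
#' miRNA-like region inside the eRNA sequence, scan each confirmed family
#' against the promoter and 3'UTR sequences of the candidate target genes
#' (seed sites by default, complementarity alignment with `mode =
#' "alignment"`; both strands), and retain (gene, family) pairs with a
#' promoter site but no 3'UTR site.
#'
#' @param erna_seq The eRNA sequence.
#' @param families Seed-family data.frame.
#' @param promoter_seqs Named character vector of promoter sequences for the
#'   candidate target genes.
#' @param utr3_seqs Named character vector of 3'UTR sequences (genes absent
#'   from it are treated as having no 3'UTR site).
#' @param mode `"seed"` or `"alignment"`.
#' @param threshold Alignment score threshold (alignment mode).
#' @return data.frame of retained matches: `gene_id`, `family_id`,
#'   `n_promoter_sites`, plus the confirmation offset within the eRNA.
#' @export
mir_like_targets <- function(erna_seq, families, promoter_seqs,
                             utr3_seqs = character(0), mode = c("seed",
                                                                "alignment"),
                             threshold = 80) {
  mode <- match.arg(mode)
  out <- NULL
  for (fi in seq_len(nrow(families))) {
    fam <- families[fi, , drop = FALSE]
    conf <- confirm_mir_region(erna_seq, fam)
    if (is.null(conf)) next
    for (g in names(promoter_seqs)) {
      scan <- function(seqv) {
        if (is.na(seqv) || nchar(seqv) < 8) return(NULL)
        if (mode == "seed") seed_site_scan(seqv, fam)
        else alignment_site_scan(seqv, fam$mature, threshold)
      }
      prom <- scan(promoter_seqs[[g]])
      utr <- if (g %in% names(utr3_seqs)) scan(utr3_seqs[[g]]) else NULL
      if (promoter_unique_filter(prom, utr)) {
        out <- rbind(out, data.frame(
          gene_id = g, family_id = fam$family_id,
          n_promoter_sites = nrow(prom), erna_offset = conf$position,
          erna_orientation = conf$orientation, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(gene_id = character(0), family_id = character(0),
                      n_promoter_sites = integer(0), erna_offset = integer(0),
                      erna_orientation = character(0))
  out
}

# uniform random permutation of a sequence's characters, or a
# dinucleotide-preserving shuffle (Altschul-Erickson): a random Eulerian walk
# on the first-order transition multigraph, made valid by reserving, for each
# vertex other than the terminal one, a "last edge" chosen so the last edges
# form an arborescence toward the terminal character
shuffle_sequence <- function(seq, dinucleotide = FALSE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!dinucleotide) return(paste(sample(chars), collapse = ""))
  n <- length(chars)
  if (n < 3) return(paste(sample(chars), collapse = ""))
  first <- chars[1]; last <- chars[n]
  succ <- split(chars[2:n], chars[1:(n - 1)])
  verts <- names(succ)
  repeat {
    last_edge <- vapply(verts, function(v)
      succ[[v]][sample.int(length(succ[[v]]), 1)], character(1))
    # every non-terminal vertex must reach `last` via selected edges
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v; seen <- character(0)
      while (cur != last && !cur %in% seen) {
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
        if (is.null(cur) || is.na(cur)) break
      }
      if (!identical(cur, last)) { ok <- FALSE; break }
    }
    if (ok) break
  }
  order_edges <- function(v) {
    e <- succ[[v]]
    if (v == last) return(sample(e))
    drop1 <- match(last_edge[[v]], e)
    rest <- e[-drop1]
    c(if (length(rest) > 0) sample(rest), last_edge[[v]])
  }
  queue <- lapply(stats::setNames(verts, verts), order_edges)
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n); out[1] <- first
  cur <- first
  for (i in 2:n) {
    nxt <- queue[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Shuffle-bootstrap p-value for a miRNA-like target statistic
#'
#' Shuffles the eRNA sequence `B` times (uniform character permutation by
#' default), re-runs the full identification procedure on each shuffle, and
#' returns the add-one bootstrap p-value
#' `(1 + #\{shuffles with statistic >= observed\}) / (1 + B)`.
#'
#' @param erna_seq The eRNA sequence.
#' @param scan_fn Function mapping a sequence to the test statistic (e.g. the
#'   number of retained promoter-unique matches from [mir_like_targets()]).
#' @param B Number of shuffles.
#' @param rng_seed Integer seed.
#' @param dinucleotide Use a dinucleotide-preserving shuffle.
#' @return List with `p`, `observed`, `shuffled` (the B statistics).
#' @export
shuffle_bootstrap <- function(erna_seq, scan_fn, B = 100, rng_seed = 1L,
                              dinucleotide = FALSE) {
  stopifnot(B >= 1)
  observed <- scan_fn(erna_seq)
  with_seed(rng_seed, {
    stats_b <- vapply(seq_len(B), function(b)
      scan_fn(shuffle_sequence(erna_seq, dinucleotide)), numeric(1))
    list(p = (1 + sum(stats_b >= observed)) / (1 + B),
         observed = observed, shuffled = stats_b)
  })
}
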