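# Coordinate conventions, interval arithmetic, sequence utilities and
# readers/writers for the tabular/sequence formats the pipeline touches.
# All internal coordinates are 0-based half-open (BED-native).

#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames in BED-native coordinates: `start` is
#' 0-based inclusive, `end` is 0-based exclusive, `strand` is one of
#' `"+"`, `"-"` or `"*"` (unstranded).
#'
#' @param chrom Chromosome names (non-empty character).
#' @param start 0-based inclusive start positions (`start >= 0`).
#' @param end 0-based exclusive end positions (`end > start`).
#' @param strand Strand per interval; recycled.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(chrom) | !nzchar(chrom)))
    stop("chrom must be non-empty")
  if (any(!is.finite(start)) || any(!is.finite(end)))
    stop("start/end must be finite")
  if (any(start < 0))
    stop("start must be >= 0")
  if (any(end <= start))
    stop("end must be > start")
  if (any(!strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Read a BED3/BED6 file
#'
#' @param path Path to a BED file (>= 3 whitespace-separated columns).
#' @param stranded If `TRUE`, strand is read from column 6.
#' @return Interval data.frame (see [genomic_intervals()]); when the file has
#'   a name column (BED4+) it is kept as `name`, a score column as `score`.
#' @export
read_bed <- function(path, stranded = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(genomic_intervals(character(), numeric(), numeric())[0, ])
  fields <- strsplit(lines, "[ \t]+")
  ncol_min <- if (stranded) 6L else 3L
  out <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < ncol_min)
      stop(sprintf("BED parse error at line %d: expected >= %d columns, got %d",
                   i, ncol_min, length(f)))
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e))
      stop(sprintf("BED parse error at line %d: non-integer coordinates", i))
    if (e <= s)
      stop(sprintf("BED parse error at line %d: end <= start", i))
    if (s < 0)
      stop(sprintf("BED parse error at line %d: negative start", i))
    strand <- "*"
    if (stranded) {
      if (!f[6] %in% c("+", "-"))
        stop(sprintf("BED parse error at line %d: bad strand '%s'", i, f[6]))
      strand <- f[6]
    }
    out[[i]] <- list(chrom = f[1], start = s, end = e, strand = strand,
                     name = if (length(f) >= 4) f[4] else NA_character_,
                     score = if (length(f) >= 5)
                       suppressWarnings(as.numeric(f[5])) else NA_real_)
  }
  df <- do.call(rbind.data.frame, c(out, list(stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' Write intervals as BED
#'
#' Emits BED6 when a `strand` column is present and any strand is set
#' (otherwise BED3/BED4). Coordinates are written bit-exactly as integers so
#' that `read_bed()` round-trips.
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x) && !all(is.na(x$name))) x$name
          else sprintf("iv%d", seq_len(nrow(x)))
  score <- if ("score" %in% names(x) && !all(is.na(x$score))) x$score else 0
  stranded <- "strand" %in% names(x) && any(x$strand %in% c("+", "-"))
  lines <- if (stranded)
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
            as.integer(x$end), name, format(score, trim = TRUE), x$strand)
  else
    sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
            as.integer(x$end), name)
  writeLines(lines, path)
  invisible(path)
}

#' Pairwise interval overlap
#'
#' Half-open convention: abutting intervals do not overlap. Strand ignored.
#'
#' @param a,b Interval data.frames, recycled to a common length.
#' @return Logical vector.
#' @export
overlaps <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] &
    a$start[ai] < b$end[bi] & b$start[bi] < a$end[ai]
}

#' Does each query interval overlap any subject interval?
#'
#' @param query,subject Interval data.frames.
#' @return Logical vector along `query`.
#' @export
overlaps_any <- function(query, subject) {
  out <- logical(nrow(query))
  if (nrow(subject) == 0L || nrow(query) == 0L) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- subject$chrom == ch
    if (!any(si)) next
    ss <- subject$start[si]; se <- subject$end[si]
    # sort subjects by start; a query overlaps some subject iff any subject
    # with start < q.end has end > q.start
    o <- order(ss); ss <- ss[o]; se <- se[o]
    cummax_end <- cummax(se)
    idx <- findInterval(query$end[qi] - 0.5, ss)  # subjects with start < q.end
    hit <- idx > 0 & ifelse(idx > 0, cummax_end[pmax(idx, 1L)], -Inf) > query$start[qi]
    out[qi] <- hit
  }
  out
}

#' Distance to the nearest gene transcript boundary
#'
#' Minimum gap in bp between each interval and any gene transcript start/end
#' on the same chromosome; 0 when the interval overlaps a gene, `Inf` when the
#' chromosome carries no gene.
#'
#' @param iv Interval data.frame.
#' @param genes Gene-model data.frame (see [read_gene_models()]).
#' @return Numeric vector of gaps (bp), possibly `Inf`.
#' @export
distance_to_nearest_gene_boundary <- function(iv, genes) {
  out <- rep(Inf, nrow(iv))
  for (ch in unique(iv$chrom)) {
    qi <- which(iv$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    gi <- genomic_intervals(g$chrom, g$start, g$end)
    ov <- overlaps_any(iv[qi, , drop = FALSE], gi)
    # gap to a boundary point b from [s,e): 0 if s <= b <= e else min distance;
    # interval coordinates: last covered base is end-1, gap to a point b >= end
    # is b - end (half-open: region [e, b) separates them).
    bounds <- sort(c(g$start, g$end))
    gap <- vapply(qi, function(j) {
      s <- iv$start[j]; e <- iv$end[j]
      d <- ifelse(bounds < s, s - bounds, ifelse(bounds > e, bounds - e, 0))
      min(d)
    }, numeric(1))
    gap[ov] <- 0
    out[qi] <- gap
  }
  out
}

#' Subtract intervals from a region
#'
#' @param region A single-row interval data.frame (or list with chrom, start,
#'   end).
#' @param cutters Interval data.frame of regions to remove.
#' @return Ordered, disjoint sub-intervals of `region` not covered by any
#'   cutter (possibly zero rows). Base-conserving: the removed and retained
#'   parts partition the region.
#' @export
subtract_intervals <- function(region, cutters) {
  chrom <- region$chrom[1]; s <- region$start[1]; e <- region$end[1]
  strand <- if ("strand" %in% names(region)) region$strand[1] else "*"
  if (nrow(cutters) > 0) {
    cutters <- cutters[cutters$chrom == chrom &
                         cutters$start < e & cutters$end > s, , drop = FALSE]
  }
  if (nrow(cutters) == 0)
    return(genomic_intervals(chrom, s, e, strand))
  cs <- pmax(cutters$start, s); ce <- pmin(cutters$end, e)
  o <- order(cs); cs <- cs[o]; ce <- ce[o]
  # merge overlapping cutters
  ms <- cs[1]; me <- ce[1]; keep_s <- numeric(0); keep_e <- numeric(0)
  for (i in seq_along(cs)[-1]) {
    if (cs[i] <= me) me <- max(me, ce[i])
    else { keep_s <- c(keep_s, ms); keep_e <- c(keep_e, me); ms <- cs[i]; me <- ce[i] }
  }
  keep_s <- c(keep_s, ms); keep_e <- c(keep_e, me)
  out_s <- c(s, keep_e); out_e <- c(keep_s, e)
  ok <- out_e > out_s
  if (!any(ok))
    return(genomic_intervals(chrom, 0, 1, strand)[0, ])
  genomic_intervals(chrom, out_s[ok], out_e[ok], strand)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

#' Reverse complement of a nucleotide sequence
#'
#' Accepts DNA or RNA alphabet case-insensitively; U is treated as T, the
#' result is always DNA alphabet. Applying twice returns the (U- and
#' case-normalized) input.
#'
#' @param seq Character vector of sequences over \{A,C,G,T,U,N\}.
#' @return Reverse-complemented sequences (uppercase DNA).
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    up <- toupper(s)
    chars <- strsplit(up, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% names(COMPLEMENT))
    if (length(bad) > 0)
      stop(sprintf("invalid character '%s' at position %d", chars[bad[1]], bad[1]))
    paste(rev(unname(COMPLEMENT[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# normalize an RNA/DNA string to uppercase DNA
normalize_dna <- function(seq) gsub("U", "T", toupper(seq), fixed = TRUE)

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- normalize_dna(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read gene models
#'
#' Tab-separated with header: `gene_id`, `chrom`, `strand`, `tx_start`,
#' `tx_end`, `cds_end` (empty/NA for noncoding genes). Coordinates 0-based
#' half-open; `cds_end` is the bp coordinate of the end of the coding region
#' on the transcript's strand.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `cds_end`.
#' @export
read_gene_models <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  if (!all(need %in% names(x)))
    stop("gene model table must have columns: ", paste(need, collapse = ", "))
  g <- data.frame(gene_id = as.character(x$gene_id), chrom = as.character(x$chrom),
                  strand = as.character(x$strand),
                  start = as.numeric(x$tx_start), end = as.numeric(x$tx_end),
                  cds_end = if ("cds_end" %in% names(x))
                    suppressWarnings(as.numeric(x$cds_end)) else NA_real_,
                  stringsAsFactors = FALSE)
  if (any(!g$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(g$end <= g$start)) stop("gene tx_end must be > tx_start")
  bad <- !is.na(g$cds_end) & (g$cds_end < g$start | g$cds_end > g$end)
  if (any(bad)) stop("cds_end must lie within the transcript span")
  g
}

#' @rdname read_gene_models
#' @param genes Gene-model data.frame.
#' @export
write_gene_models <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand,
                    tx_start = as.integer(genes$start),
                    tx_end = as.integer(genes$end),
                    cds_end = ifelse(is.na(genes$cds_end), "",
                                     format(as.integer(genes$cds_end))))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an enhancer-target pairing table
#'
#' Tab-separated with header: `enhancer_id`, `chrom`, `start`, `end`,
#' `tissue`, `gene_id`. One row per (enhancer, target gene).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_enhancers <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("enhancer_id", "chrom", "start", "end", "tissue", "gene_id")
  if (!all(need %in% names(x)))
    stop("enhancer table must have columns: ", paste(need, collapse = ", "))
  x$start <- as.numeric(x$start); x$end <- as.numeric(x$end)
  if (any(x$end <= x$start)) stop("enhancer end must be > start")
  x[need]
}

#' @rdname read_enhancers
#' @param enhancers Enhancer data.frame.
#' @export
write_enhancers <- function(enhancers, path) {
  out <- enhancers[c("enhancer_id", "chrom", "start", "end", "tissue", "gene_id")]
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a BPKM expression table
#'
#' Long format, tab-separated with header: `region_id`, `tissue`, `bpkm`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_bpkm_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "tissue", "bpkm")
  if (!all(need %in% names(x)))
    stop("BPKM table must have columns: ", paste(need, collapse = ", "))
  x$bpkm <- as.numeric(x$bpkm)
  if (any(x$bpkm < 0)) stop("BPKM must be >= 0")
  x[need]
}

#' @rdname read_bpkm_table
#' @param bpkm BPKM data.frame.
#' @export
write_bpkm_table <- function(bpkm, path) {
  out <- bpkm[c("region_id", "tissue", "bpkm")]
  out$bpkm <- sprintf("%.10g", out$bpkm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA seed-family table
#'
#' Tab-separated with header: `family_id`, `seed7` (mature positions 2-8,
#' 7 nt), `mature` (full mature sequence). RNA or DNA alphabet accepted.
#'
#' @param path TSV path.
#' @return data.frame with DNA-normalized `seed7` and `mature`.
#' @export
read_seed_families <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "seed7", "mature")
  if (!all(need %in% names(x)))
    stop("seed-family table must have columns: ", paste(need, collapse = ", "))
  x$seed7 <- normalize_dna(x$seed7)
  x$mature <- normalize_dna(x$mature)
  if (any(nchar(x$seed7) != 7)) stop("seed7 must be 7 nt")
  x[need]
}

#' @rdname read_seed_families
#' @param families Seed-family data.frame.
#' @export
write_seed_families <- function(families, path) {
  utils::write.table(families[c("family_id", "seed7", "mature")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a ncRNA family-hit table
#'
#' Tab-separated with header: `query_id`, `family_id`, `family_class`
#' (`miRNA` or `other`), `score`; one row per retained (query, family) hit,
#' the dialect a thin importer can fill from covariance-model scan output.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_family_hits <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_id", "family_id", "family_class", "score")
  if (!all(need %in% names(x)))
    stop("family-hit table must have columns: ", paste(need, collapse = ", "))
  x[need]
}

#' @rdname read_family_hits
#' @param hits Family-hit data.frame.
#' @export
write_family_hits <- function(hits, path) {
  utils::write.table(hits[c("query_id", "family_id", "family_class", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# run code with a private RNG stream, restoring the caller's .Random.seed
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
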