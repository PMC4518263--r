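# Independent brute-force oracles and tiny instance generators used across
# the suite. Oracles deliberately avoid the package's code paths: per-base
# set arithmetic, naive substring enumeration, exhaustive rank enumeration.

# per-base overlap: do the two intervals share any covered base?
oracle_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1))) > 0
}

# per-base window membership: is any contig 5' start inside the enhancer
# window [start - w, end + w)?
oracle_state <- function(enh, contigs, window = 3000) {
  bases <- seq(enh$start - window, enh$end + window - 1)
  s5 <- ifelse(contigs$strand == "+", contigs$start, contigs$end - 1)
  hit <- contigs$chrom == enh$chrom & s5 %in% bases
  list(state = if (any(hit)) "eRNA" else "no-eRNA",
       best = if (any(hit)) contigs$name[which(hit)[which.max(contigs$score[hit])]]
              else NA_character_)
}

# from-scratch Pearson r and one-sided (greater) p via the t transform
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = stats::pt(t, n - 2, lower.tail = FALSE))
}

# from-scratch pooled two-proportion z
oracle_pooled_z <- function(k1, n1, k2, n2) {
  p <- (k1 + k2) / (n1 + n2)
  (k1 / n1 - k2 / n2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
}

# exhaustive one-sided rank-sum p: P(W >= observed) over all assignments
oracle_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(pooled), length(x))
  stats_all <- apply(combos, 2, function(ix) sum(r[ix]))
  mean(stats_all >= obs)
}

# naive complement map independent of the package's
ORC_COMP <- c(A = "T", C = "G", G = "C", T = "A")
oracle_revcomp <- function(s) {
  ch <- strsplit(s, "")[[1]]
  paste(rev(unname(ORC_COMP[ch])), collapse = "")
}

# naive seed-site enumeration on the sense strand of `seq`
oracle_seed_sites_sense <- function(seq, seed7) {
  L <- nchar(seq)
  rc7 <- oracle_revcomp(seed7)
  rc6 <- oracle_revcomp(substr(seed7, 1, 6))
  m8c <- unname(ORC_COMP[substr(seed7, 7, 7)])
  out <- NULL
  for (i in seq_len(L - 6)) {
    if (substr(seq, i, i + 6) == rc7) {
      nxt <- if (i + 7 <= L) substr(seq, i + 7, i + 7) else ""
      out <- rbind(out, data.frame(position = i - 1,
                                   site_type = if (nxt == "A") "8mer" else "7mer-m8"))
    }
  }
  for (i in seq_len(L - 6)) {
    if (substr(seq, i, i + 5) == rc6 && substr(seq, i + 6, i + 6) == "A") {
      prev <- if (i > 1) substr(seq, i - 1, i - 1) else ""
      if (prev != m8c)
        out <- rbind(out, data.frame(position = i - 1, site_type = "7mer-A1"))
    }
  }
  out
}

# naive all-windows ungapped complementarity scorer (sense strand)
oracle_alignment_sense <- function(seq, mature, threshold) {
  L <- nchar(seq); n <- nchar(mature)
  if (L < n) return(NULL)
  sc <- strsplit(seq, "")[[1]]; mc <- strsplit(mature, "")[[1]]
  out <- NULL
  for (w in 0:(L - n)) {
    total <- 0
    for (k in seq_len(n)) {
      mir_pos <- n + 1 - k               # window base k pairs miRNA pos n+1-k
      mb <- mc[mir_pos]; tb <- sc[w + k]
      s <- if (ORC_COMP[mb] == tb) 5
           else if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) 1
           else -3
      if (mir_pos >= 2 && mir_pos <= 8) s <- 2 * s
      total <- total + s
    }
    if (total >= threshold)
      out <- rbind(out, data.frame(position = w, score = total))
  }
  out
}

# exhaustive same-positioned-enhancer grouping oracle: per gene, connected
# components of the <=window midpoint graph (transitive closure), keep
# both-state components of maximum size
oracle_groups <- function(calls, window = 1000) {
  res <- list()
  for (gene in sort(unique(calls$gene_id))) {
    m <- calls[calls$gene_id == gene, , drop = FALSE]
    if (nrow(m) < 2) next
    mid <- (m$start + m$end) / 2
    adj <- abs(outer(mid, mid, "-")) <= window
    reach <- adj
    for (k in seq_len(nrow(m))) reach <- reach | (reach %*% reach) > 0
    comp <- rep(NA_integer_, nrow(m))
    cid <- 0
    for (i in seq_len(nrow(m))) {
      if (is.na(comp[i])) { cid <- cid + 1; comp[which(reach[i, ])] <- cid }
    }
    valid <- Filter(function(ix) length(ix) >= 2 &&
                      any(m$state[ix] == "eRNA") &&
                      any(m$state[ix] == "no-eRNA"),
                    split(seq_len(nrow(m)), comp))
    if (length(valid) == 0) next
    sizes <- vapply(valid, length, integer(1))
    for (ix in valid[sizes == max(sizes)])
      res[[length(res) + 1]] <- sort(m$enhancer_id[ix])
  }
  res
}

# random enhancer/contig instance on one chromosome (no genes)
random_call_instance <- function(seed, n_enh = 200, n_ctg = 100,
                                 span = 1e6) {
  set.seed(seed)
  es <- sort(sample.int(span, n_enh))
  el <- sample(200:1000, n_enh, replace = TRUE)
  cs <- sample.int(span, n_ctg)
  cl <- sample(100:2000, n_ctg, replace = TRUE)
  list(
    enhancers = data.frame(enhancer_id = sprintf("e%03d", seq_len(n_enh)),
                           chrom = "chr1", start = es, end = es + el,
                           stringsAsFactors = FALSE),
    contigs = data.frame(chrom = "chr1", start = cs, end = cs + cl,
                         name = sprintf("c%03d", seq_len(n_ctg)),
                         score = round(stats::runif(n_ctg), 6),
                         strand = sample(c("+", "-"), n_ctg, replace = TRUE),
                         stringsAsFactors = FALSE))
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# tiny gene set helper
tiny_genes <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], chrom = r[[2]], strand = r[[3]],
               start = as.numeric(r[[4]]), end = as.numeric(r[[5]]),
               cds_end = if (length(r) >= 6) as.numeric(r[[6]]) else NA_real_,
               stringsAsFactors = FALSE)))
}
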