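# Synthetic multi-tissue worlds with planted structure: gene models, enhancer
# maps shared across tissues, strand-aware RNA contigs, BPKM tables with a
# planted eRNA-target correlation and a planted state-dependent shift,
# promoter/3'UTR/eRNA sequences with planted seed sites, and ncRNA family-hit
# tables with planted enrichment. Every planted quantity is recorded in a
# truth component so downstream stages can be tested against ground truth.

#' Simulation configuration
#'
#' Defaults are the package's reference study conditions: 12 tissues, one
#' 8 Mb chromosome, 300 genes, 250 enhancer loci, 40% of enhancers
#' transcribing, planted BPKM correlation 0.6, planted state shift 0.5 on the
#' z-score scale, log-scale expression sd 0.3 (chosen so the BPKM-scale
#' Pearson correlation stays close to the latent one), half of the loci shared
#' across all tissues (midpoint jitter <= 250 bp), 200 ncRNA families hit at
#' background rate 0.02 with one miRNA-class family given +0.15 excess and one
#' other-class family +0.06.
#'
#' @param n_tissues Number of tissues.
#' @param chrom_length Chromosome length (bp).
#' @param n_genes Number of non-overlapping genes (>= 7 kb gaps).
#' @param n_enhancers Number of enhancer loci (at most `n_genes - 1`).
#' @param erna_fraction Probability a (locus, tissue) transcribes an eRNA.
#' @param rho Planted latent Pearson correlation between eRNA and target-gene
#'   log expression.
#' @param delta Planted mean shift, on the latent z-score scale, of target
#'   genes of transcribing enhancers.
#' @param sigma Log-scale expression standard deviation.
#' @param share_fraction Fraction of loci present (jittered) in every tissue;
#'   the rest appear in a single tissue.
#' @param seed_site_rate Per-eRNA probability of a planted miRNA-like region
#'   plus matching promoter seed site.
#' @param n_families Number of ncRNA families in the hit tables.
#' @param mirna_family_fraction Fraction of families in class `miRNA`.
#' @param base_hit_rate Per-query, per-family background hit probability.
#' @param family_enrichment Planted excess hit proportion for one designated
#'   miRNA-class family.
#' @param other_enrichment Planted excess for one other-class family (keeps
#'   the miRNA-vs-other class comparison defined).
#' @param n_seed_families Number of miRNA seed families in the seed table.
#' @param erna_seq_length Length (nt) of synthetic eRNA sequences.
#' @param rng_seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_tissues = 12, chrom_length = 8e6, n_genes = 300,
                       n_enhancers = 250, erna_fraction = 0.4, rho = 0.6,
                       delta = 0.5, sigma = 0.3, share_fraction = 0.5,
                       seed_site_rate = 0.5, n_families = 200,
                       mirna_family_fraction = 0.2, base_hit_rate = 0.02,
                       family_enrichment = 0.15, other_enrichment = 0.06,
                       n_seed_families = 10, erna_seq_length = 80,
                       rng_seed = 1L) {
  cfg <- list(n_tissues = n_tissues, chrom_length = chrom_length,
              n_genes = n_genes, n_enhancers = n_enhancers,
              erna_fraction = erna_fraction, rho = rho, delta = delta,
              sigma = sigma, share_fraction = share_fraction,
              seed_site_rate = seed_site_rate, n_families = n_families,
              mirna_family_fraction = mirna_family_fraction,
              base_hit_rate = base_hit_rate,
              family_enrichment = family_enrichment,
              other_enrichment = other_enrichment,
              n_seed_families = n_seed_families,
              erna_seq_length = erna_seq_length,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$erna_fraction >= 0, cfg$erna_fraction <= 1,
            cfg$rho > -1, cfg$rho < 1, cfg$delta >= 0, cfg$sigma > 0,
            cfg$n_enhancers <= cfg$n_genes - 1, cfg$n_tissues >= 1)
  class(cfg) <- "sim_config"
  cfg
}

# place n non-overlapping genes with inter-gene gaps >= 15 kb, wide enough
# for an enhancer plus its 3 kb margins and 3 kb of flank bins on both sides
place_genes <- function(cfg) {
  lens <- round(stats::runif(cfg$n_genes, 2000, 8000))
  gaps <- round(15000 + stats::rexp(cfg$n_genes + 1, 1 / 3000))
  total <- sum(lens) + sum(gaps)
  if (total > cfg$chrom_length)
    stop("infeasible packing: ", cfg$n_genes, " genes need ", total,
         " bp but chrom_length is ", cfg$chrom_length)
  starts <- cumsum(gaps[seq_len(cfg$n_genes)]) +
    cumsum(c(0, lens[-cfg$n_genes]))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  cds_frac <- ifelse(strand == "+", 0.7, 0.3)
  cds_end <- starts + round(cds_frac * lens)
  cds_end[sample.int(cfg$n_genes, max(1, round(0.1 * cfg$n_genes)))] <- NA
  data.frame(gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
             chrom = "chrS", strand = strand,
             start = starts, end = starts + lens, cds_end = cds_end,
             stringsAsFactors = FALSE)
}

# mixture moments of exp(sigma * (Z + delta * S)), S ~ Bern(f): used to
# standardize planted expression onto the measured z-score scale
lognormal_mixture_moments <- function(sigma, delta, f) {
  m0 <- exp(sigma^2 / 2); m1 <- exp(sigma * delta) * m0
  v0 <- exp(sigma^2) * (exp(sigma^2) - 1); v1 <- exp(2 * sigma * delta) * v0
  mu <- (1 - f) * m0 + f * m1
  s2 <- (1 - f) * v0 + f * v1 + (1 - f) * (m0 - mu)^2 + f * (m1 - mu)^2
  list(mean = mu, sd = sqrt(s2), shift = (m1 - m0) / sqrt(s2))
}

random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  bytes <- charToRaw("ACGT")[sample.int(4, n * len, replace = TRUE)]
  vapply(seq_len(n), function(i)
    rawToChar(bytes[((i - 1) * len + 1):(i * len)]), character(1))
}

#' Generate a synthetic multi-tissue world
#'
#' Builds the full input bundle for the pipeline: gene models, per-tissue
#' enhancer maps (a configurable fraction of loci shared across tissues within
#' a 1000 bp window, same target gene), strand-aware RNA contigs whose 5'
#' starts respect the planted transcription states, a BPKM table in which eRNA
#' and target-gene expression are correlated at `rho` on the log scale and
#' target genes of transcribing enhancers are shifted by `delta` latent
#' z-units, background-region expression independent of everything, miRNA seed
#' families plus eRNA/promoter/3'UTR sequences with planted seed sites, and
#' family-hit tables with planted enrichment. The `truth` component records
#' every planted quantity.
#'
#' @param config A [sim_config()].
#' @return A list of class `erna_world` with components `config`, `genes`,
#'   `enhancers`, `contigs`, `bpkm`, `chrom_sizes`, `seed_families`,
#'   `sequences` (`erna`, `promoter`, `utr3`), `family_hits` (`real`,
#'   `control`, `families`, `n_real`, `n_control`) and `truth`.
#' @export
generate_world <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, {
    genes <- place_genes(config)
    tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))

    ## ---- enhancer loci in inter-gene gaps, one locus per gap ----
    n_gaps <- config$n_genes - 1
    gap_idx <- sort(sample.int(n_gaps, config$n_enhancers))
    gap_lo <- genes$end[gap_idx]          # left gene end
    gap_hi <- genes$start[gap_idx + 1]    # right gene start
    enh_len <- round(stats::runif(config$n_enhancers, 200, 1000))
    # keep 250 bp of jitter room inside the 3 kb margins on both sides
    base_start <- round(stats::runif(config$n_enhancers,
                                     gap_lo + 3250, gap_hi - 3250 - enh_len))
    locus_id <- sprintf("L%03d", seq_len(config$n_enhancers))
    target_gene <- genes$gene_id[gap_idx]  # left neighbour, unique per locus
    shared <- stats::runif(config$n_enhancers) < config$share_fraction

    n_rep <- ifelse(shared, config$n_tissues, 1L)
    li <- rep(seq_len(config$n_enhancers), n_rep)
    tiss <- unlist(lapply(seq_len(config$n_enhancers), function(i)
      if (shared[i]) tissues else sample(tissues, 1)), use.names = FALSE)
    jit <- ifelse(shared[li], round(stats::runif(length(li), -250, 250)), 0)
    enhancers <- data.frame(
      enhancer_id = sprintf("%s_%s", locus_id[li], tiss),
      locus_id = locus_id[li], chrom = "chrS",
      start = base_start[li] + jit, end = base_start[li] + jit + enh_len[li],
      tissue = tiss, gene_id = target_gene[li], gap_lo = gap_lo[li],
      gap_hi = gap_hi[li], stringsAsFactors = FALSE)

    ## ---- planted states and expression latents ----
    enhancers$state <- ifelse(stats::runif(nrow(enhancers)) < config$erna_fraction,
                              "eRNA", "no-eRNA")
    tr <- enhancers$state == "eRNA"
    n_tr <- sum(tr)
    eps <- stats::rnorm(n_tr)                       # eRNA latent
    g_lat <- config$rho * eps +
      sqrt(1 - config$rho^2) * stats::rnorm(n_tr) + config$delta

    mu_e <- log(5); mu_g <- log(10); mu_f <- log(3)
    erna_bpkm <- exp(mu_e + config$sigma * eps)

    # gene BPKM for every (gene, tissue): baseline N(0,1) latent, overridden
    # for target genes of transcribing enhancers by the correlated latent
    gene_grid <- expand.grid(gene_id = genes$gene_id, tissue = tissues,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gene_lat <- stats::rnorm(nrow(gene_grid))
    key <- paste(gene_grid$gene_id, gene_grid$tissue)
    tr_key <- paste(enhancers$gene_id[tr], enhancers$tissue[tr])
    gene_lat[match(tr_key, key)] <- g_lat
    gene_bpkm <- data.frame(region_id = gene_grid$gene_id,
                            tissue = gene_grid$tissue,
                            bpkm = exp(mu_g + config$sigma * gene_lat),
                            stringsAsFactors = FALSE)

    ## ---- contigs for transcribing enhancers ----
    ctg_rows <- NULL
    if (n_tr > 0) {
      es <- enhancers$start[tr]; ee <- enhancers$end[tr]
      lo <- enhancers$gap_lo[tr]; hi <- enhancers$gap_hi[tr]
      s5 <- floor(stats::runif(n_tr, es - 3000, ee + 3000))
      len <- pmin(pmax(round(stats::rlnorm(n_tr, log(500), 0.5)), 50), 3000)
      strand <- sample(c("+", "-"), n_tr, replace = TRUE)
      cs <- ifelse(strand == "+", s5, pmax(lo, s5 - len + 1))
      ce <- ifelse(strand == "+", pmin(s5 + len, hi), s5 + 1)
      ctg_rows <- data.frame(
        chrom = "chrS", start = cs, end = ce,
        name = sprintf("ctg_%s", enhancers$enhancer_id[tr]),
        score = erna_bpkm, strand = strand, tissue = enhancers$tissue[tr],
        stringsAsFactors = FALSE)
    }
    # decoy contigs with 5' starts outside every enhancer window of their
    # tissue (and outside gene bodies)
    n_dec <- round(0.2 * config$n_enhancers)
    dec_rows <- vector("list", length(tissues))
    for (ti in seq_along(tissues)) {
      t <- tissues[ti]
      et <- enhancers[enhancers$tissue == t, , drop = FALSE]
      # batch rejection sampling of 5' starts outside every enhancer window
      kept5 <- numeric(0)
      for (round_i in 1:10) {
        need <- n_dec - length(kept5)
        if (need <= 0) break
        gi <- sample.int(n_gaps, 3 * need, replace = TRUE)
        s5 <- floor(genes$end[gi] +
                      stats::runif(3 * need) * (genes$start[gi + 1] - genes$end[gi]))
        in_win <- vapply(s5, function(p)
          any(et$start - 3000 <= p & p < et$end + 3000), logical(1))
        ok <- which(!in_win)
        take <- utils::head(ok, need)
        kept5 <- c(kept5, s5[take])
        gi_kept <- if (round_i == 1) gi[take] else c(gi_kept, gi[take])
      }
      m <- length(kept5)
      if (m == 0) { dec_rows[[ti]] <- NULL; next }
      len <- pmin(pmax(round(stats::rlnorm(m, log(500), 0.5)), 50), 3000)
      strand <- sample(c("+", "-"), m, replace = TRUE)
      glo <- genes$end[gi_kept]; ghi <- genes$start[gi_kept + 1]
      dec_rows[[ti]] <- data.frame(
        chrom = "chrS",
        start = ifelse(strand == "+", kept5, pmax(glo, kept5 - len + 1)),
        end = ifelse(strand == "+", pmin(kept5 + len, ghi), kept5 + 1),
        name = sprintf("dec_%s_%04d", t, seq_len(m)),
        score = exp(log(2) + config$sigma * stats::rnorm(m)),
        strand = strand, tissue = t, stringsAsFactors = FALSE)
    }
    contigs <- rbind(ctg_rows, do.call(rbind, dec_rows))
    rownames(contigs) <- NULL

    ## ---- background-region BPKM (independent of everything planted) ----
    bg_rows <- list(gene_bpkm,
                    data.frame(region_id = contigs$name, tissue = contigs$tissue,
                               bpkm = contigs$score, stringsAsFactors = FALSE))
    if (n_tr > 0) {
      tr_idx <- which(tr)
      fb <- flank_bins_all(enhancers$enhancer_id[tr_idx], "chrS",
                           enhancers$start[tr_idx], enhancers$end[tr_idx],
                           ctg_rows$start, ctg_rows$end, 3000, genes)
      ids <- c(paste0(fb$enhancer_id, ":flank_", fb$side, "_", fb$bin),
               paste0(enhancers$enhancer_id[tr_idx], ":gene_upstream"),
               paste0(enhancers$enhancer_id[tr_idx], ":random_intergenic"))
      tiss <- c(enhancers$tissue[tr_idx][match(fb$enhancer_id,
                                               enhancers$enhancer_id[tr_idx])],
                rep(enhancers$tissue[tr_idx], 2))
      bg_rows[[length(bg_rows) + 1]] <- data.frame(
        region_id = ids, tissue = tiss,
        bpkm = exp(mu_f + config$sigma * stats::rnorm(length(ids))),
        stringsAsFactors = FALSE)
    }
    bpkm <- do.call(rbind, bg_rows)
    rownames(bpkm) <- NULL

    ## ---- seed families and sequences with planted miRNA-like structure ----
    fam <- data.frame(
      family_id = sprintf("miR-f%02d", seq_len(config$n_seed_families)),
      seed7 = random_dna(config$n_seed_families, 7),
      mature = NA_character_, stringsAsFactors = FALSE)
    fam$mature <- paste0(random_dna(config$n_seed_families, 1), fam$seed7,
                         random_dna(config$n_seed_families, 14))

    erna_names <- if (n_tr > 0) ctg_rows$name else character(0)
    erna_seqs <- stats::setNames(random_dna(n_tr, config$erna_seq_length),
                                 erna_names)
    promoter_seqs <- stats::setNames(random_dna(config$n_genes, 1200),
                                     genes$gene_id)
    utr3_seqs <- stats::setNames(random_dna(config$n_genes, 1000),
                                 genes$gene_id)

    planted_mir <- NULL
    if (n_tr > 0) {
      pick <- which(stats::runif(n_tr) < config$seed_site_rate)
      for (j in pick) {
        fi <- sample.int(nrow(fam), 1)
        mat <- fam$mature[fi]
        pos <- sample.int(config$erna_seq_length - nchar(mat) + 1, 1)
        substr(erna_seqs[j], pos, pos + nchar(mat) - 1) <- mat
        gid <- enhancers$gene_id[which(tr)[j]]
        site <- paste0(reverse_complement(fam$seed7[fi]), "A")  # 8mer
        ppos <- sample.int(nchar(promoter_seqs[gid]) - 8 + 1, 1)
        substr(promoter_seqs[gid], ppos, ppos + 7) <- site
        planted_mir <- rbind(planted_mir, data.frame(
          erna = erna_names[j], gene_id = gid, family_id = fam$family_id[fi],
          erna_pos = pos, promoter_pos = ppos - 1, site_type = "8mer",
          stringsAsFactors = FALSE))
      }
    }

    ## ---- family-hit tables with planted enrichment ----
    fh <- generate_family_hits(
      n_real = max(n_tr, 1), n_control = max(n_tr, 1),
      n_families = config$n_families,
      mirna_family_fraction = config$mirna_family_fraction,
      base_rate = config$base_hit_rate,
      mirna_excess = config$family_enrichment,
      other_excess = config$other_enrichment,
      rng_seed = sample.int(2^30, 1),
      query_ids = if (n_tr > 0) erna_names else "q1")

    mm <- lognormal_mixture_moments(config$sigma, config$delta,
                                    config$erna_fraction)
    truth <- list(
      config = unclass(config),
      states = enhancers[c("enhancer_id", "locus_id", "tissue", "state",
                           "gene_id")],
      shared_loci = locus_id[shared],
      latent_correlation = if (n_tr > 2) stats::cor(eps, g_lat) else NA_real_,
      expected_bpkm_correlation = (exp(config$rho * config$sigma^2) - 1) /
        (exp(config$sigma^2) - 1),
      expected_measured_shift = mm$shift,
      planted_mir_sites = planted_mir,
      enriched_families = fh$enriched)

    enhancers$gap_lo <- NULL; enhancers$gap_hi <- NULL
    world <- list(config = config, genes = genes, enhancers = enhancers,
                  contigs = contigs, bpkm = bpkm,
                  chrom_sizes = data.frame(chrom = "chrS",
                                           length = config$chrom_length),
                  seed_families = fam,
                  sequences = list(erna = erna_seqs, promoter = promoter_seqs,
                                   utr3 = utr3_seqs),
                  family_hits = fh, truth = truth)
    class(world) <- "erna_world"
    world
  })
}

#' Generate ncRNA family-hit tables with planted enrichment
#'
#' Each query hits each family independently at the background rate; one
#' designated miRNA-class family gets `mirna_excess` extra hit probability in
#' the real table and one other-class family gets `other_excess`.
#'
#' @param n_real,n_control Numbers of real (eRNA) and control queries.
#' @param n_families Number of families.
#' @param mirna_family_fraction Fraction of families labelled class `miRNA`.
#' @param base_rate Background per-query hit probability.
#' @param mirna_excess,other_excess Planted excess proportions (0 for a null
#'   table).
#' @param rng_seed Integer seed.
#' @param query_ids Optional real query ids (length `n_real`).
#' @return List with `real`, `control` (hit data.frames), `families`,
#'   `n_real`, `n_control` and `enriched` (the planted family ids).
#' @export
generate_family_hits <- function(n_real, n_control, n_families = 200,
                                 mirna_family_fraction = 0.2,
                                 base_rate = 0.02, mirna_excess = 0.15,
                                 other_excess = 0.04, rng_seed = 1L,
                                 query_ids = NULL) {
  with_seed(rng_seed, {
    n_mir <- max(1, round(mirna_family_fraction * n_families))
    families <- data.frame(
      family_id = sprintf("RF%04d", seq_len(n_families)),
      family_class = rep(c("miRNA", "other"), c(n_mir, n_families - n_mir)),
      stringsAsFactors = FALSE)
    rate_real <- rep(base_rate, n_families)
    enriched <- character(0)
    if (mirna_excess > 0) {
      rate_real[1] <- base_rate + mirna_excess
      enriched <- c(enriched, families$family_id[1])
    }
    if (other_excess > 0 && n_families > n_mir) {
      rate_real[n_mir + 1] <- base_rate + other_excess
      enriched <- c(enriched, families$family_id[n_mir + 1])
    }
    if (is.null(query_ids)) query_ids <- sprintf("erna%05d", seq_len(n_real))
    ctrl_ids <- sprintf("ctrl%05d", seq_len(n_control))
    draw <- function(ids, rates) {
      hit <- matrix(stats::runif(length(ids) * n_families),
                    length(ids), n_families) <
        matrix(rates, length(ids), n_families, byrow = TRUE)
      idx <- which(hit, arr.ind = TRUE)
      data.frame(query_id = ids[idx[, 1]],
                 family_id = families$family_id[idx[, 2]],
                 family_class = families$family_class[idx[, 2]],
                 score = round(stats::runif(nrow(idx), 20, 100), 1),
                 stringsAsFactors = FALSE)
    }
    real <- draw(query_ids, rate_real)
    control <- draw(ctrl_ids, rep(base_rate, n_families))
    list(real = real, control = control, families = families,
         n_real = length(query_ids), n_control = length(ctrl_ids),
         enriched = enriched)
  })
}

#' Plant miRNA seed-complement sites into promoter sequences
#'
#' With probability `rate` per sequence, overwrites a random stretch with the
#' exact site string for a randomly chosen family: `8mer` is the reverse
#' complement of the 7-nt seed followed by A, `7mer-m8` the reverse complement
#' followed by a non-A base, `7mer-A1` the reverse complement of seed
#' positions 1-6 followed by A (with the preceding base forced to break an
#' 8mer). The remaining sequence is untouched uniform-random background.
#'
#' @param promoter_seqs Named character vector of sequences (length >= 8).
#' @param families Seed-family data.frame (see [read_seed_families()]).
#' @param rate Per-sequence planting probability.
#' @param site_type One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`.
#' @param rng_seed Integer seed.
#' @return List with `seqs` (modified sequences) and `truth` (data.frame of
#'   seq_id, family_id, position (0-based), site_type).
#' @export
plant_seed_sites <- function(promoter_seqs, families, rate = 0.5,
                             site_type = "8mer", rng_seed = 1L) {
  stopifnot(all(nchar(promoter_seqs) >= 8),
            site_type %in% c("8mer", "7mer-m8", "7mer-A1"))
  with_seed(rng_seed, {
    truth <- NULL
    for (i in seq_along(promoter_seqs)) {
      if (stats::runif(1) >= rate) next
      fi <- sample.int(nrow(families), 1)
      seed7 <- families$seed7[fi]
      rc7 <- reverse_complement(seed7)
      site <- switch(site_type,
        "8mer" = paste0(rc7, "A"),
        "7mer-m8" = rc7,
        "7mer-A1" = paste0(reverse_complement(substr(seed7, 1, 6)), "A"))
      L <- nchar(promoter_seqs[i])
      # leave room for the forced context base around the site
      pos <- sample.int(L - nchar(site) - 1, 1) + 1
      substr(promoter_seqs[i], pos, pos + nchar(site) - 1) <- site
      if (site_type == "7mer-m8") {
        # following base must not be A (would upgrade to 8mer)
        substr(promoter_seqs[i], pos + 7, pos + 7) <- "G"
      } else if (site_type == "7mer-A1") {
        # preceding base must not complete a full 7-nt seed match
        m8c <- reverse_complement(substr(seed7, 7, 7))
        alt <- setdiff(c("A", "C", "G", "T"), m8c)[1]
        substr(promoter_seqs[i], pos - 1, pos - 1) <- alt
      }
      truth <- rbind(truth, data.frame(
        seq_id = names(promoter_seqs)[i], family_id = families$family_id[fi],
        position = pos - 1, site_type = site_type, stringsAsFactors = FALSE))
    }
    list(seqs = promoter_seqs, truth = truth)
  })
}

#' Simulate per-group tissue z-scores under the expression model
#'
#' Group-level counterpart of [generate_world()]'s expression model, used for
#' statistical calibration at scale: each group has `n_tissues` members whose
#' states are Bernoulli(`erna_fraction`) conditioned on both states being
#' present; member expression is standardized lognormal,
#' `exp(sigma * (N(0,1) + delta * state))`, standardized with the analytic
#' mixture moments so values live on the measured z-score scale.
#'
#' @param n_groups Number of groups.
#' @param n_tissues Members per group.
#' @param erna_fraction Transcription probability per member.
#' @param delta Planted latent shift.
#' @param sigma Log-scale sd.
#' @param rng_seed Integer seed.
#' @return data.frame with columns `group_id`, `tissue`, `state`, `z`.
#' @export
simulate_group_zscores <- function(n_groups, n_tissues = 12,
                                   erna_fraction = 0.4, delta = 0.5,
                                   sigma = 0.3, rng_seed = 1L) {
  stopifnot(n_tissues >= 2)
  with_seed(rng_seed, {
    mm <- lognormal_mixture_moments(sigma, delta, erna_fraction)
    out <- vector("list", n_groups)
    for (g in seq_len(n_groups)) {
      repeat {
        s <- stats::runif(n_tissues) < erna_fraction
        if (any(s) && !all(s)) break
      }
      x <- exp(sigma * (stats::rnorm(n_tissues) + delta * s))
      out[[g]] <- data.frame(
        group_id = sprintf("G%05d", g),
        tissue = sprintf("tissue%02d", seq_len(n_tissues)),
        state = ifelse(s, "eRNA", "no-eRNA"),
        z = (x - mm$mean) / mm$sd, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Write a synthetic world to disk
#'
#' Emits exactly the formats the readers consume: `genes.tsv`,
#' `enhancers.tsv`, `contigs.bed` (BED6, score = BPKM, per-tissue suffix in
#' the name kept in a `tissue` column file `contig_tissues.tsv`), `bpkm.tsv`,
#' `erna.fa`, `promoters.fa`, `utr3.fa`, `seed_families.tsv`,
#' `hits_real.tsv`, `hits_control.tsv` and `truth.json`. Output is
#' byte-identical for a fixed world.
#'
#' @param world An `erna_world`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gene_models(world$genes, p("genes.tsv"))
  write_enhancers(world$enhancers, p("enhancers.tsv"))
  write_bed(world$contigs, p("contigs.bed"))
  utils::write.table(world$contigs[c("name", "tissue")], p("contig_tissues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bpkm_table(world$bpkm, p("bpkm.tsv"))
  if (length(world$sequences$erna) > 0)
    write_fasta(world$sequences$erna, p("erna.fa"))
  write_fasta(world$sequences$promoter, p("promoters.fa"))
  write_fasta(world$sequences$utr3, p("utr3.fa"))
  write_seed_families(world$seed_families, p("seed_families.tsv"))
  write_family_hits(world$family_hits$real, p("hits_real.tsv"))
  write_family_hits(world$family_hits$control, p("hits_control.tsv"))
  jsonlite::write_json(world$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(dir)
}
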