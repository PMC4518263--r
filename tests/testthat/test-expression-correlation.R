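# BPKM arithmetic, matched/flanking/background regions, Pearson profiles.

test_that("bpkm matches its closed form and rejects bad inputs", {
  expect_equal(bpkm(4000, 2000, 1e9), 2.0)
  expect_equal(bpkm(0, 500, 1e7), 0.0)
  expect_equal(bpkm(700, 700, 1e6), 1000.0)
  expect_error(bpkm(10, 0, 1e6), "region_length")
  expect_error(bpkm(10, 100, 0), "total_mapped_bases")
  expect_error(bpkm(-1, 100, 1e6), "covered_bases")
  set.seed(5)
  c0 <- stats::runif(200, 0, 1e6); L <- stats::runif(200, 1, 1e5)
  Tm <- stats::runif(200, 1e6, 1e10)
  expect_equal(bpkm(c0, L, Tm), c0 * 1e9 / (L * Tm), tolerance = 1e-12)
})

test_that("matched_gene_region anchors at the strand-aware TSS and truncates", {
  gp <- tiny_genes(list("g", "chr1", "+", 50000, 60000))
  expect_equal(matched_gene_region(gp, 800)[, c("start", "end")],
               data.frame(start = 50000, end = 50800))
  gm <- tiny_genes(list("g", "chr1", "-", 50000, 60000))
  expect_equal(matched_gene_region(gm, 800)[, c("start", "end")],
               data.frame(start = 59200, end = 60000))
  big <- matched_gene_region(gp, 1e6)
  expect_equal(c(big$start, big$end), c(50000, 60000))
})

test_that("flanking bins start at the window boundary or the eRNA's far end", {
  enh <- data.frame(chrom = "chr1", start = 10000, end = 11000)
  no_genes <- tiny_genes(list("g", "chr9", "+", 1, 10))
  fl <- flanking_regions(enh, data.frame(start = 9500, end = 10500),
                         genes = no_genes)
  dn <- fl[fl$side == "dn", ]
  expect_equal(dn$start, c(14000, 15000, 16000))
  expect_equal(dn$end, c(15000, 16000, 17000))
  up <- fl[fl$side == "up", ]
  expect_equal(sort(up$start), c(4000, 5000, 6000))
  # eRNA extending past the downstream boundary shifts the bins
  fl2 <- flanking_regions(enh, data.frame(start = 9500, end = 15000),
                          genes = no_genes)
  dn2 <- fl2[fl2$side == "dn", ]
  expect_equal(dn2$start, c(15000, 16000, 17000))
  # a bin overlapping a gene is dropped with its label
  genes <- tiny_genes(list("g", "chr1", "+", 15500, 18000))
  fl3 <- flanking_regions(enh, data.frame(start = 9500, end = 10500),
                          genes = genes)
  expect_setequal(fl3$bin[fl3$side == "dn"], "0_1k")
  expect_equal(nrow(fl3[fl3$side == "up", ]), 3)
})

test_that("pearson_cor matches a from-scratch implementation", {
  x <- 1:10
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1.0)
  set.seed(2)
  xr <- stats::rnorm(30)
  neg <- pearson_cor(xr, -xr)
  expect_equal(neg$r, -1.0)
  expect_gt(neg$p, 0.999)
  expect_error(pearson_cor(rep(1, 10), stats::rnorm(10)), "constant")
  for (i in 1:50) {
    a <- stats::rnorm(sample(5:50, 1)); b <- stats::rnorm(length(a))
    got <- pearson_cor(a, b); want <- oracle_pearson(a, b)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("gene_upstream_region sits 5' of the TSS on either strand", {
  gp <- tiny_genes(list("g", "chr1", "+", 5000, 9000))
  expect_equal(unlist(gene_upstream_region(gp, 800)[c("start", "end")]),
               c(start = 4200, end = 5000))
  gm <- tiny_genes(list("g", "chr1", "-", 5000, 9000))
  expect_equal(unlist(gene_upstream_region(gm, 800)[c("start", "end")]),
               c(start = 9000, end = 9800))
})

test_that("sampled intergenic regions avoid margin-expanded genes", {
  genes <- tiny_genes(list("g1", "chr1", "+", 50000, 60000),
                      list("g2", "chr1", "-", 150000, 160000))
  sizes <- data.frame(chrom = "chr1", length = 3e5)
  set.seed(10)
  for (i in 1:50) {
    iv <- sample_intergenic_region(2000, genes, sizes)
    expanded <- genomic_intervals(genes$chrom, pmax(0, genes$start - 3000),
                                  genes$end + 3000)
    expect_false(any(overlaps_any(iv, expanded)))
    expect_equal(iv$end - iv$start, 2000)
  }
})

test_that("correlation_profile pairs by region id, drops listwise and flags small n", {
  w <- generate_world(sim_config(n_tissues = 1, n_genes = 80, n_enhancers = 60,
                                 chrom_length = 2.4e6, erna_fraction = 1,
                                 rng_seed = 17))
  calls <- call_erna_states(
    filter_intergenic_enhancers(w$enhancers, w$genes),
    filter_gene_overlapping_contigs(w$contigs, w$genes))
  pr <- correlation_profile(calls, w$genes, w$bpkm)
  expect_equal(nrow(pr), 6)          # one row per class, single tissue
  expect_true(all(pr$n[pr$label == "target_gene"] > 0))
  # removing some gene rows shrinks the target-gene n (listwise deletion)
  drop_genes <- utils::head(unique(calls$gene_id[calls$state == "eRNA"]), 5)
  b2 <- w$bpkm[!(w$bpkm$region_id %in% drop_genes), ]
  pr2 <- correlation_profile(calls, w$genes, b2)
  expect_equal(pr2$n[pr2$label == "target_gene"],
               pr$n[pr$label == "target_gene"] - 5)
  # fewer than 3 usable pairs: undefined result, flagged with NA
  few <- calls[calls$state == "eRNA", ][1:2, ]
  pr3 <- correlation_profile(few, w$genes, w$bpkm)
  expect_true(is.na(pr3$r[pr3$label == "target_gene"]))
  expect_equal(pr3$n[pr3$label == "target_gene"], 2)
})

test_that("target-gene correlation dominates background classes on planted worlds", {
  cfg <- sim_config(n_tissues = 1, n_genes = 301, n_enhancers = 300,
                    chrom_length = 1e7, erna_fraction = 1, rho = 0.6,
                    rng_seed = 23)
  w <- generate_world(cfg)
  calls <- call_erna_states(
    filter_intergenic_enhancers(w$enhancers, w$genes),
    filter_gene_overlapping_contigs(w$contigs, w$genes))
  pr <- correlation_profile(calls, w$genes, w$bpkm)
  r_target <- pr$r[pr$label == "target_gene"]
  expect_gt(r_target, 0.4)
  expect_true(all(r_target > pr$r[pr$label != "target_gene"]))
})
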