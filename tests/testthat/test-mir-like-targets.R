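# Seed-site and alignment scanners, region builders, promoter-unique filter
# and the shuffle bootstrap.

let7 <- data.frame(family_id = "let-7", seed7 = "GAGGTAG",
                   mature = "TGAGGTAGTAGGTTGTATAGTT", stringsAsFactors = FALSE)

test_that("confirm_mir_region finds exact mature/seed occurrences in both orientations", {
  erna <- paste0("CCCCC", "TGAGGTAGTAGGTTGTATAGTT", "AAAAA")
  hit <- confirm_mir_region(erna, let7)
  expect_equal(hit$position, 5)
  expect_equal(hit$orientation, "sense")
  expect_equal(hit$matched, "mature")
  # RNA-alphabet input is equivalent
  expect_equal(confirm_mir_region(gsub("T", "U", erna), let7)$position, 5)
  # seed on the reverse strand
  anti <- paste0("GGGG", reverse_complement("GAGGTAG"), "GGGG")
  hit2 <- confirm_mir_region(anti, let7)
  expect_equal(hit2$orientation, "antisense")
  # a sequence avoiding the seed in both orientations: absent
  expect_null(confirm_mir_region(strrep("AC", 30), let7))
})

test_that("build_promoter spans TSS-1000..TSS+200 minus other gene bodies", {
  genes <- tiny_genes(list("g", "chr1", "+", 50000, 55000),
                      list("n", "chr1", "+", 48000, 49100))
  pr <- build_promoter(genes[1, ], genes)
  expect_equal(pr$start, 49100); expect_equal(pr$end, 50200)
  # no neighbours: full window
  pr2 <- build_promoter(genes[1, ], genes[1, ])
  expect_equal(c(pr2$start, pr2$end), c(49000, 50200))
  # minus strand: TSS is tx_end
  gm <- tiny_genes(list("g", "chr1", "-", 55000, 60000))
  pr3 <- build_promoter(gm, gm)
  expect_equal(c(pr3$start, pr3$end), c(59800, 61000))
  # neighbour covering the whole window: empty promoter
  cover <- tiny_genes(list("g", "chr1", "+", 50000, 55000),
                      list("big", "chr1", "+", 40000, 51000))
  expect_equal(nrow(build_promoter(cover[1, ], cover)), 0)
})

test_that("build_utr3 runs from the coding end to the gene end", {
  gp <- tiny_genes(list("g", "chr1", "+", 50000, 60000, 59000))
  u <- build_utr3(gp)
  expect_equal(c(u$start, u$end), c(59000, 60000))
  gm <- tiny_genes(list("g", "chr1", "-", 50000, 60000, 51500))
  um <- build_utr3(gm)
  expect_equal(c(um$start, um$end), c(50000, 51500))
  expect_null(build_utr3(tiny_genes(list("g", "chr1", "+", 0, 100, 100))))
  expect_null(build_utr3(tiny_genes(list("g", "chr1", "+", 0, 100))))
})

test_that("seed sites are typed by the canonical nomenclature", {
  # seed GAGGUAG: site core CTACCTC
  s8 <- paste0("GGGG", "CTACCTCA", "GGGG")
  got <- seed_site_scan(s8, let7, scan_antisense = FALSE)
  expect_equal(got$site_type, "8mer"); expect_equal(got$position, 4)
  s7 <- paste0("GGGG", "CTACCTCG", "GGGG")
  got7 <- seed_site_scan(s7, let7, scan_antisense = FALSE)
  expect_equal(got7$site_type, "7mer-m8")
  # 7mer-A1: complement of positions 2-7 + A, no position-8 match
  sA1 <- paste0("GGGG", "TACCTCA", "GGGG")
  gotA <- seed_site_scan(sA1, let7, scan_antisense = FALSE)
  expect_equal(gotA$site_type, "7mer-A1"); expect_equal(gotA$position, 4)
  # the A1 substring inside an 8mer is not double-reported
  expect_equal(nrow(seed_site_scan(s8, let7, scan_antisense = FALSE)), 1)
})

test_that("seed scanner agrees with the naive oracle and is strand-symmetric", {
  set.seed(33)
  for (i in 1:300) {
    seq <- random_dna_str(sample(40:150, 1))
    fam <- data.frame(family_id = "f", seed7 = random_dna_str(7),
                      mature = paste0("A", random_dna_str(21)))
    got <- seed_site_scan(seq, fam, scan_antisense = FALSE)
    want <- oracle_seed_sites_sense(seq, fam$seed7)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want$position), ]
      expect_equal(got$position, want$position)
      expect_equal(got$site_type, want$site_type)
    }
    # strand symmetry: antisense hits equal sense hits on the reverse
    # complement, with mirrored coordinates
    both <- seed_site_scan(seq, fam)
    anti <- both[both$strand_scanned == "antisense", ]
    rc_sense <- seed_site_scan(oracle_revcomp(seq), fam, scan_antisense = FALSE)
    L <- nchar(seq)
    mapped <- L - (rc_sense$position + ifelse(rc_sense$site_type == "8mer", 8, 7))
    expect_setequal(anti$position, mapped)
  }
})

test_that("alignment scores follow the declared weighting scheme", {
  mature <- "TGAGGTAGTAGGTTGTATAGTT"   # 22 nt
  perfect <- reverse_complement(mature)
  got <- alignment_site_scan(perfect, mature, threshold = 80,
                             scan_antisense = FALSE)
  expect_equal(got$score, 145)
  expect_equal(got$position, 0)
  # one seed mismatch swings 2*(5+3)
  seed_pos2 <- substr(mature, 2, 2)    # pairs near the 3' end of the site
  mutated <- perfect
  substr(mutated, 21, 21) <- setdiff(c("A", "C", "G", "T"),
                                     c(reverse_complement(seed_pos2)))[1]
  got2 <- alignment_site_scan(mutated, mature, threshold = 80,
                              scan_antisense = FALSE)
  expect_equal(got2$score, 129)
})

test_that("alignment scanner agrees with the all-windows oracle", {
  set.seed(35)
  for (i in 1:150) {
    seq <- random_dna_str(sample(40:90, 1))
    mature <- random_dna_str(sample(18:23, 1))
    thr <- sample(c(-50, 0, 40), 1)    # low thresholds exercise many windows
    got <- alignment_site_scan(seq, mature, threshold = thr,
                               scan_antisense = FALSE)
    want <- oracle_alignment_sense(seq, mature, thr)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$position, want$position)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("promoter-unique filter keeps promoter-only triples and is monotone", {
  sites <- data.frame(position = 1, site_type = "8mer", strand_scanned = "sense")
  none <- sites[0, ]
  expect_true(promoter_unique_filter(sites, none))
  expect_false(promoter_unique_filter(sites, sites))
  expect_false(promoter_unique_filter(none, none))
  expect_false(promoter_unique_filter(NULL, NULL))
  # adding a 3'UTR site can only remove a triple, never add one
  expect_lte(promoter_unique_filter(sites, sites),
             promoter_unique_filter(sites, none))
})

test_that("shuffle bootstrap reproduces the add-one formula exactly", {
  seqA <- strrep("ACGT", 20)
  # statistic blind to shuffling: every shuffle ties the observed value
  expect_identical(shuffle_bootstrap(seqA, function(s) 1, B = 100,
                                     rng_seed = 1)$p, 1.0)
  # statistic only the original sequence attains
  sb <- shuffle_bootstrap(seqA, function(s) as.numeric(identical(s, seqA)),
                          B = 100, rng_seed = 1)
  expect_identical(sb$p, 1 / 101)
  # null input: observed 0 ties every shuffle
  expect_identical(shuffle_bootstrap(seqA, function(s) 0, B = 50,
                                     rng_seed = 1)$p, 1.0)
  # determinism
  f <- function(s) sum(strsplit(s, "")[[1]][1:5] == "A")
  expect_identical(shuffle_bootstrap(seqA, f, B = 30, rng_seed = 4),
                   shuffle_bootstrap(seqA, f, B = 30, rng_seed = 4))
})

test_that("dinucleotide shuffle preserves the dinucleotide multiset", {
  set.seed(40)
  f <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sort(paste0(ch[-length(ch)], ch[-1]))
  }
  s <- random_dna_str(200)
  sh <- ernatools:::shuffle_sequence(s, dinucleotide = TRUE)
  expect_identical(f(sh), f(s))
  expect_false(identical(sh, s))
})

test_that("bootstrap p-values on null sequences are conservative", {
  set.seed(41)
  fams <- data.frame(family_id = sprintf("f%d", 1:5),
                     seed7 = vapply(1:5, function(i) random_dna_str(7), ""),
                     mature = vapply(1:5, function(i)
                       paste0("T", random_dna_str(21)), ""))
  prom <- c(gene1 = random_dna_str(400))
  ps <- vapply(1:60, function(i) {
    shuffle_bootstrap(random_dna_str(80), function(s)
      nrow(mir_like_targets(s, fams, prom)), B = 20, rng_seed = i)$p
  }, numeric(1))
  # stochastically >= uniform: the empirical CDF never exceeds uniform by much
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(vapply(grid, function(q) mean(ps <= q), 0) <= grid + 0.1))
})
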