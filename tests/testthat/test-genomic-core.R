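# Interval arithmetic, BED/TSV/FASTA I/O and sequence utilities.

test_that("read_bed parses BED3/BED6 and reports malformed lines", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr2\t0\t50\tx\t7\t-"), f)
  iv <- read_bed(f)
  expect_equal(iv$chrom, c("chr1", "chr2"))
  expect_equal(iv$start, c(100, 0))
  expect_equal(iv$end, c(200, 50))
  expect_equal(iv$strand, c("*", "*"))
  f2 <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200\ta\t0\t+", "chr1\t100\t200\tb\t0\t-"), f2)
  expect_equal(read_bed(f2, stranded = TRUE)$strand, c("+", "-"))

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), bad)
  expect_error(read_bed(bad), "line 2.*end <= start")
  writeLines("chr1\tx\t200", bad)
  expect_error(read_bed(bad), "line 1.*non-integer")
})

test_that("write_bed/read_bed round-trips coordinates bit-exactly", {
  set.seed(42)
  s <- sample.int(1e8, 500)
  iv <- data.frame(chrom = sample(paste0("chr", 1:5), 500, replace = TRUE),
                   start = s, end = s + sample.int(1e4, 500),
                   name = sprintf("n%03d", 1:500), score = 0,
                   strand = sample(c("+", "-"), 500, replace = TRUE),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile()
  write_bed(iv, f)
  back <- read_bed(f, stranded = TRUE)
  expect_identical(back$start, as.numeric(iv$start))
  expect_identical(back$end, as.numeric(iv$end))
  expect_identical(back$chrom, iv$chrom)
  expect_identical(back$strand, iv$strand)
  # writing again reproduces the file byte-for-byte
  f2 <- withr::local_tempfile()
  write_bed(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("overlaps follows the half-open convention and matches a per-base oracle", {
  a <- genomic_intervals("chr1", 0, 10)
  expect_false(overlaps(a, genomic_intervals("chr1", 10, 20)))
  expect_true(overlaps(a, genomic_intervals("chr1", 9, 20)))
  expect_false(overlaps(a, genomic_intervals("chr2", 0, 10)))

  set.seed(1)
  for (i in 1:1000) {
    s1 <- sample.int(200, 1); s2 <- sample.int(200, 1)
    x <- genomic_intervals(sample(c("c1", "c2"), 1), s1, s1 + sample.int(30, 1))
    y <- genomic_intervals(sample(c("c1", "c2"), 1), s2, s2 + sample.int(30, 1))
    expect_identical(overlaps(x, y),
                     oracle_overlap(as.list(x[1, ]), as.list(y[1, ])))
  }
})

test_that("distance_to_nearest_gene_boundary handles gap, overlap and empty cases", {
  genes <- tiny_genes(list("g1", "chr1", "+", 20000, 30000))
  expect_equal(distance_to_nearest_gene_boundary(
    genomic_intervals("chr1", 16000, 16900), genes), 3100)
  expect_equal(distance_to_nearest_gene_boundary(
    genomic_intervals("chr1", 21000, 21500), genes), 0)
  expect_equal(distance_to_nearest_gene_boundary(
    genomic_intervals("chr2", 0, 100), genes), Inf)
  # boundary on the other side: gap measured from interval start
  expect_equal(distance_to_nearest_gene_boundary(
    genomic_intervals("chr1", 33000, 34000), genes), 3000)
})

test_that("subtract_intervals cuts, preserves and conserves bases", {
  region <- genomic_intervals("chr1", 0, 100)
  r1 <- subtract_intervals(region, genomic_intervals("chr1", 40, 60))
  expect_equal(r1$start, c(0, 60)); expect_equal(r1$end, c(40, 100))
  r2 <- subtract_intervals(region, genomic_intervals("chr1", 0, 1)[0, ])
  expect_equal(r2$start, 0); expect_equal(r2$end, 100)
  expect_equal(nrow(subtract_intervals(region, genomic_intervals("chr1", 0, 100))), 0)

  # base conservation against a per-base boolean-mask oracle
  set.seed(7)
  for (i in 1:200) {
    rs <- sample.int(50, 1); re <- rs + sample.int(100, 1)
    k <- sample.int(4, 1)
    cs <- sample.int(200, k); ce <- cs + sample.int(60, k)
    region <- genomic_intervals("c", rs, re)
    cutters <- genomic_intervals("c", cs, ce)
    res <- subtract_intervals(region, cutters)
    mask <- rep(TRUE, re - rs)                      # bases rs..re-1
    for (j in seq_len(k)) {
      lo <- max(cs[j], rs); hi <- min(ce[j] - 1, re - 1)
      if (lo <= hi) mask[(lo:hi) - rs + 1] <- FALSE
    }
    kept <- if (nrow(res) > 0) sum(res$end - res$start) else 0
    expect_equal(kept, sum(mask))
    # and the kept intervals are exactly the mask's TRUE runs
    covered <- rep(FALSE, re - rs)
    if (nrow(res) > 0)
      for (j in seq_len(nrow(res)))
        covered[(res$start[j] - rs + 1):(res$end[j] - rs)] <- TRUE
    expect_identical(covered, mask)
  }
})

test_that("reverse_complement is an involution over DNA/RNA input", {
  expect_equal(reverse_complement("GAGGTAG"), "CTACCTC")
  expect_equal(reverse_complement("GAGGUAG"), "CTACCTC")
  expect_equal(reverse_complement("N"), "N")
  expect_equal(reverse_complement("acgt"), "ACGT")
  expect_error(reverse_complement("ACXT"), "invalid character 'X' at position 3")
  set.seed(3)
  for (i in 1:50) {
    s <- random_dna_str(sample(5:80, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s), oracle_revcomp(s))
  }
})

test_that("interval constructor enforces its invariants", {
  expect_error(genomic_intervals("chr1", -1, 10), "start")
  expect_error(genomic_intervals("chr1", 10, 10), "end")
  expect_error(genomic_intervals("", 0, 10), "chrom")
  expect_error(genomic_intervals("chr1", 0, 10, "x"), "strand")
})

test_that("gene model and FASTA round trips preserve content", {
  genes <- tiny_genes(list("g1", "chr1", "+", 100, 5000, 4000),
                      list("g2", "chr2", "-", 200, 900))
  f <- withr::local_tempfile()
  write_gene_models(genes, f)
  back <- read_gene_models(f)
  expect_equal(back$start, genes$start)
  expect_equal(back$cds_end, genes$cds_end)
  expect_equal(back$strand, genes$strand)

  seqs <- c(s1 = "ACGTACGT", s2 = "TTTTAAAA")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
})
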