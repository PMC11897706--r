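# All fixtures are generated in code at test time; binary BigWigs are written
# to tempdir() through rtracklayer and never stored in the repository.

make_bedgraph <- function(df, path = tempfile(fileext = ".bedGraph")) {
  write_bedgraph(df, path)
  path
}

test_that("per-base values are summed into fixed-width bins", {
  p <- make_bedgraph(data.frame(chrom = "chr1", start = 0, end = 4, value = 1))
  b <- read_bedgraph_binned(p, "chr1", 0, 4, bin_bp = 2)
  expect_equal(b$series$values, c(2, 2))
  expect_equal(b$series$weights, c(1, 1))
  # partial last bin: 3 bins over 50 bp at width 20, last weight 0.5
  p <- make_bedgraph(data.frame(chrom = "chr1", start = 0, end = 50, value = 1))
  b <- read_bedgraph_binned(p, "chr1", 0, 50, bin_bp = 20)
  expect_equal(length(b$series), 3L)
  expect_equal(b$series$weights, c(1, 1, 0.5))
  expect_equal(b$series$values, c(20, 20, 10))
  # mean option divides by covered width
  b <- read_bedgraph_binned(p, "chr1", 0, 50, bin_bp = 20, method = "mean")
  expect_equal(b$series$values, c(1, 1, 1))
})

test_that("binning conserves mass and matches an independent re-aggregation", {
  set.seed(420)
  vals <- rpois(23, 4)
  df <- data.frame(chrom = "chrQ", start = 0:22, end = 1:23, value = vals)
  p <- make_bedgraph(df)
  b <- read_bedgraph_binned(p, "chrQ", 0, 23, bin_bp = 5)
  expect_equal(sum(b$series$values), sum(vals), tolerance = 1e-6)
  manual <- tapply(vals, (0:22) %/% 5, sum)
  expect_equal(unname(b$series$values), unname(as.numeric(manual)))
})

test_that("BigWig and BedGraph readers agree on the same signal", {
  gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 41, 61), c(40, 60, 100)),
        score = c(2, 5, 2),
        seqinfo = GenomeInfoDb::Seqinfo("chr1", 200))
  bw <- tempfile(fileext = ".bw")
  rtracklayer::export.bw(gr, bw)
  bg <- make_bedgraph(data.frame(chrom = "chr1", start = c(0, 40, 60),
                                 end = c(40, 60, 100), value = c(2, 5, 2)))
  a <- read_bigwig_binned(bw, "chr1", 0, 100, bin_bp = 20)
  b <- read_bedgraph_binned(bg, "chr1", 0, 100, bin_bp = 20)
  expect_equal(a$series$values, b$series$values)
  # missing intervals read as zero signal with full weight
  z <- read_bigwig_binned(bw, "chr1", 100, 200, bin_bp = 50)
  expect_equal(z$series$values, c(0, 0))
  expect_equal(z$series$weights, c(1, 1))
  expect_error(read_bigwig_binned(bw, "chrZ", 0, 10), "chrZ")
  expect_error(read_bigwig_binned(bw, "chr1", 150, 300), "bounds")
})

test_that("bedgraph writing merges equal-valued adjacent intervals", {
  p <- tempfile(fileext = ".bedGraph")
  write_bedgraph(data.frame(chrom = "chr1", start = c(0, 20, 40),
                            end = c(20, 40, 60), value = c(0, 0, 10)), p)
  expect_length(readLines(p), 2L)
  rt <- read_bedgraph(p)
  expect_equal(rt$start, c(0, 40))
  expect_equal(rt$value, c(0, 10))
  # non-touching equal values are not merged
  write_bedgraph(data.frame(chrom = "chr1", start = c(0, 30), end = c(10, 40),
                            value = c(1, 1)), p)
  expect_length(readLines(p), 2L)
})

test_that("segmentations map back to basepair space with end clipping", {
  p <- make_bedgraph(data.frame(chrom = "chr1", start = 0, end = 50,
                                value = c(1)))
  tr <- read_bedgraph_binned(p, "chr1", 0, 50, bin_bp = 20)
  fit <- l0_segment(tr$series, "poisson", 1e6)
  df <- segmentation_to_track(fit, tr)
  expect_equal(df$start, 0)
  expect_equal(df$end, 50)  # region end, not the 60 bp bin end
  # bin-aligned regions round-trip exactly
  p2 <- make_bedgraph(data.frame(chrom = "chr1", start = c(0, 40),
                                 end = c(40, 80), value = c(1, 3)))
  tr2 <- read_bedgraph_binned(p2, "chr1", 0, 80, bin_bp = 20)
  fit2 <- l0_segment(tr2$series, "poisson", 0.5)
  df2 <- segmentation_to_track(fit2, tr2)
  expect_equal(df2$start, c(0, 40))
  expect_equal(df2$end, c(40, 80))
})

test_that("bismark coverage files parse with both coordinate dialects", {
  p <- tempfile(fileext = ".cov")
  # 6-column .cov, 1-based: (chr1, 100, 101, 75.0, 3, 1) -> meth 3 of 4 at 99
  writeLines(c("chr1\t100\t101\t75.0\t3\t1",
               "chr1\t150\t151\t50.0\t2\t2"), p)
  m <- read_bismark(p)
  expect_equal(m$pos, c(99, 149))
  expect_equal(m$series$meth, c(3, 2))
  expect_equal(m$series$total, c(4, 4))
  # 0-based dialect detected from a zero start
  writeLines(c("chr1\t0\t1\t100.0\t5\t0", "chr1\t10\t11\t0.0\t0\t4"), p)
  expect_equal(read_bismark(p)$pos, c(0, 10))
  # 7-column cytosine report
  writeLines(c("chr1\t100\t+\t3\t1\tCpG\tCGA"), p)
  expect_equal(read_bismark(p)$series$total, 4)
  # malformed and unsorted input are rejected with context
  writeLines(c("chr1\t100\t101\t75.0\tx\t1"), p)
  expect_error(read_bismark(p), "line 1")
  writeLines(c("chr1\t200\t201\t75.0\t3\t1", "chr1\t100\t101\t75.0\t3\t1"), p)
  expect_error(read_bismark(p), "increasing")
  # empty region gives an empty track
  writeLines(c("chr1\t100\t101\t75.0\t3\t1"), p)
  expect_null(read_bismark(p, start = 500, end = 600)$series)
})

test_that("write_bismark_cov round-trips through read_bismark", {
  sim <- sim_meth_cpg_outliers(n = 40, outliers = c(12, 30), seed = 421)
  p <- tempfile(fileext = ".cov")
  write_bismark_cov(sim$series, p, chrom = "chr2", start = 500, spacing = 7)
  m <- read_bismark(p)
  expect_equal(m$series$meth, sim$series$meth)
  expect_equal(m$series$total, sim$series$total)
  expect_equal(m$pos, 500 + 7 * (0:39))
})

test_that("TES/TSS follow the strand convention in BED and GTF input", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t500\ttx1\t0\t+",
               "chr1\t700\t900\ttx2\t0\t-"), bed)
  te <- transcript_ends(read_bed(bed))
  expect_equal(te$tes, c(500, 700))
  expect_equal(te$tss, c(100, 900))
  # BED12: outer bounds, strand-aware
  bed12 <- tempfile(fileext = ".bed")
  writeLines(paste("chr1", 1000, 2000, "tx3", 0, "-", 1000, 2000, "0", 2,
                   "100,100", "0,900", sep = "\t"), bed12)
  te12 <- transcript_ends(read_bed(bed12))
  expect_equal(te12$tes, 1000)
  expect_equal(te12$tss, 2000)
  # minimal GTF transcript parsing
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "transcript", 101, 500, ".", "+", ".",
                   'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
  tg <- transcript_ends(gtf)
  expect_equal(tg$tes, 500)
  expect_equal(tg$tss, 100)
})

test_that("methylation segments span the genomic extent of their CpGs", {
  sim <- sim_meth_low_coverage_insert(seed = 422)
  p <- tempfile(fileext = ".cov")
  write_bismark_cov(sim$series, p, start = 1000, spacing = 10)
  m <- read_bismark(p)
  fit <- l0_segment(m$series, "binomial",
                    lambda_for_target_segments(m$series, "binomial", "L0", 3)$lambda)
  df <- meth_segmentation_to_track(fit, m)
  expect_equal(df$start[1], 1000)
  expect_equal(df$end[nrow(df)], 1000 + 299 * 10 + 1)
  expect_true(all(df$start[-1] > df$start[-nrow(df)]))
})
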