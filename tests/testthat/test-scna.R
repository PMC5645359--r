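seg_df <- function(...) {
  segment_set(data.frame(..., stringsAsFactors = FALSE))
}

two_region_set <- function() {
  data.frame(chrom = c("chr1", "chr1"), start = c(0, 200), end = c(100, 300),
             label = c("R1", "R2"), stringsAsFactors = FALSE)
}

test_that("segment validation rejects overlaps and empty intervals", {
  expect_error(seg_df(sample = "a", chrom = "chr1", start = 10, end = 10,
                      seg_mean = 0), "end <= start")
  expect_error(seg_df(sample = c("a", "a"), chrom = "chr1",
                      start = c(0, 50), end = c(100, 150), seg_mean = c(0, 1)),
               "overlapping")
  # same interval in different samples is fine
  ok <- seg_df(sample = c("a", "b"), chrom = "chr1",
               start = c(0, 0), end = c(100, 100), seg_mean = c(0, 1))
  expect_s3_class(ok, "segment_set")
})

test_that("region calls threshold the length-weighted mean log2 ratio", {
  regions <- two_region_set()
  segs <- seg_df(sample = rep("a", 2), chrom = "chr1",
                 start = c(0, 200), end = c(100, 300), seg_mean = c(1.2, 0))
  rc <- call_regions(segs, regions)
  expect_equal(unname(rc$calls[, "a"]), c(2L, 0L))
  # half covered at 2.0, half at 0.0: weighted mean exactly at the +2 boundary
  segs2 <- seg_df(sample = rep("a", 2), chrom = "chr1",
                  start = c(0, 50), end = c(50, 100), seg_mean = c(2, 0))
  rc2 <- call_regions(segs2, regions[1, ])
  expect_equal(unname(rc2$calls[1, "a"]), 2L)
  # single-copy band
  segs3 <- seg_df(sample = "a", chrom = "chr1", start = 0, end = 100, seg_mean = 0.5)
  expect_equal(unname(call_regions(segs3, regions[1, ])$calls[1, "a"]), 1L)
  segs4 <- seg_df(sample = "a", chrom = "chr1", start = 0, end = 100, seg_mean = -0.5)
  expect_equal(unname(call_regions(segs4, regions[1, ])$calls[1, "a"]), -1L)
  # all-neutral profile and an uncovered region
  segs5 <- seg_df(sample = "a", chrom = "chr1", start = 0, end = 100, seg_mean = 0)
  expect_warning(rc5 <- call_regions(segs5, regions), "coverage")
  expect_true(all(rc5$calls == 0))
})

test_that("region calls are invariant to subdividing a segment", {
  regions <- two_region_set()[1, ]
  whole <- seg_df(sample = "a", chrom = "chr1", start = 0, end = 100, seg_mean = 1.4)
  pieces <- seg_df(sample = rep("a", 3), chrom = "chr1",
                   start = c(0, 30, 70), end = c(30, 70, 100),
                   seg_mean = rep(1.4, 3))
  expect_identical(call_regions(whole, regions)$calls,
                   call_regions(pieces, regions)$calls)
})

test_that("fraction of genome altered follows the length arithmetic", {
  flat <- seg_df(sample = "a", chrom = "chr1", start = 0, end = 1000, seg_mean = 0)
  expect_equal(unname(fraction_genome_altered(flat)), 0)
  hot <- seg_df(sample = "a", chrom = "chr1", start = 0, end = 1000, seg_mean = 1.5)
  expect_equal(unname(fraction_genome_altered(hot)), 1)
  # 2 of 10 equal-length regions altered
  ten <- seg_df(sample = rep("a", 10), chrom = "chr1",
                start = seq(0, 900, 100), end = seq(100, 1000, 100),
                seg_mean = c(1.5, -1.2, rep(0, 8)))
  expect_equal(unname(fraction_genome_altered(ten)), 0.2)
  # subdividing an altered segment changes nothing
  split2 <- seg_df(sample = rep("a", 3), chrom = "chr1",
                   start = c(0, 50, 100), end = c(50, 100, 1000),
                   seg_mean = c(1.5, 1.5, 0))
  merged <- seg_df(sample = rep("a", 2), chrom = "chr1",
                   start = c(0, 100), end = c(100, 1000), seg_mean = c(1.5, 0))
  expect_equal(fraction_genome_altered(split2), fraction_genome_altered(merged))
})

test_that("region frequency comparison matches exact hypergeometric values", {
  regions <- data.frame(chrom = "chr1", start = 0, end = 100, label = "R1",
                        stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("s%02d", 1:20),
                        group = rep(c("STIC", "NOSTIC"), each = 10))
  # altered in all of one group and none of the other
  calls <- matrix(c(rep(2L, 10), rep(0L, 10)), 1,
                  dimnames = list("R1", samples$sample_id))
  rc <- region_calls(regions, calls, samples)
  res <- region_frequency_test(rc)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$freq_STIC, 1)
  expect_equal(res$freq_NOSTIC, 0)
  # identical call patterns give p = 1
  bal <- region_calls(regions,
                      matrix(rep(c(2L, 0L), 10), 1,
                             dimnames = list("R1", samples$sample_id)),
                      samples)
  expect_equal(region_frequency_test(bal)$p, 1)
  # never-altered regions are flagged with p = 1
  flat <- region_calls(regions,
                       matrix(0L, 1, 20, dimnames = list("R1", samples$sample_id)),
                       samples)
  rf <- region_frequency_test(flat)
  expect_true(rf$flat); expect_equal(rf$p, 1)
})

test_that("frequency comparison is symmetric in group relabeling", {
  cn <- generate_copy_number(scna_config(n_regions = 30, seed = 9))
  res <- region_frequency_test(cn)
  flipped <- cn
  flipped$samples$group <- c(STIC = "NOSTIC", NOSTIC = "STIC")[cn$samples$group]
  res2 <- region_frequency_test(flipped)
  expect_equal(res$p, res2$p)
  expect_equal(res$freq_STIC, res2$freq_NOSTIC)
})
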