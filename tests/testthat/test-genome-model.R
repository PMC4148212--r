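# Data model, format readers/writers, and the overlap primitive.

test_that("narrowPeak lines map onto the peak model", {
  f <- withr::local_tempfile(lines = c(
    "chr2L\t1000\t1500\tp1\t100\t.\t5.0\t8.0\t6.0\t250",
    "chr2L\t5000\t5700\tp2\t80\t.\t4.0\t6.5\t5.0\t-1"))
  p <- read_peaks(f, "narrowPeak")
  expect_equal(GenomicRanges::start(p), c(1001, 5001))  # 1-based internal
  expect_equal(GenomicRanges::end(p), c(1500, 5700))
  expect_equal(GenomicRanges::width(p), c(500, 700))
  expect_equal(S4Vectors::mcols(p)$summit_offset, c(250L, 350L)) # -1 -> midpoint
  expect_equal(S4Vectors::mcols(p)$neg_log10_p, c(8.0, 6.5))
})

test_that("BED6 peaks get midpoint summits and zero significance", {
  f <- withr::local_tempfile(lines = "chr3R\t100\t800\tb1\t0\t.")
  p <- read_peaks(f, "bed6")
  expect_equal(S4Vectors::mcols(p)$summit_offset, 350L)
  expect_equal(S4Vectors::mcols(p)$neg_log10_p, 0)
})

test_that("malformed or inverted peak records fail with a line number", {
  f <- withr::local_tempfile(lines = c(
    "chr2L\t1000\t1500\tp1\t100\t.\t5.0\t8.0\t6.0\t250",
    "chr2L\t1000\t1500"))
  expect_error(read_peaks(f, "narrowPeak"), "line 2")
  g <- withr::local_tempfile(lines = "chr2L\t1500\t1000\tp1\t0\t.")
  expect_error(read_peaks(g, "bed6"), "start >= end")
  expect_error(read_peaks(f, "bogus"))
})

test_that("table format converts 1-based inclusive and honors the width column", {
  f <- withr::local_tempfile(lines = c(
    "Chromosome\tStart\tEnd\tWidth\tPeak",
    "chr2L\t1001\t1500\t500\tk1",
    "chr2L\t2001\t2500\t480\tk2"))   # width disagrees with end - start + 1
  p <- read_peaks(f, "table",
                  column_map = list(chrom = "Chromosome", start = "Start",
                                    end = "End", width = "Width",
                                    name = "Peak"))
  expect_equal(GenomicRanges::start(p), c(1001, 2001))
  expect_equal(GenomicRanges::width(p), c(500, 480))
  expect_error(read_peaks(f, "table"), "column_map")
})

test_that("TSS follows the strand rule and GFF3 round-trips", {
  tx <- new_transcripts(c("chr2L", "chr2L"), c(2000, 2000), c(3000, 3000),
                        strand = c("+", "-"),
                        transcript_id = c("plus", "minus"))
  expect_equal(tss_positions(tx), c(2001, 3000))  # 0-based 2000 and 2999
  expect_equal(tes_positions(tx), c(3000, 2001))
  f <- withr::local_tempfile()
  write_transcripts(tx, f)
  tx2 <- read_transcripts(f, "gff3")
  expect_equal(GenomicRanges::start(tx2), GenomicRanges::start(tx))
  expect_equal(as.character(GenomicRanges::strand(tx2)),
               as.character(GenomicRanges::strand(tx)))
  expect_equal(S4Vectors::mcols(tx2)$transcript_id,
               S4Vectors::mcols(tx)$transcript_id)
})

test_that("BED transcript input keeps ids and requires strand", {
  f <- withr::local_tempfile(lines = c(
    "chr2L\t100\t900\ttxA\t0\t+",
    "chr2L\t2000\t2600\ttxB\t0\t-"))
  tx <- read_transcripts(f, "bed")
  expect_equal(S4Vectors::mcols(tx)$transcript_id, c("txA", "txB"))
  g <- withr::local_tempfile(lines = "chr2L\t100\t900\ttxA")
  expect_error(read_transcripts(g, "bed"), "strand")
})

test_that("bedGraph reading fills dense bins and rejects bad input", {
  f <- withr::local_tempfile(lines = "chr\t0\t300\t5")
  tr <- read_binned_track(f, chrom_sizes = c(chr = 1000), bin_size = 100)
  expect_length(tr$counts$chr, 10)
  expect_equal(tr$counts$chr, c(5, 5, 5, rep(0, 7)))
  g <- withr::local_tempfile(lines = c("chr\t0\t300\t5", "chr\t200\t400\t2"))
  expect_error(read_binned_track(g, c(chr = 1000), 100), "overlapping")
  h <- withr::local_tempfile(lines = "chr\t50\t250\t5")
  expect_error(read_binned_track(h, c(chr = 1000), 100), "aligned")
})

test_that("binned tracks round-trip through bedGraph, partial last bin included", {
  withr::local_seed(11)
  tr <- random_track(chrom_sizes = c(chrA = 950, chrB = 2000), lambda = 3)
  f <- withr::local_tempfile()
  write_binned_track(tr, f)
  tr2 <- read_binned_track(f, tr$chrom_sizes, tr$bin_size)
  expect_equal(tr2$counts, lapply(tr$counts, as.numeric))
})

test_that("overlap pairs respect half-open boundaries", {
  a <- new_peaks("c", 100, 200)
  expect_equal(nrow(overlap_pairs(a, new_peaks("c", 199, 300))), 1)
  expect_equal(nrow(overlap_pairs(a, new_peaks("c", 200, 300))), 0)
  expect_equal(nrow(overlap_pairs(a[0], a)), 0)
})

test_that("overlap pairs match the quadratic oracle and are symmetric", {
  for (seed in 1:20) {
    withr::local_seed(seed)
    a <- random_peaks(200)
    b <- random_peaks(200)
    got <- overlap_pairs(a, b)
    ref <- bf_overlap_pairs(a, b)
    expect_equal(got$a, ref$a)
    expect_equal(got$b, ref$b)
    rev_ <- overlap_pairs(b, a)
    expect_equal(got[order(got$b, got$a), ]$a, rev_$b)
  }
})

test_that("peak writers round-trip the data model", {
  withr::local_seed(5)
  p <- random_peaks(50)
  f <- withr::local_tempfile()
  write_peaks(p, f, "narrowPeak")
  p2 <- read_peaks(f, "narrowPeak")
  expect_equal(GenomicRanges::start(p2), GenomicRanges::start(p))
  expect_equal(GenomicRanges::width(p2), GenomicRanges::width(p))
  expect_equal(S4Vectors::mcols(p2)$summit_offset,
               S4Vectors::mcols(p)$summit_offset)
  expect_equal(S4Vectors::mcols(p2)$neg_log10_p,
               S4Vectors::mcols(p)$neg_log10_p)
})

test_that("segmentations reject overlaps and bad labels, and round-trip", {
  expect_error(new_segmentation("c", c(0, 50), c(100, 150),
                                c("RED", "BLUE")), "overlap")
  expect_error(new_segmentation("c", 0, 100, "PINK"), "labels")
  seg <- new_segmentation(c("c", "c"), c(0, 100), c(100, 300),
                          c("RED", "BLACK"))
  f <- withr::local_tempfile()
  write_segmentation(seg, f)
  seg2 <- read_segmentation(f)
  expect_equal(as.character(S4Vectors::mcols(seg2)$label), c("RED", "BLACK"))
  expect_equal(GenomicRanges::start(seg2), GenomicRanges::start(seg))
})
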