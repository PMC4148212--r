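# Strand-aware peak-to-transcript annotation and TSS-distance histograms.

test_that("category rules follow the documented precedence and sign convention", {
  tx <- new_transcripts("c", 2000, 3000, "+", "t1")
  # summit exactly at the plus-strand TSS -> overlapStart, d = 0
  p <- new_peaks("c", 1900, 2100, summit_offset = 100)
  ann <- annotate_peaks(p, tx)
  expect_equal(ann$category, "overlapStart")
  expect_equal(ann$distance, 0)
  # peak covering the whole transcript
  big <- new_peaks("c", 1900, 3100)
  expect_equal(annotate_peaks(big, tx)$category, "includeFeature")
  # peak strictly within the transcript body
  expect_equal(annotate_peaks(new_peaks("c", 2300, 2700), tx)$category,
               "inside")
  # peak over the 3' end
  expect_equal(annotate_peaks(new_peaks("c", 2800, 3200), tx)$category,
               "overlapEnd")
  # non-overlapping peaks by sign of d
  expect_equal(annotate_peaks(new_peaks("c", 1000, 1500), tx)$category,
               "upstream")
  expect_equal(annotate_peaks(new_peaks("c", 3500, 4000), tx)$category,
               "downstream")
})

test_that("minus-strand distances run against the genomic axis", {
  tx <- new_transcripts("c", 2000, 3000, "-", "t1")  # TSS at 0-based 2999
  p <- new_peaks("c", 2900, 3050, summit_offset = 69) # summit at 0-based 2969
  ann <- annotate_peaks(p, tx)
  expect_equal(ann$distance, 30)       # 30 bp downstream in transcription
  expect_equal(ann$category, "overlapStart")
})

test_that("peaks on empty chromosomes are flagged unassigned", {
  tx <- new_transcripts("c1", 0, 1000, "+", "t1")
  p <- new_peaks(c("c1", "c9"), c(100, 100), c(300, 300))
  ann <- annotate_peaks(p, tx)
  expect_equal(ann$category[2], "unassigned")
  expect_true(is.na(ann$distance[2]))
})

test_that("flipping strands negates distances (point transcripts)", {
  withr::local_seed(41)
  tx <- new_transcripts("chrA", seq(1000, 90000, by = 4000),
                        seq(1000, 90000, by = 4000) + 1,
                        strand = sample(c("+", "-"), 23, replace = TRUE),
                        transcript_id = sprintf("t%02d", 1:23))
  p <- random_peaks(60, max_pos = 9e4, chroms = "chrA")
  d1 <- annotate_peaks(p, tx)$distance
  flipped <- tx
  GenomicRanges::strand(flipped) <-
    ifelse(as.character(GenomicRanges::strand(tx)) == "+", "-", "+")
  d2 <- annotate_peaks(p, flipped)$distance
  expect_equal(d2, -d1)
})

test_that("annotation matches the brute-force nearest-TSS scan", {
  for (seed in 1:20) {
    withr::local_seed(seed)
    p <- random_peaks(200, max_pos = 3e5)
    tx <- random_transcripts(100, max_pos = 3e5)
    got <- annotate_peaks(p, tx)
    ref <- bf_annotate(p, tx)
    expect_equal(got$category, ref$category)
    expect_equal(got$transcript_id, ref$transcript_id)
    expect_equal(got$distance, ref$distance)
  }
})

test_that("summit-TSS histogram recovers a planted downstream offset", {
  withr::local_seed(17)
  n <- 200
  tss0 <- seq(5000, by = 5000, length.out = n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tx <- new_transcripts("chrA",
                        ifelse(strand == "+", tss0, tss0 - 2000 + 1),
                        ifelse(strand == "+", tss0 + 2000, tss0 + 1),
                        strand = strand,
                        transcript_id = sprintf("t%03d", 1:n))
  d_true <- 35 + round(rnorm(n, 0, 5))
  summit0 <- tss0 + ifelse(strand == "+", d_true, -d_true)
  p <- new_peaks("chrA", summit0 - 250, summit0 + 250, summit_offset = 250)
  ann <- annotate_peaks(p, tx)
  expect_equal(ann$distance, d_true)
  h <- tss_distance_histogram(ann, bin = 25)
  expect_equal(h$mode_bin, 25)                      # mode in [25, 50)
  expect_equal(sum(h$histogram$count), n)           # mass conservation
})

test_that("category composition is exhaustive and sums to 100", {
  tx <- new_transcripts("c", 2000, 3000, "+", "t1")
  p <- new_peaks("c", c(1900, 1950), c(2100, 2150))
  comp <- category_composition(annotate_peaks(p, tx))
  expect_equal(sum(comp$percent), 100)
  expect_equal(comp$percent[comp$category == "overlapStart"], 100)
  withr::local_seed(3)
  ann <- annotate_peaks(random_peaks(150, max_pos = 3e5),
                        random_transcripts(80, max_pos = 3e5))
  comp2 <- category_composition(ann)
  expect_equal(sum(comp2$percent), 100)
  expect_equal(comp2$n[comp2$category == "inside"],
               sum(ann$category == "inside"))
})
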