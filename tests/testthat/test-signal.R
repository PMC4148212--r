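# Upper-quantile normalization, meta-profiles, heatmap matrices, locus
# profiles.

test_that("a doubled track is scaled back onto its partner", {
  withr::local_seed(2)
  a <- random_track()
  b <- a; b$counts <- lapply(b$counts, `*`, 2)
  nrm <- upper_quantile_normalize(list(a = a, b = b))
  expect_equal(nrm$tracks$a$counts, nrm$tracks$b$counts)
  expect_equal(unname(nrm$factors["b"]), unname(nrm$factors["a"]) / 2)
  single <- upper_quantile_normalize(list(a = a))
  expect_equal(unname(single$factors), 1)
})

test_that("normalized tracks share the upper quantile of nonzero bins", {
  withr::local_seed(6)
  trks <- list(x = random_track(lambda = 3), y = random_track(lambda = 9),
               z = random_track(lambda = 30))
  nrm <- upper_quantile_normalize(trks, q = 0.95)
  qs <- vapply(nrm$tracks, function(t) {
    v <- unlist(t$counts); stats::quantile(v[v != 0], 0.95, names = FALSE)
  }, numeric(1))
  expect_lt(diff(range(qs)) / mean(qs), 1e-9)
})

test_that("between-track ratios are invariant to pre-scaling a track", {
  # the symmetric (geometric-mean) reference moves by c^(1/T) when one track
  # is pre-scaled by c, so single-track outputs shift by a global constant
  # while every between-track ratio is preserved
  withr::local_seed(13)
  trks <- list(x = random_track(lambda = 4), y = random_track(lambda = 12))
  out1 <- upper_quantile_normalize(trks)
  trks$x$counts <- lapply(trks$x$counts, `*`, 7)
  out2 <- upper_quantile_normalize(trks)
  expect_equal(out2$tracks$x$counts$chrA * out1$tracks$y$counts$chrA,
               out1$tracks$x$counts$chrA * out2$tracks$y$counts$chrA)
  g1 <- out2$tracks$x$counts$chrA / out1$tracks$x$counts$chrA
  expect_lt(diff(range(g1[is.finite(g1) & g1 > 0])), 1e-9)
  zero <- binned_track(NULL, c(chrA = 5e4))
  expect_error(upper_quantile_normalize(list(a = zero)), "nonzero")
})

test_that("an impulse at every summit yields a unit spike at offset zero", {
  summits0 <- c(5050, 12050, 30050)
  p <- new_peaks("chrA", summits0 - 250, summits0 + 250, summit_offset = 250)
  tr <- binned_track(NULL, c(chrA = 5e4))
  tr$counts$chrA[summits0 %/% 100 + 1] <- 1
  prof <- meta_profile(tr, p, flank = 2000)
  expect_equal(prof$n_used, 3)
  expect_equal(unname(prof$profile[prof$offsets == 0]), 1)
  expect_equal(sum(prof$profile), 1)
  expect_equal(prof$n_dropped, 0)
})

test_that("strand mirroring reverses the profile", {
  withr::local_seed(10)
  tr <- random_track(chrom_sizes = c(chrA = 1e5))
  centers <- seq(10000, 90000, by = 10000) + 50
  point_tx <- function(strand)
    new_transcripts("chrA", centers - 1, centers, strand = strand,
                    transcript_id = sprintf("t%d", seq_along(centers)))
  fwd <- meta_profile(tr, point_tx("+"), flank = 1000)
  rev_ <- meta_profile(tr, point_tx("-"), flank = 1000)
  expect_equal(rev_$profile, rev(fwd$profile), ignore_attr = TRUE)
})

test_that("profiles of a constant track are constant; edge anchors are dropped", {
  tr <- binned_track(NULL, c(chrA = 2e4))
  tr$counts$chrA[] <- 4
  p <- new_peaks("chrA", c(100, 9000), c(600, 9500))  # first too close to 0
  prof <- meta_profile(tr, p, flank = 2000)
  expect_equal(unname(prof$profile), rep(4, 41))
  expect_equal(prof$n_used + prof$n_dropped, 2)
  expect_equal(prof$n_dropped, 1)
  expect_error(meta_profile(tr, p, flank = 150), "multiple")
  expect_error(meta_profile(tr, p[0], flank = 2000), "usable")
})

test_that("heatmap rows order by width and columns average to the profile", {
  withr::local_seed(21)
  tr <- random_track(chrom_sizes = c(chrA = 1e5))
  s <- seq(10000, 80000, by = 10000)
  w <- c(900, 300, 1500, 600, 450, 1200, 750, 350)
  p <- new_peaks("chrA", s, s + w, name = sprintf("p%d", 1:8))
  m <- heatmap_matrix(tr, p, flank = 500)
  expect_equal(rownames(m), sprintf("p%d", order(-w)))
  prof <- meta_profile(tr, p, flank = 500)
  expect_equal(unname(colMeans(m)), unname(prof$profile))
  # direct slicing oracle for one row
  i <- which(rownames(m) == "p3")
  sb <- (s[3] + 750) %/% 100   # summit bin of p3 (width 1500, midpoint)
  expect_equal(unname(m[i, ]), tr$counts$chrA[(sb - 5):(sb + 5) + 1])
})

test_that("locus profiles return exact bin values and replicate means", {
  withr::local_seed(33)
  a <- random_track(chrom_sizes = c(chrA = 2e4))
  b <- random_track(chrom_sizes = c(chrA = 2e4))
  lp <- locus_profile(list(one = a, pair = list(a, b)), "chrA", 1000, 2000)
  expect_equal(lp$one, a$counts$chrA[11:20])
  expect_equal(lp$pair, (a$counts$chrA[11:20] + b$counts$chrA[11:20]) / 2)
  zero <- binned_track(NULL, c(chrA = 2e4))
  expect_equal(locus_profile(list(z = zero), "chrA", 0, 500)$z, rep(0, 5))
  expect_error(locus_profile(list(z = zero), "chrA", 19000, 21000),
               "outside")
  expect_error(locus_profile(list(z = zero), "chrB", 0, 100), "not in track")
})
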