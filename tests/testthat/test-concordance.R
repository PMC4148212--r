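# Replicate concordance: ranking, percent overlap, cutoff selection,
# consensus and superset.

make_ranked_pair <- function(seed = 1, n = 120) {
  withr::local_seed(seed)
  list(a = rank_peaks(random_peaks(n)), b = rank_peaks(random_peaks(n)))
}

test_that("peaks rank by significance with positional tie-breaking", {
  p <- new_peaks(c("c2", "c1", "c1"), c(500, 100, 300),
                 c(600, 200, 400), neg_log10_p = c(3, 10, 7))
  r <- rank_peaks(p)
  expect_equal(S4Vectors::mcols(r)$neg_log10_p, c(10, 7, 3))
  ties <- new_peaks(c("c2", "c1"), c(500, 100), c(600, 200),
                    neg_log10_p = c(5, 5))
  expect_equal(as.character(GenomicRanges::seqnames(rank_peaks(ties))),
               c("c1", "c2"))
  expect_equal(rank_peaks(r), r)  # idempotent on sorted input
})

test_that("percent overlap is 100 for identical and 0 for disjoint lists", {
  x <- make_ranked_pair(3)
  for (r in c(1, 10, 60, 120))
    expect_equal(percent_overlap_at_rank(x$a, x$a, r), 100)
  b2 <- x$a
  GenomeInfoDb::seqlevels(b2) <- c("chrA", "chrB", "chrZ")
  b2 <- GenomicRanges::GRanges("chrZ",
                               IRanges::IRanges(GenomicRanges::start(x$a),
                                                GenomicRanges::end(x$a)),
                               name = S4Vectors::mcols(x$a)$name,
                               summit_offset = S4Vectors::mcols(x$a)$summit_offset,
                               neg_log10_p = S4Vectors::mcols(x$a)$neg_log10_p,
                               score = S4Vectors::mcols(x$a)$score)
  expect_equal(percent_overlap_at_rank(x$a, b2, 50), 0)
  expect_error(percent_overlap_at_rank(x$a, x$a, 0), "outside")
  expect_error(percent_overlap_at_rank(x$a, x$a, 500), "outside")
})

test_that("percent overlap at each rank equals a brute-force recount", {
  cfg <- simulation_config(seed = 42, n_peaks = 200, shared_fraction = 0.6)
  pk <- simulate_replicate_peaks(cfg)
  a <- rank_peaks(pk$rep1); b <- rank_peaks(pk$rep2)
  for (r in c(5, 40, 120, 200)) {
    pairs <- bf_overlap_pairs(utils::head(a, r), utils::head(b, r))
    o_ref <- 100 * (length(unique(pairs$a)) / r +
                    length(unique(pairs$b)) / r) / 2
    expect_equal(percent_overlap_at_rank(a, b, r), o_ref)
  }
})

test_that("the cutoff maximizes the curve; plateaus break to the smallest rank", {
  x <- make_ranked_pair(7)
  curve <- max_overlap_cutoff(x$a, x$a, rank_grid = c(10, 40, 80, 120))
  expect_s3_class(curve, "OverlapCurve")
  expect_equal(curve$percent, rep(100, 4))   # identical lists: flat at 100
  expect_equal(curve$cutoff_rank, 10)        # smallest rank of the plateau
  expect_error(max_overlap_cutoff(x$a, x$b, rank_grid = integer()), "grid")
  expect_error(max_overlap_cutoff(x$a, x$b, rank_grid = c(0, 10)), "grid")
})

test_that("the fast gridded curve agrees with the per-rank definition", {
  cfg <- simulation_config(seed = 9, n_peaks = 150, shared_fraction = 0.5)
  pk <- simulate_replicate_peaks(cfg)
  grid <- c(10, 30, 75, 110, 150)
  curve <- max_overlap_cutoff(pk$rep1, pk$rep2, rank_grid = grid)
  a <- rank_peaks(pk$rep1); b <- rank_peaks(pk$rep2)
  expect_equal(curve$percent,
               vapply(grid, function(r) percent_overlap_at_rank(a, b, r),
                      numeric(1)))
})

test_that("consensus is reference-anchored, unique, and empty for disjoint lists", {
  x <- make_ranked_pair(12)
  curve <- max_overlap_cutoff(x$a, x$a, rank_grid = c(50, 120))
  cons <- consensus_peaks(x$a, x$a, curve)
  expect_equal(S4Vectors::mcols(cons)$name,
               S4Vectors::mcols(utils::head(x$a, curve$cutoff_rank))$name)
  a1 <- new_peaks("c1", c(0, 1000), c(500, 1500), neg_log10_p = c(9, 8))
  b1 <- new_peaks("c2", c(0, 1000), c(500, 1500), neg_log10_p = c(9, 8))
  curve2 <- max_overlap_cutoff(a1, b1, rank_grid = 1:2)
  expect_length(consensus_peaks(a1, b1, curve2), 0)
})

test_that("planted concordance is recovered from the rank ordering", {
  # moderate depth here; the full 20-seed grid runs in the acceptance suite
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed, shared_fraction = 0.6)
    pk <- simulate_replicate_peaks(cfg)
    curve <- max_overlap_cutoff(pk$rep1, pk$rep2,
                                rank_grid = seq(10, 200, by = 2))
    planted <- nrow(pk$truth)
    expect_lt(abs(curve$cutoff_rank - planted) / planted, 0.1)
    cons <- consensus_peaks(pk$rep1, pk$rep2, curve)
    nm <- S4Vectors::mcols(cons)$name
    jac <- length(intersect(nm, pk$truth$name_rep1)) /
      length(union(nm, pk$truth$name_rep1))
    expect_gte(jac, 0.9)
  }
})

test_that("superset keeps reference peaks present in every other set", {
  withr::local_seed(31)
  ref <- random_peaks(150)
  expect_equal(superset(ref, list(ref)), ref)
  expect_length(superset(ref, list(ref[0])), 0)
  expect_error(superset(ref, list()), "non-empty")
  others <- list(random_peaks(100), random_peaks(100))
  got <- superset(ref, others)
  keep <- vapply(seq_along(ref), function(i)
    all(vapply(others, function(o)
      nrow(bf_overlap_pairs(ref[i], o)) > 0, logical(1))), logical(1))
  expect_equal(S4Vectors::mcols(got)$name, S4Vectors::mcols(ref)$name[keep])
  # adding datasets can only shrink the superset
  expect_lte(length(superset(ref, c(others, list(random_peaks(80))))),
             length(got))
})
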