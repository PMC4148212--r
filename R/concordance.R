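## Replicate concordance: rank peaks by significance, measure percent overlap
## of the top-r lists of two replicates across a grid of ranks, and cut both
## lists at the rank of maximum percent overlap to obtain the peaks present in
## both samples. The "superset" extends this to more than two datasets.

#' Rank peaks by significance
#'
#' Orders peaks by decreasing \eqn{-\log_{10} p}; ties are broken by
#' (chromosome, start) ascending so the order is stable and reproducible.
#'
#' @param peaks peak \code{GRanges}.
#' @return the same \code{GRanges}, reordered.
#' @export
rank_peaks <- function(peaks) {
  if (length(peaks) == 0) return(peaks)
  nlp <- S4Vectors::mcols(peaks)$neg_log10_p
  if (is.null(nlp) || any(is.na(nlp))) stop("all peaks need neg_log10_p")
  o <- order(-nlp, as.character(GenomicRanges::seqnames(peaks)),
             GenomicRanges::start(peaks))
  peaks[o]
}

#' Percent overlap between the top-r peaks of two ranked lists
#'
#' For rank \code{r} the top-\code{r} peaks of each list are intersected:
#' \deqn{O(r) = 100 \cdot \tfrac12
#'   \left( \frac{|A_r \cap B_r|_A}{r} + \frac{|A_r \cap B_r|_B}{r} \right)}
#' where \eqn{|A_r \cap B_r|_A} counts top-\code{r} peaks of A overlapping
#' (sharing >= 1 bp with) any top-\code{r} peak of B. The symmetric mean is
#' the default because the two one-directional fractions differ when several
#' peaks of one list hit a single peak of the other; both directions are
#' available for diagnostics.
#'
#' @param a_ranked,b_ranked peak \code{GRanges} already ordered by
#'   \code{\link{rank_peaks}}.
#' @param r rank, \code{1 <= r <= min(length(a), length(b))}.
#' @param direction \code{"symmetric"} (default), \code{"a_in_b"} or
#'   \code{"b_in_a"}.
#' @return percent in \code{[0, 100]}.
#' @export
percent_overlap_at_rank <- function(a_ranked, b_ranked, r,
                                    direction = c("symmetric", "a_in_b",
                                                  "b_in_a")) {
  direction <- match.arg(direction)
  n <- min(length(a_ranked), length(b_ranked))
  if (r < 1 || r > n) stop("rank r = ", r, " outside [1, ", n, "]")
  ta <- utils::head(a_ranked, r); tb <- utils::head(b_ranked, r)
  fa <- sum(count_overlaps_q(ta, tb) > 0) / r
  fb <- sum(count_overlaps_q(tb, ta) > 0) / r
  100 * switch(direction,
               symmetric = (fa + fb) / 2, a_in_b = fa, b_in_a = fb)
}

#' Overlap curve and maximum-overlap cutoff
#'
#' Evaluates \code{\link{percent_overlap_at_rank}} on a grid of ranks and
#' selects the cutoff rank as the smallest rank attaining the maximum percent
#' overlap. The default grid is 50 evenly spaced ranks from 100 (or 1 for
#' short lists) to \code{min(length(a), length(b))}; pass a denser grid
#' starting lower when the expected concordant set may be small.
#'
#' @param a,b peak \code{GRanges} (ranked internally).
#' @param rank_grid increasing integer vector of ranks, or \code{NULL} for the
#'   default grid.
#' @param direction passed to \code{\link{percent_overlap_at_rank}}.
#' @return object of class \code{OverlapCurve}: list with \code{ranks},
#'   \code{percent} and \code{cutoff_rank}.
#' @export
max_overlap_cutoff <- function(a, b, rank_grid = NULL,
                               direction = "symmetric") {
  a <- rank_peaks(a); b <- rank_peaks(b)
  n <- min(length(a), length(b))
  if (n < 1) stop("empty peak list")
  if (is.null(rank_grid))
    rank_grid <- unique(round(seq(min(100, n), n, length.out = 50)))
  rank_grid <- sort(unique(as.integer(rank_grid)))
  if (length(rank_grid) == 0) stop("empty rank grid")
  if (min(rank_grid) < 1 || max(rank_grid) > n)
    stop("rank grid outside [1, ", n, "]")
  # one overlap pass; a peak of A is counted at rank r iff its best-ranked
  # partner in B is within B's top r (and symmetrically), which reproduces
  # percent_overlap_at_rank without re-intersecting per rank
  h <- find_overlaps_q(a, b)
  q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
  best_b <- rep(Inf, length(a)); best_a <- rep(Inf, length(b))
  if (length(q)) {
    agg <- tapply(s, q, min)
    best_b[as.integer(names(agg))] <- agg
    agg <- tapply(q, s, min)
    best_a[as.integer(names(agg))] <- agg
  }
  pct <- vapply(rank_grid, function(r) {
    fa <- sum(best_b[seq_len(r)] <= r) / r
    fb <- sum(best_a[seq_len(r)] <= r) / r
    100 * switch(direction,
                 symmetric = (fa + fb) / 2, a_in_b = fa, b_in_a = fb)
  }, numeric(1))
  structure(list(ranks = rank_grid, percent = pct,
                 cutoff_rank = rank_grid[which.max(pct)]),
            class = "OverlapCurve")
}

#' @export
print.OverlapCurve <- function(x, ...) {
  cat(sprintf("OverlapCurve: %d ranks in [%d, %d]; max overlap %.1f%% at cutoff rank %d\n",
              length(x$ranks), min(x$ranks), max(x$ranks),
              max(x$percent), x$cutoff_rank))
  invisible(x)
}

#' @method as.data.frame OverlapCurve
#' @export
as.data.frame.OverlapCurve <- function(x, ...) {
  data.frame(rank = x$ranks, percent = x$percent,
             is_cutoff = x$ranks == x$cutoff_rank)
}

#' Consensus peaks present in both replicates
#'
#' Cuts both ranked lists at the curve's cutoff rank and keeps every top
#' peak of the reference list A that overlaps at least one top peak of B.
#' Coordinates are taken from A (reference-anchored, keeping a well-defined
#' summit); \code{mode = "union"} instead merges each overlapping A/B pair
#' into its interval union (metadata from A).
#'
#' @param a,b peak \code{GRanges} the curve was computed from.
#' @param curve an \code{OverlapCurve} from \code{\link{max_overlap_cutoff}}.
#' @param mode \code{"reference"} (default) or \code{"union"}.
#' @return peak \code{GRanges}, each reference peak at most once.
#' @export
consensus_peaks <- function(a, b, curve, mode = c("reference", "union")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "OverlapCurve"))
  r <- curve$cutoff_rank
  ta <- utils::head(rank_peaks(a), r); tb <- utils::head(rank_peaks(b), r)
  hit <- count_overlaps_q(ta, tb) > 0
  res <- ta[hit]
  if (mode == "union" && length(res)) {
    summit_pos <- summit_positions(res)
    h <- find_overlaps_q(res, tb)
    lo <- tapply(GenomicRanges::start(tb)[S4Vectors::subjectHits(h)],
                 S4Vectors::queryHits(h), min)
    hi <- tapply(GenomicRanges::end(tb)[S4Vectors::subjectHits(h)],
                 S4Vectors::queryHits(h), max)
    idx <- as.integer(names(lo))
    ns <- pmin(GenomicRanges::start(res)[idx], unname(lo))
    ne <- pmax(GenomicRanges::end(res)[idx], unname(hi))
    res2 <- res
    GenomicRanges::ranges(res2)[idx] <- IRanges::IRanges(ns, ne)
    S4Vectors::mcols(res2)$summit_offset <- as.integer(
      summit_pos - GenomicRanges::start(res2))
    res <- res2
  }
  res
}

#' High-confidence superset across several datasets
#'
#' Keeps the peaks of the reference list that overlap at least one peak in
#' every other list -- the highest-confidence binding regions common to all
#' datasets.
#'
#' @param reference peak \code{GRanges}.
#' @param others list of peak \code{GRanges} (at least one).
#' @return subset of \code{reference}.
#' @export
superset <- function(reference, others) {
  if (!is.list(others) || length(others) == 0)
    stop("others must be a non-empty list of peak sets")
  keep <- rep(TRUE, length(reference))
  for (o in others)
    keep <- keep & count_overlaps_q(reference, o) > 0
  reference[keep]
}
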