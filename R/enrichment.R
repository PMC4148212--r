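## Chromatin-class enrichment of summit windows and pairwise peak-set
## overlap (Venn) counts.

#' Chromatin-class composition and enrichment of peak summits
#'
#' Each peak contributes a summit-centered window (default
#' \code{[summit - 50, summit + 50)} for 100 bp) which is assigned to the
#' chromatin class with the largest base-pair overlap (ties to the first
#' class in RED/YELLOW/BLUE/GREEN/BLACK order). Peak percentages are taken
#' over assigned peaks and compared with the percent of segmented base pairs
#' per class; the enrichment ratio is their quotient.
#'
#' @param peaks peak \code{GRanges}.
#' @param segmentation segmentation \code{GRanges}
#'   (see \code{\link{new_segmentation}}).
#' @param summit_window window width in bp centered on the summit.
#' @return data.frame with \code{class}, \code{n_peaks}, \code{peak_percent},
#'   \code{genome_percent}, \code{enrichment}; attribute \code{n_unassigned}
#'   counts windows outside the segmentation.
#' @export
class_composition <- function(peaks, segmentation, summit_window = 100) {
  if (summit_window <= 0) stop("summit_window must be > 0")
  if (length(segmentation) == 0) stop("empty segmentation")
  half <- floor(summit_window / 2)
  sp <- summit_positions(peaks)                       # 1-based
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(pmax(sp - half, 1), sp - half + summit_window - 1))
  lv <- put_common_levels(win, segmentation)
  win <- lv$a; segmentation <- lv$b
  h <- GenomicRanges::findOverlaps(win, segmentation, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(win[q],
                                                       segmentation[s]))
  lab <- as.integer(S4Vectors::mcols(segmentation)$label[s])
  # per (window, class) overlap bp; assign each window to its max class
  assigned <- rep(NA_integer_, length(peaks))
  if (length(q)) {
    key <- split(seq_along(q), q)
    for (nm in names(key)) {
      rows <- key[[nm]]
      bp <- tapply(ov[rows], lab[rows], sum)
      best <- as.integer(names(bp))[order(-bp, as.integer(names(bp)))][1L]
      assigned[as.integer(nm)] <- best
    }
  }
  n_assigned <- sum(!is.na(assigned))
  if (n_assigned == 0) stop("no summit window overlaps the segmentation")
  peak_n <- tabulate(assigned, nbins = length(CHROMATIN_CLASSES))
  seg_bp <- tapply(GenomicRanges::width(segmentation),
                   S4Vectors::mcols(segmentation)$label, sum, default = 0)
  seg_bp <- as.numeric(seg_bp[CHROMATIN_CLASSES])
  seg_bp[is.na(seg_bp)] <- 0
  peak_pct <- 100 * peak_n / n_assigned
  gen_pct <- 100 * seg_bp / sum(seg_bp)
  res <- data.frame(class = CHROMATIN_CLASSES, n_peaks = peak_n,
                    peak_percent = peak_pct, genome_percent = gen_pct,
                    enrichment = ifelse(gen_pct > 0, peak_pct / gen_pct, NA),
                    stringsAsFactors = FALSE)
  attr(res, "n_unassigned") <- length(peaks) - n_assigned
  res
}

#' Venn overlap counts between two peak sets
#'
#' A peak of A is shared iff it overlaps at least one peak of B and vice
#' versa; both directional shared counts are reported since a peak of one set
#' can span several of the other.
#'
#' @param a,b peak \code{GRanges}.
#' @return list with \code{a_total}, \code{b_total}, \code{a_only},
#'   \code{b_only}, \code{shared_from_a}, \code{shared_from_b}.
#' @export
venn_overlap <- function(a, b) {
  sa <- sum(count_overlaps_q(a, b) > 0)
  sb <- sum(count_overlaps_q(b, a) > 0)
  list(a_total = length(a), b_total = length(b),
       a_only = length(a) - sa, b_only = length(b) - sb,
       shared_from_a = sa, shared_from_b = sb)
}
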