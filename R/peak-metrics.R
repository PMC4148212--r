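## Peak-width statistics, width histograms, 5 kb proximity clustering and
## cross-set width-distribution comparisons.

#' Summary statistics of peak widths
#'
#' Widths come from the interval model (for supplementary-table input the
#' loader already honored the table's width column). Mean and median are
#' rounded to the nearest integer bp, matching the precision at which such
#' statistics are conventionally reported.
#'
#' @param peaks non-empty peak \code{GRanges}.
#' @param threshold width threshold in bp for the "broad peak" count
#'   (strictly greater than).
#' @return list with \code{n}, \code{mean}, \code{median}, \code{max},
#'   \code{count_over_threshold}, \code{fraction_over_threshold}.
#' @export
width_stats <- function(peaks, threshold = 2000) {
  if (length(peaks) == 0) stop("empty peak list")
  w <- GenomicRanges::width(peaks)
  list(n = length(w),
       mean = round(mean(w)),
       median = round(stats::median(w)),
       max = max(w),
       count_over_threshold = sum(w > threshold),
       fraction_over_threshold = sum(w > threshold) / length(w))
}

#' Histogram of peak widths
#'
#' Bin \code{k} counts widths in \code{[k*bin, (k+1)*bin)}; the counts sum to
#' the number of peaks.
#'
#' @param peaks peak \code{GRanges}.
#' @param bin bin width in bp (> 0).
#' @return data.frame with \code{bin_start}, \code{bin_end}, \code{count}
#'   covering bin 0 through the bin of the widest peak.
#' @export
width_histogram <- function(peaks, bin = 100) {
  if (bin <= 0) stop("bin must be > 0")
  w <- GenomicRanges::width(peaks)
  if (length(w) == 0)
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer()))
  k <- floor(w / bin)
  counts <- tabulate(k + 1, nbins = max(k) + 1)
  data.frame(bin_start = (seq_along(counts) - 1) * bin,
             bin_end = seq_along(counts) * bin,
             count = counts)
}

#' Number of other peaks within a window of each peak
#'
#' Distance is the nearest-edge gap (overlapping or touching peaks have
#' distance 0); \code{mode = "center"} uses midpoint-to-midpoint distance
#' instead.
#'
#' @param peaks peak \code{GRanges}.
#' @param window distance cutoff in bp (>= 0), default 5 kb.
#' @param mode \code{"gap"} (default) or \code{"center"}.
#' @return integer vector, one count per peak (self excluded).
#' @export
proximity_counts <- function(peaks, window = 5000, mode = c("gap", "center")) {
  mode <- match.arg(mode)
  if (window < 0) stop("window must be >= 0")
  n <- length(peaks)
  if (n == 0) return(integer(0))
  if (mode == "gap") {
    h <- GenomicRanges::findOverlaps(peaks, peaks, maxgap = window,
                                     ignore.strand = TRUE)
    q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
    tabulate(q[q != s], nbins = n)
  } else {
    mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2
    chr <- as.character(GenomicRanges::seqnames(peaks))
    vapply(seq_len(n), function(i)
      sum(chr == chr[i] & abs(mid - mid[i]) <= window) - 1L, integer(1))
  }
}

#' Compare width distributions across peak sets
#'
#' Per-set summaries (n, mean, median, quantiles) plus the raw widths as a
#' plotting payload for overlay density plots.
#'
#' @param peak_sets named list of peak \code{GRanges} (>= 1 set).
#' @param probs quantile probabilities for the summary table.
#' @return list with \code{summary} (data.frame, one row per set) and
#'   \code{widths} (named list of numeric vectors).
#' @export
width_density_compare <- function(peak_sets,
                                  probs = c(0.05, 0.25, 0.75, 0.95)) {
  if (!is.list(peak_sets) || length(peak_sets) == 0)
    stop("peak_sets must be a non-empty named list")
  if (is.null(names(peak_sets)) || any(names(peak_sets) == ""))
    stop("peak_sets must be named")
  widths <- lapply(peak_sets, GenomicRanges::width)
  rows <- lapply(names(widths), function(nm) {
    w <- widths[[nm]]
    qs <- stats::quantile(w, probs = probs, names = FALSE)
    cbind(data.frame(set = nm, n = length(w), mean = round(mean(w)),
                     median = round(stats::median(w)), max = max(w)),
          stats::setNames(as.data.frame(t(qs)),
                          sprintf("q%02d", round(100 * probs))))
  })
  list(summary = do.call(rbind, rows), widths = widths)
}
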