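## Binned-signal operations: upper-quantile normalization across samples,
## anchored meta-profiles with strand-aware mirroring, width-ordered heatmap
## matrices, and locus profiles for plotting/export.

#' Upper-quantile normalization of binned tracks
#'
#' Each track is scaled by \eqn{s_t = Q_{ref} / Q_t}, where \eqn{Q_t} is the
#' \code{q}-quantile of the track's bin counts (nonzero bins by default --
#' mostly-zero genomes make the raw quantile degenerate) and \eqn{Q_{ref}}
#' the geometric mean of the per-track quantiles, so the reference is
#' symmetric in the samples. After scaling all tracks share the same
#' \code{q}-quantile of (nonzero) bins up to floating-point error.
#'
#' @param tracks named list of \code{\link{binned_track}} objects on the same
#'   bin grid.
#' @param q quantile in (0, 1), default 0.95.
#' @param nonzero_only take the quantile over nonzero bins (default) or all
#'   bins.
#' @return list with \code{tracks} (scaled), \code{factors} and
#'   \code{quantiles} (named numeric vectors).
#' @export
upper_quantile_normalize <- function(tracks, q = 0.95, nonzero_only = TRUE) {
  if (!is.list(tracks) || length(tracks) == 0 || is.null(names(tracks)))
    stop("tracks must be a non-empty named list")
  bs <- unique(vapply(tracks, function(t) t$bin_size, numeric(1)))
  if (length(bs) != 1) stop("tracks are on different bin grids")
  qt <- vapply(tracks, function(t) {
    v <- unlist(t$counts, use.names = FALSE)
    if (nonzero_only) v <- v[v != 0]
    if (length(v) == 0) stop("track has no nonzero bins")
    stats::quantile(v, q, names = FALSE)
  }, numeric(1))
  if (any(qt <= 0)) stop("non-positive quantile; cannot scale")
  qref <- exp(mean(log(qt)))
  s <- qref / qt
  scaled <- mapply(function(t, f) {
    t$counts <- lapply(t$counts, function(v) v * f)
    t
  }, tracks, s, SIMPLIFY = FALSE)
  list(tracks = scaled, factors = s, quantiles = qt)
}

## Anchor extraction shared by meta_profile and heatmap_matrix: returns the
## per-anchor window matrix (rows = usable anchors) plus bookkeeping.
extract_windows <- function(track, chrom, anchor0, flank) {
  bs <- track$bin_size
  if (flank %% bs != 0) stop("flank must be a multiple of bin_size (", bs, ")")
  k <- flank / bs
  abin <- floor(anchor0 / bs)
  nb <- vapply(chrom, function(c) {
    v <- track$counts[[c]]; if (is.null(v)) -1L else length(v)
  }, integer(1))
  usable <- nb >= 0 & abin - k >= 0 & abin + k <= nb - 1
  idx <- which(usable)
  mat <- matrix(NA_real_, nrow = length(idx), ncol = 2 * k + 1)
  for (j in seq_along(idx)) {
    i <- idx[j]
    mat[j, ] <- track$counts[[chrom[i]]][(abin[i] - k):(abin[i] + k) + 1]
  }
  list(matrix = mat, offsets = (-k:k) * bs, used = idx,
       n_dropped = sum(!usable))
}

#' Average signal profile anchored at peaks or TSSs
#'
#' Extracts a window of \code{2*flank/bin_size + 1} bins centered on each
#' anchor (peak summit, or TSS for transcript anchors) and averages over
#' anchors. When \code{strand_source} transcripts are given, each anchor is
#' assigned the strand of its nearest transcript (by summit-TSS distance) and
#' minus-strand windows are mirrored before averaging, so offsets read in the
#' direction of transcription. Anchors whose window leaves the chromosome are
#' dropped and counted.
#'
#' @param track a \code{\link{binned_track}}.
#' @param anchors peak \code{GRanges} (summit-anchored) or transcript
#'   \code{GRanges} (TSS-anchored, detected by a \code{transcript_id} column).
#' @param flank half-window in bp; multiple of the track bin size.
#' @param strand_source optional transcript \code{GRanges} used to orient
#'   peak anchors; transcript anchors use their own strand.
#' @return object of class \code{MetaProfile}: list with \code{offsets} (bp,
#'   bin-centered), \code{profile} (mean per offset), \code{n_used},
#'   \code{n_dropped}.
#' @export
meta_profile <- function(track, anchors, flank = 2000, strand_source = NULL) {
  is_tx <- "transcript_id" %in% names(S4Vectors::mcols(anchors))
  anchor0 <- if (is_tx) tss_positions(anchors) - 1
             else summit_positions(anchors) - 1
  chrom <- as.character(GenomicRanges::seqnames(anchors))
  win <- extract_windows(track, chrom, anchor0, flank)
  if (nrow(win$matrix) == 0) stop("no usable anchors")
  flip <- rep(FALSE, nrow(win$matrix))
  if (is_tx) {
    flip <- as.character(GenomicRanges::strand(anchors))[win$used] == "-"
  } else if (!is.null(strand_source)) {
    ann <- annotate_peaks(anchors[win$used], strand_source)
    std <- as.character(GenomicRanges::strand(strand_source))
    names(std) <- S4Vectors::mcols(strand_source)$transcript_id
    flip <- !is.na(ann$transcript_id) & std[ann$transcript_id] == "-"
  }
  m <- win$matrix
  m[flip, ] <- m[flip, rev(seq_len(ncol(m))), drop = FALSE]
  structure(list(offsets = win$offsets, profile = colMeans(m),
                 n_used = nrow(m), n_dropped = win$n_dropped),
            class = "MetaProfile")
}

#' @export
print.MetaProfile <- function(x, ...) {
  cat("MetaProfile: offsets", min(x$offsets), "..", max(x$offsets), "bp,",
      x$n_used, "anchors used,", x$n_dropped, "dropped\n")
  invisible(x)
}

#' Per-peak signal matrix ordered by peak width
#'
#' Rows are peaks (summit-anchored windows by default, peak centers with
#' \code{anchor = "center"}) ordered by decreasing width, ties by
#' (chromosome, start); columns are offset bins. Column means equal the
#' \code{\link{meta_profile}} of the same anchors without strand mirroring.
#'
#' @param track a \code{\link{binned_track}}.
#' @param peaks peak \code{GRanges}.
#' @param flank half-window in bp (default 500); multiple of the bin size.
#' @param anchor \code{"summit"} or \code{"center"}.
#' @return numeric matrix with peak names as rownames and an \code{offsets}
#'   attribute (bp).
#' @export
heatmap_matrix <- function(track, peaks, flank = 500,
                           anchor = c("summit", "center")) {
  anchor <- match.arg(anchor)
  o <- order(-GenomicRanges::width(peaks),
             as.character(GenomicRanges::seqnames(peaks)),
             GenomicRanges::start(peaks))
  peaks <- peaks[o]
  anchor0 <- if (anchor == "summit") summit_positions(peaks) - 1
             else floor((GenomicRanges::start(peaks) - 1 +
                         GenomicRanges::end(peaks)) / 2)
  win <- extract_windows(track, as.character(GenomicRanges::seqnames(peaks)),
                         anchor0, flank)
  m <- win$matrix
  rownames(m) <- S4Vectors::mcols(peaks)$name[win$used]
  colnames(m) <- win$offsets
  attr(m, "offsets") <- win$offsets
  attr(m, "n_dropped") <- win$n_dropped
  m
}

#' Per-bin values of one or more tracks over a region
#'
#' Returns the exact bin values over a genomic region for each named track;
#' an element that is itself a list of tracks is averaged (replicate mean).
#'
#' @param tracks named list; each element a \code{\link{binned_track}} or a
#'   list of replicate tracks.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open region, within the chromosome.
#' @return data.frame with \code{chrom}, \code{bin_start}, \code{bin_end} and
#'   one value column per track.
#' @export
locus_profile <- function(tracks, chrom, start, end) {
  if (!is.list(tracks) || is.null(names(tracks)))
    stop("tracks must be a named list")
  one <- tracks[[1]]; if (is.list(one) && !inherits(one, "BinnedTrack"))
    one <- one[[1]]
  bs <- one$bin_size
  if (!chrom %in% names(one$chrom_sizes))
    stop("chromosome ", chrom, " not in track")
  size <- one$chrom_sizes[[chrom]]
  if (start < 0 || end > size || start >= end)
    stop("region [", start, ", ", end, ") outside chromosome ", chrom,
         " (size ", size, ")")
  bins <- (floor(start / bs)):(ceiling(end / bs) - 1)
  vals <- lapply(tracks, function(t) {
    if (inherits(t, "BinnedTrack")) t <- list(t)
    reps <- lapply(t, function(tt) tt$counts[[chrom]][bins + 1])
    Reduce(`+`, reps) / length(reps)
  })
  cbind(data.frame(chrom = chrom, bin_start = bins * bs,
                   bin_end = pmin((bins + 1) * bs, size)),
        as.data.frame(vals, optional = TRUE))
}
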