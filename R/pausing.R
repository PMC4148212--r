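## Promoter-proximal RNA polymerase II pausing. The pause ratio of a
## transcript is the density of polymerase signal in the first 250 bp
## downstream of the TSS divided by the density over the remaining gene body;
## values near 1 mean uniform elongation, high values mean a polymerase
## stalled at the promoter.

#' Per-transcript pause ratios
#'
#' For each transcript the TSS window is \code{[TSS, TSS + tss_window)} in
#' the direction of transcription and the gene body the remainder of the
#' transcript. With densities per bp,
#' \deqn{PR = \frac{(c_{tss} + \epsilon)/L_{tss}}
#'                  {(c_{body} + \epsilon)/L_{body}}}
#' where \eqn{\epsilon} is a pseudocount guarding against empty windows
#' (set \code{pseudocount = 0} for the exact density ratio). Transcripts whose
#' body would be shorter than \code{min_body} are marked unusable and carry
#' \code{NA} ratios. Window sums pro-rate partial bins, so uniform coverage
#' gives a ratio of exactly 1.
#'
#' @param track a \code{\link{binned_track}} of polymerase signal.
#' @param transcripts transcript \code{GRanges}.
#' @param tss_window TSS window length in bp (default 250).
#' @param min_body minimum usable gene-body length in bp (default 500).
#' @param pseudocount added to both window counts (default 1).
#' @return data.frame with one row per transcript: \code{transcript_id},
#'   \code{tss_count}, \code{body_count}, \code{body_length},
#'   \code{pause_ratio}, \code{usable}.
#' @export
pause_ratios <- function(track, transcripts, tss_window = 250,
                         min_body = 500, pseudocount = 1) {
  n <- length(transcripts)
  chr <- as.character(GenomicRanges::seqnames(transcripts))
  std <- as.character(GenomicRanges::strand(transcripts))
  s0 <- GenomicRanges::start(transcripts) - 1
  e0 <- GenomicRanges::end(transcripts)
  len <- e0 - s0
  usable <- len > tss_window + min_body & chr %in% names(track$counts)
  tssc <- bodyc <- rep(NA_real_, n)
  pr <- rep(NA_real_, n)
  body_len <- len - tss_window
  for (i in which(usable)) {
    if (std[i] == "+") {
      tssc[i] <- track_window_sum(track, chr[i], s0[i], s0[i] + tss_window)
      bodyc[i] <- track_window_sum(track, chr[i], s0[i] + tss_window, e0[i])
    } else {
      tssc[i] <- track_window_sum(track, chr[i], e0[i] - tss_window, e0[i])
      bodyc[i] <- track_window_sum(track, chr[i], s0[i], e0[i] - tss_window)
    }
    pr[i] <- ((tssc[i] + pseudocount) / tss_window) /
             ((bodyc[i] + pseudocount) / body_len[i])
  }
  data.frame(transcript_id = S4Vectors::mcols(transcripts)$transcript_id,
             tss_count = tssc, body_count = bodyc,
             body_length = ifelse(usable, body_len, NA_real_),
             pause_ratio = pr, usable = usable,
             stringsAsFactors = FALSE)
}

#' Decile classification of pause ratios
#'
#' Usable transcripts are ranked by pause ratio (ties broken by transcript
#' id, so degenerate inputs still split evenly) and divided into
#' \code{n_groups} quantile groups of near-equal size; group
#' \code{n_groups} holds the most-paused transcripts.
#'
#' @param records data.frame from \code{\link{pause_ratios}}.
#' @param n_groups number of quantile groups (default 10).
#' @return the input with an integer \code{decile} column (\code{NA} for
#'   unusable transcripts).
#' @export
pause_deciles <- function(records, n_groups = 10) {
  u <- which(records$usable)
  if (length(u) < n_groups)
    stop("need at least ", n_groups, " usable transcripts, have ", length(u))
  o <- order(records$pause_ratio[u], records$transcript_id[u])
  rank_ <- integer(length(u)); rank_[o] <- seq_along(u)
  records$decile <- NA_integer_
  records$decile[u] <- as.integer(
    floor((rank_ - 1) * n_groups / length(u)) + 1)
  records
}

#' Pause-decile composition of peak-associated transcripts
#'
#' Among transcripts whose TSS is overlapped by a peak (annotation category
#' \code{overlapStart} by default) and that carry a pause decile, the percent
#' falling into each decile; a flat 10 percent per decile means peaks ignore
#' pausing, enrichment in decile 10 means peaks prefer highly paused genes.
#'
#' @param annotation data.frame from \code{\link{annotate_peaks}}.
#' @param decile_records data.frame from \code{\link{pause_deciles}} over the
#'   same transcript set.
#' @param category annotation category defining "peak at TSS".
#' @param n_groups number of deciles in \code{decile_records}.
#' @return data.frame with \code{decile}, \code{n}, \code{percent}
#'   (percentages sum to 100).
#' @export
peak_pause_enrichment <- function(annotation, decile_records,
                                  category = "overlapStart", n_groups = 10) {
  tids <- unique(annotation$transcript_id[annotation$category %in% category])
  dec <- decile_records$decile[match(tids, decile_records$transcript_id)]
  dec <- dec[!is.na(dec)]
  if (length(dec) == 0) stop("no peak-associated usable transcript")
  tab <- tabulate(dec, nbins = n_groups)
  data.frame(decile = seq_len(n_groups), n = tab,
             percent = 100 * tab / sum(tab))
}
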