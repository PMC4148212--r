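# Quadratic brute-force oracles and small random-instance generators.
# Oracles work on plain data frames of 0-based half-open intervals and are
# kept deliberately independent of the package's interval machinery.

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             s = GenomicRanges::start(gr) - 1,
             e = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# all index pairs with >= 1 bp overlap, by definition
bf_overlap_pairs <- function(a, b) {
  A <- gr_to_df(a); B <- gr_to_df(b)
  out <- list()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (A$chrom[i] == B$chrom[j] &&
        max(A$s[i], B$s[j]) < min(A$e[i], B$e[j]))
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(a = integer(), b = integer()))
  m <- do.call(rbind, out)
  df <- data.frame(a = m[, 1], b = m[, 2])
  df[order(df$a, df$b), , drop = FALSE]
}

# per-peak count of other peaks with edge gap <= window
bf_proximity <- function(peaks, window) {
  d <- gr_to_df(peaks)
  n <- nrow(d)
  cnt <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || d$chrom[i] != d$chrom[j]) next
    gap <- max(0, max(d$s[i], d$s[j]) - min(d$e[i], d$e[j]))
    if (gap <= window) cnt[i] <- cnt[i] + 1L
  }
  cnt
}

# scalar nearest-TSS annotation, re-deriving the category rules from scratch
bf_annotate_one <- function(summit1, ps0, pe0, pchrom, tx) {
  cand <- which(tx$chrom == pchrom)
  if (!length(cand)) return(list(category = "unassigned",
                                 transcript_id = NA, distance = NA))
  dists <- abs(summit1 - tx$tss1[cand])
  best_set <- cand[dists == min(dists)]
  best <- best_set[order(tx$tid[best_set])][1]
  d <- if (tx$strand[best] == "+") summit1 - tx$tss1[best]
       else tx$tss1[best] - summit1
  covers <- ps0 <= tx$s[best] && pe0 >= tx$e[best]
  has_tss <- tx$tss1[best] > ps0 && tx$tss1[best] <= pe0
  has_tes <- tx$tes1[best] > ps0 && tx$tes1[best] <= pe0
  within <- ps0 >= tx$s[best] && pe0 <= tx$e[best]
  cat_ <- if (covers) "includeFeature" else if (has_tss) "overlapStart"
    else if (has_tes) "overlapEnd" else if (within) "inside"
    else if (d < 0) "upstream" else "downstream"
  list(category = cat_, transcript_id = tx$tid[best], distance = d)
}

bf_annotate <- function(peaks, transcripts) {
  tx <- gr_to_df(transcripts)
  tx$strand <- as.character(GenomicRanges::strand(transcripts))
  tx$tid <- S4Vectors::mcols(transcripts)$transcript_id
  tx$tss1 <- ifelse(tx$strand == "+", tx$s + 1, tx$e)
  tx$tes1 <- ifelse(tx$strand == "+", tx$e, tx$s + 1)
  pd <- gr_to_df(peaks)
  summit1 <- summit_positions(peaks)
  rows <- lapply(seq_along(peaks), function(i)
    bf_annotate_one(summit1[i], pd$s[i], pd$e[i], pd$chrom[i], tx))
  data.frame(category = vapply(rows, `[[`, character(1), "category"),
             transcript_id = vapply(rows, function(r)
               as.character(r$transcript_id %||% NA), character(1)),
             distance = vapply(rows, function(r)
               as.numeric(r$distance %||% NA), numeric(1)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x[1])) y else x

bf_venn <- function(a, b) {
  p <- bf_overlap_pairs(a, b)
  list(shared_from_a = length(unique(p$a)), shared_from_b = length(unique(p$b)))
}

# random peak set on a compact two-chromosome genome
random_peaks <- function(n, max_pos = 5e5, width_range = c(50, 2000),
                         chroms = c("chrA", "chrB")) {
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  s <- sample.int(max_pos - max(w), n, replace = TRUE)
  new_peaks(sample(chroms, n, replace = TRUE), s, s + w,
            neg_log10_p = round(runif(n, 0, 30), 2))
}

random_transcripts <- function(n, max_pos = 5e5, len_range = c(500, 8000),
                               chroms = c("chrA", "chrB")) {
  l <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  s <- sample.int(max_pos - max(l), n, replace = TRUE)
  new_transcripts(sample(chroms, n, replace = TRUE), s, s + l,
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  transcript_id = sprintf("t%03d", seq_len(n)))
}

# dense random track for signal tests
random_track <- function(chrom_sizes = c(chrA = 5e4), bin_size = 100,
                         lambda = 5) {
  counts <- lapply(chrom_sizes, function(sz)
    rpois(ceiling(sz / bin_size), lambda))
  binned_track(counts, chrom_sizes, bin_size)
}
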