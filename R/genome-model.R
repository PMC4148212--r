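## Core containers and readers/writers. Peaks, transcripts and segmentations
## are GRanges; coordinates on disk are BED-style 0-based half-open, inside
## GRanges 1-based closed. Constructors below take 0-based half-open input
## (the native convention of every format this package reads).

#' Construct a peak set
#'
#' Builds a \code{GRanges} of ChIP-seq peaks with the metadata columns used
#' throughout the package: \code{name}, \code{summit_offset} (bp from the peak
#' start, 0-based), \code{neg_log10_p} and \code{score}.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open coordinates (as in BED/narrowPeak).
#' @param name peak identifiers; generated when \code{NULL}.
#' @param summit_offset integer offset of the summit from \code{start};
#'   defaults to the interval midpoint when \code{NULL} (midpoint rule for
#'   formats that carry no summit).
#' @param neg_log10_p peak significance as \eqn{-\log_{10} p}; 0 when unknown.
#' @param score display score (e.g. narrowPeak column 5).
#' @return \code{GRanges} with the four metadata columns above.
#' @export
new_peaks <- function(chrom, start, end, name = NULL, summit_offset = NULL,
                      neg_log10_p = 0, score = 0) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("peak start < 0")
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop("peak ", bad, ": start >= end (", start[bad], " >= ", end[bad], ")")
  }
  w <- end - start
  if (is.null(summit_offset)) summit_offset <- floor(w / 2)
  summit_offset <- as.integer(summit_offset)
  if (any(summit_offset < 0 | summit_offset >= w))
    stop("summit_offset outside [0, width)")
  neg_log10_p <- rep_len(as.numeric(neg_log10_p), length(start))
  if (any(!is.finite(neg_log10_p)) || any(neg_log10_p < 0))
    stop("neg_log10_p must be finite and >= 0")
  if (is.null(name)) name <- sprintf("peak_%05d", seq_along(start))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  S4Vectors::mcols(gr)$name <- as.character(name)
  S4Vectors::mcols(gr)$summit_offset <- summit_offset
  S4Vectors::mcols(gr)$neg_log10_p <- neg_log10_p
  S4Vectors::mcols(gr)$score <- rep_len(as.numeric(score), length(start))
  gr
}

#' Construct a transcript set
#'
#' @param chrom,start,end as in \code{\link{new_peaks}} (0-based half-open).
#' @param strand \code{"+"} or \code{"-"} per transcript (required; the TSS of
#'   a minus-strand transcript is its last base).
#' @param transcript_id,gene_id identifiers; \code{gene_id} defaults to
#'   \code{transcript_id}.
#' @return stranded \code{GRanges} with \code{transcript_id} and
#'   \code{gene_id} metadata columns.
#' @export
new_transcripts <- function(chrom, start, end, strand, transcript_id,
                            gene_id = transcript_id) {
  if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(start >= end)) stop("transcript start >= end")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                               strand = strand)
  S4Vectors::mcols(gr)$transcript_id <- as.character(transcript_id)
  S4Vectors::mcols(gr)$gene_id <- as.character(gene_id)
  gr
}

#' Transcription start/end sites
#'
#' TSS of a plus-strand transcript is its first base; of a minus-strand
#' transcript its last base (1-based genomic positions, matching the GRanges).
#'
#' @param transcripts stranded \code{GRanges}.
#' @return integer vector of genomic positions.
#' @export
tss_positions <- function(transcripts) {
  ifelse(as.character(GenomicRanges::strand(transcripts)) == "+",
         GenomicRanges::start(transcripts), GenomicRanges::end(transcripts))
}

#' @rdname tss_positions
#' @export
tes_positions <- function(transcripts) {
  ifelse(as.character(GenomicRanges::strand(transcripts)) == "+",
         GenomicRanges::end(transcripts), GenomicRanges::start(transcripts))
}

#' Genomic summit positions of peaks
#'
#' @param peaks peak \code{GRanges} (see \code{\link{new_peaks}}).
#' @return 1-based genomic positions of the summits.
#' @export
summit_positions <- function(peaks) {
  GenomicRanges::start(peaks) + S4Vectors::mcols(peaks)$summit_offset
}

## ---------------------------------------------------------------------------
## BinnedTrack: dense fixed-width per-chromosome count vectors.

#' Fixed-width binned coverage track
#'
#' A dense per-chromosome vector of non-negative counts over a fixed bin grid
#' (default 100 bp), the substrate for normalization, meta-profiles and pause
#' ratios. Bin \code{i} (0-based) covers \code{[i*bin_size, (i+1)*bin_size)}.
#'
#' @param counts named list of numeric vectors, one per chromosome, or
#'   \code{NULL} to build an all-zero track from \code{chrom_sizes}.
#' @param chrom_sizes named vector of chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @return object of class \code{BinnedTrack}.
#' @export
binned_track <- function(counts = NULL, chrom_sizes, bin_size = 100) {
  chrom_sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""))
    stop("chrom_sizes must be named")
  nbins <- ceiling(chrom_sizes / bin_size)
  if (is.null(counts)) {
    counts <- lapply(nbins, function(n) numeric(n))
  } else {
    if (!setequal(names(counts), names(chrom_sizes)))
      stop("counts and chrom_sizes name different chromosomes")
    counts <- counts[names(chrom_sizes)]
    for (chr in names(counts)) {
      if (length(counts[[chr]]) != nbins[[chr]])
        stop("chromosome ", chr, ": expected ", nbins[[chr]], " bins, got ",
             length(counts[[chr]]))
      if (any(counts[[chr]] < 0)) stop("negative counts on ", chr)
    }
  }
  structure(list(bin_size = bin_size, counts = counts,
                 chrom_sizes = chrom_sizes),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  tot <- sum(vapply(x$counts, sum, numeric(1)))
  cat("BinnedTrack:", length(x$counts), "chromosome(s),",
      x$bin_size, "bp bins,", format(tot, big.mark = ","), "total counts\n")
  invisible(x)
}

#' Sum track counts over an interval, pro-rating partial bins
#'
#' Bins are treated as uniform so a window covering half a bin receives half
#' its counts; this makes window sums exact for windows (such as the 250 bp
#' TSS window) that do not align to the bin grid.
#'
#' @param track a \code{\link{binned_track}}.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window.
#' @return numeric scalar.
#' @export
track_window_sum <- function(track, chrom, start, end) {
  v <- track$counts[[chrom]]
  if (is.null(v)) stop("chromosome ", chrom, " not in track")
  bs <- track$bin_size
  start <- max(0, start); end <- min(end, length(v) * bs)
  if (start >= end) return(0)
  i0 <- floor(start / bs); i1 <- ceiling(end / bs) - 1
  idx <- i0:i1
  lo <- pmax(start, idx * bs); hi <- pmin(end, (idx + 1) * bs)
  sum(v[idx + 1] * (hi - lo) / bs)
}

## ---------------------------------------------------------------------------
## Segmentation

#' Construct a five-class chromatin segmentation
#'
#' @param chrom,start,end 0-based half-open intervals; within a chromosome the
#'   intervals must be disjoint.
#' @param label chromatin class per interval, one of
#'   \code{RED, YELLOW, BLUE, GREEN, BLACK} (the five principal chromatin
#'   types of the Drosophila "chromatin colors" model).
#' @return \code{GRanges} with a \code{label} factor column.
#' @export
new_segmentation <- function(chrom, start, end, label) {
  if (any(!label %in% CHROMATIN_CLASSES))
    stop("labels must be one of: ", paste(CHROMATIN_CLASSES, collapse = ", "))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  S4Vectors::mcols(gr)$label <- factor(label, levels = CHROMATIN_CLASSES)
  self <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  if (any(S4Vectors::queryHits(self) != S4Vectors::subjectHits(self)))
    stop("segmentation intervals overlap within a chromosome")
  gr
}

## ---------------------------------------------------------------------------
## Readers

#' Read a peak file
#'
#' Supported formats: ENCODE \code{narrowPeak} (BED6+4, with summit offset and
#' \eqn{-\log_{10} p} columns), plain \code{bed6} (no summit: midpoint rule;
#' no p-value: 0), and \code{table} -- a delimited text export of a
#' supplementary peak table, declared 1-based inclusive and converted on read.
#' For \code{table} input an explicit width column, when mapped, overrides the
#' recomputed \code{end - start + 1} so printed widths are honored verbatim.
#'
#' @param path file path.
#' @param format one of \code{"narrowPeak"}, \code{"bed6"}, \code{"table"}.
#' @param column_map for \code{format = "table"}: named list mapping the
#'   fields \code{chrom, start, end} (required) and optionally
#'   \code{width, name, summit, neg_log10_p, score} to column names in the
#'   file. \code{summit} is an absolute 1-based genomic position.
#' @param sep field separator for \code{format = "table"}.
#' @return peak \code{GRanges} (see \code{\link{new_peaks}}).
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6", "table"),
                       column_map = NULL, sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "table") return(read_peak_table(path, column_map, sep))
  raw <- readLines(path)
  raw <- raw[!grepl("^(track|browser|#)", raw) & nzchar(raw)]
  if (length(raw) == 0) return(new_peaks(character(), numeric(), numeric())[0])
  fields <- strsplit(raw, "\t", fixed = TRUE)
  need <- if (format == "narrowPeak") 10L else 6L
  nf <- lengths(fields)
  if (any(nf < need))
    stop("line ", which(nf < need)[1L], ": expected >= ", need,
         " tab-separated fields, found ", nf[which(nf < need)[1L]])
  get <- function(k) vapply(fields, `[[`, character(1), k)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  if (any(is.na(start) | is.na(end)))
    stop("line ", which(is.na(start) | is.na(end))[1L],
         ": non-numeric coordinates")
  if (any(start >= end))
    stop("line ", which(start >= end)[1L], ": start >= end")
  if (format == "narrowPeak") {
    summit <- suppressWarnings(as.integer(get(10)))
    summit[is.na(summit) | summit < 0] <- NA
    summit[is.na(summit)] <- floor((end - start) / 2)[is.na(summit)]
    nlp <- suppressWarnings(as.numeric(get(8)))
    nlp[is.na(nlp) | nlp < 0] <- 0
    new_peaks(get(1), start, end, name = get(4), summit_offset = summit,
              neg_log10_p = nlp,
              score = suppressWarnings(as.numeric(get(5))))
  } else {
    new_peaks(get(1), start, end, name = get(4),
              score = suppressWarnings(as.numeric(get(5))))
  }
}

read_peak_table <- function(path, column_map, sep) {
  if (is.null(column_map) ||
      !all(c("chrom", "start", "end") %in% names(column_map)))
    stop("format 'table' needs a column_map with at least chrom, start, end")
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(unlist(column_map), names(df))
  if (length(missing_cols))
    stop("columns not in table: ", paste(missing_cols, collapse = ", "))
  col <- function(f) if (f %in% names(column_map)) df[[column_map[[f]]]] else NULL
  start1 <- as.numeric(col("start")); end1 <- as.numeric(col("end"))
  if (any(is.na(start1) | is.na(end1))) stop("non-numeric table coordinates")
  start0 <- start1 - 1          # declared 1-based inclusive
  end0 <- end1
  w <- col("width")
  if (!is.null(w)) end0 <- start0 + as.numeric(w)   # honor printed widths
  summit_abs <- col("summit")
  summit_off <- if (!is.null(summit_abs)) {
    pmin(pmax(as.numeric(summit_abs) - start1, 0), end0 - start0 - 1)
  } else NULL
  nlp <- col("neg_log10_p"); if (is.null(nlp)) nlp <- 0
  sc <- col("score"); if (is.null(sc)) sc <- 0
  nm <- col("name")
  new_peaks(col("chrom"), start0, end0, name = nm,
            summit_offset = summit_off, neg_log10_p = nlp, score = sc)
}

#' Read transcript annotations
#'
#' GTF/GFF3 files are parsed with \pkg{rtracklayer}; records of type
#' \code{transcript} or \code{mRNA} are kept (all records if neither type is
#' present but a \code{transcript_id} attribute is). BED12/BED6 input uses the
#' name column as transcript id. Chromosome names are never rewritten.
#'
#' @param path file path.
#' @param format \code{"gtf"}, \code{"gff3"} or \code{"bed"}.
#' @return transcript \code{GRanges} (see \code{\link{new_transcripts}}).
#' @export
read_transcripts <- function(path, format = c("gtf", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = format)
  if (format %in% c("gtf", "gff3")) {
    mc <- S4Vectors::mcols(gr)
    if ("type" %in% names(mc)) {
      keep <- as.character(mc$type) %in% c("transcript", "mRNA")
      if (any(keep)) gr <- gr[keep]
    }
    mc <- S4Vectors::mcols(gr)
    tid <- if ("transcript_id" %in% names(mc)) mc$transcript_id
           else if ("ID" %in% names(mc)) mc$ID
           else stop("no transcript_id/ID attribute in ", path)
    gid <- if ("gene_id" %in% names(mc)) mc$gene_id else tid
  } else {
    tid <- S4Vectors::mcols(gr)$name
    if (is.null(tid)) stop("BED transcript input needs a name column")
    gid <- tid
  }
  std <- as.character(GenomicRanges::strand(gr))
  if (any(!std %in% c("+", "-")))
    stop("transcript ", which(!std %in% c("+", "-"))[1L],
         ": strand must be '+' or '-'")
  new_transcripts(as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
                  strand = std, transcript_id = as.character(tid),
                  gene_id = as.character(gid))
}

#' Read a bedGraph file into a BinnedTrack
#'
#' Every record must align to the bin grid (start and end multiples of
#' \code{bin_size}) and records must not overlap; regions absent from the file
#' are zero.
#'
#' @param path bedGraph file.
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param bin_size bin width (bp).
#' @return a \code{\link{binned_track}}.
#' @export
read_binned_track <- function(path, chrom_sizes, bin_size = 100) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  tr <- binned_track(NULL, chrom_sizes, bin_size)
  if (length(gr) == 0) return(tr)
  s0 <- GenomicRanges::start(gr) - 1; e0 <- GenomicRanges::end(gr)
  chr <- as.character(GenomicRanges::seqnames(gr))
  if (any(!chr %in% names(chrom_sizes)))
    stop("chromosome not in chrom_sizes: ",
         chr[which(!chr %in% names(chrom_sizes))[1L]])
  # a record may end at the chromosome end even when that is not a bin multiple
  bad <- s0 %% bin_size != 0 |
    (e0 %% bin_size != 0 & e0 != chrom_sizes[chr])
  if (any(bad))
    stop("record ", which(bad)[1L],
         ": interval not aligned to the ", bin_size, " bp bin grid")
  hits <- GenomicRanges::findOverlaps(gr, gr)
  if (any(S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)))
    stop("overlapping bedGraph records")
  val <- S4Vectors::mcols(gr)$score
  for (k in seq_along(gr)) {
    bins <- (s0[k] %/% bin_size):(ceiling(e0[k] / bin_size) - 1) + 1
    tr$counts[[chr[k]]][bins] <- val[k]
  }
  tr
}

## ---------------------------------------------------------------------------
## Writers (plain text; BED-style 0-based half-open on disk)

#' Write peaks to narrowPeak or BED6
#' @param peaks peak \code{GRanges}.
#' @param path output path.
#' @param format \code{"narrowPeak"} or \code{"bed6"}.
#' @export
write_peaks <- function(peaks, path, format = c("narrowPeak", "bed6")) {
  format <- match.arg(format)
  mc <- S4Vectors::mcols(peaks)
  base <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                     start = GenomicRanges::start(peaks) - 1,
                     end = GenomicRanges::end(peaks),
                     name = mc$name, score = mc$score, strand = ".")
  if (format == "narrowPeak")
    base <- cbind(base, signal = 0, p = mc$neg_log10_p, q = -1,
                  summit = mc$summit_offset)
  utils::write.table(base, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a BinnedTrack as bedGraph (nonzero bins only)
#' @param track a \code{\link{binned_track}}.
#' @param path output path.
#' @export
write_binned_track <- function(track, path) {
  bs <- track$bin_size
  rows <- lapply(names(track$counts), function(chr) {
    v <- track$counts[[chr]]
    i <- which(v != 0) - 1
    if (!length(i)) return(NULL)
    data.frame(chrom = chr, start = i * bs,
               end = pmin((i + 1) * bs, track$chrom_sizes[[chr]]),
               score = v[i + 1])
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), score = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write transcripts as GFF3 (round-trips through \code{read_transcripts})
#' @param transcripts transcript \code{GRanges}.
#' @param path output path.
#' @export
write_transcripts <- function(transcripts, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(transcripts)),
                   source = "corepeak", type = "transcript",
                   start = GenomicRanges::start(transcripts),
                   end = GenomicRanges::end(transcripts),
                   score = ".",
                   strand = as.character(GenomicRanges::strand(transcripts)),
                   phase = ".",
                   attr = sprintf("ID=%s;transcript_id=%s;gene_id=%s",
                                  S4Vectors::mcols(transcripts)$transcript_id,
                                  S4Vectors::mcols(transcripts)$transcript_id,
                                  S4Vectors::mcols(transcripts)$gene_id))
  writeLines(c("##gff-version 3",
               do.call(paste, c(df, sep = "\t"))), path)
  invisible(path)
}

#' Write a segmentation as BED4
#' @param segmentation segmentation \code{GRanges}.
#' @param path output path.
#' @export
write_segmentation <- function(segmentation, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(segmentation)),
                   start = GenomicRanges::start(segmentation) - 1,
                   end = GenomicRanges::end(segmentation),
                   label = as.character(S4Vectors::mcols(segmentation)$label))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4 segmentation
#' @param path BED4 file (chrom, start, end, class label).
#' @return segmentation \code{GRanges}.
#' @export
read_segmentation <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("segmentation BED needs 4 columns")
  new_segmentation(df[[1]], df[[2]], df[[3]], df[[4]])
}

## ---------------------------------------------------------------------------

## findOverlaps/countOverlaps over possibly different chromosome sets:
## harmonize seqlevels first so disjoint sets compare cleanly.
put_common_levels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

find_overlaps_q <- function(a, b, ...) {
  x <- put_common_levels(a, b)
  GenomicRanges::findOverlaps(x$a, x$b, ..., ignore.strand = TRUE)
}

count_overlaps_q <- function(a, b) {
  x <- put_common_levels(a, b)
  GenomicRanges::countOverlaps(x$a, x$b, ignore.strand = TRUE)
}

#' All pairs of intervals sharing at least one base pair
#'
#' The overlap primitive used by every other module: a pair \code{(i, j)} is
#' reported iff the two intervals are on the same chromosome and
#' \code{max(startA, startB) < min(endA, endB)} (half-open semantics; strand
#' ignored).
#'
#' @param a,b \code{GRanges}.
#' @return data.frame with integer columns \code{a} and \code{b}, ordered by
#'   \code{(a, b)}.
#' @export
overlap_pairs <- function(a, b) {
  h <- find_overlaps_q(a, b)
  df <- data.frame(a = S4Vectors::queryHits(h), b = S4Vectors::subjectHits(h))
  df[order(df$a, df$b), , drop = FALSE]
}
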