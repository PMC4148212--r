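## Seeded synthetic-data generator. Emits the inputs the analysis assumes --
## two-replicate peak lists with a planted concordant subset and ordered
## p-values, transcript models, Poisson coverage tracks with planted
## promoter-proximal pausing and acetylation dips at peaks, and a five-class
## chromatin segmentation -- together with ground-truth manifests so recovery
## can be scored.

#' Simulation configuration
#'
#' Defaults describe a compact two-chromosome genome with peak widths drawn
#' log-normal around the width scale typical of point-source co-repressor
#' ChIP-seq peaks (median ~700 bp), 200 peaks per replicate of which 60
#' percent are shared, Poisson coverage with a 9-fold planted pause ratio on
#' paused genes, and five equal chromatin classes.
#'
#' @param seed integer seed; all generator functions are deterministic given
#'   the config.
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param bin_size track bin width (bp).
#' @param n_genes number of transcripts to simulate.
#' @param n_peaks peaks per replicate.
#' @param shared_fraction fraction of peaks planted in both replicates.
#' @param width_meanlog,width_sdlog log-normal peak-width parameters.
#' @param jitter maximum jitter (bp) of a shared peak's start and end
#'   between replicates (boundary-call variability).
#' @param summit_noise_sd sd (bp) of the per-replicate perturbation of the
#'   planted summit, which is otherwise held fixed across replicates (summit
#'   estimates are far more reproducible than boundary calls).
#' @param rank_noise_sd sd of the replicate-specific perturbation of
#'   \eqn{-\log_{10} p}, which shuffles ranks between replicates.
#' @param shared_shift,shared_rate shared peaks draw
#'   \eqn{-\log_{10} p \sim} \code{shared_shift} + Exp(\code{shared_rate}),
#'   sitting above the noise peaks' Exp(\code{noise_rate}).
#' @param noise_rate exponential rate for replicate-specific noise peaks.
#' @param noise_cap upper bound on noise-peak \eqn{-\log_{10} p}; keeping it
#'   below \code{shared_shift} makes the shared/noise rank boundary sharp, so
#'   the planted shared count is genuinely encoded in the rank ordering. The
#'   gap between \code{noise_cap} and \code{shared_shift} relative to
#'   \code{rank_noise_sd} controls how much the boundary blurs.
#' @param background_rate background Poisson rate per bin (input and
#'   acetylation baseline).
#' @param rnap_background background rate per bin of the polymerase track;
#'   kept low relative to \code{body_rate} since genic polymerase signal
#'   dominates its background, and a large flat background would shrink
#'   every density ratio toward 1.
#' @param body_rate extra polymerase rate per bin over gene bodies.
#' @param paused_fraction fraction of genes planted as paused.
#' @param pr_paused,pr_unpaused planted pause ratios of the two gene classes.
#' @param tss_peak_fraction fraction of shared peaks planted with their
#'   summit at a transcript TSS (emulating the frequent TSS overlap of
#'   co-repressor peaks).
#' @param tss_peak_paused_fraction fraction of those TSS peaks directed to
#'   planted-paused genes rather than arbitrary genes.
#' @param summit_tss_offset planted summit position downstream of the TSS
#'   (bp, in the direction of transcription).
#' @param acetyl_rate acetylation rate per bin outside peaks.
#' @param acetyl_dip fractional reduction of acetylation inside peak
#'   intervals (0 = no dip).
#' @param class_fractions named genome fractions of the five chromatin
#'   classes (must sum to 1).
#' @param seg_tile segmentation tile length (bp).
#' @return list of class \code{SimulationConfig}.
#' @export
simulation_config <- function(seed = 1,
                              chrom_sizes = c(chr2L = 8e6, chr2R = 8e6),
                              bin_size = 100,
                              n_genes = 300,
                              n_peaks = 200,
                              shared_fraction = 0.6,
                              width_meanlog = log(708),
                              width_sdlog = 0.566,
                              jitter = 100,
                              summit_noise_sd = 8,
                              rank_noise_sd = 1.2,
                              shared_shift = 6,
                              shared_rate = 1,
                              noise_rate = 1,
                              noise_cap = 4,
                              background_rate = 5,
                              rnap_background = 0.5,
                              body_rate = 20,
                              paused_fraction = 0.3,
                              pr_paused = 9,
                              pr_unpaused = 1,
                              tss_peak_fraction = 0.4,
                              tss_peak_paused_fraction = 0.5,
                              summit_tss_offset = 35,
                              acetyl_rate = 20,
                              acetyl_dip = 0.6,
                              class_fractions = stats::setNames(
                                rep(0.2, 5), CHROMATIN_CLASSES),
                              seg_tile = 20000) {
  cfg <- as.list(environment())
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]")
  rates <- c(cfg$background_rate, cfg$body_rate, cfg$acetyl_rate,
             cfg$noise_rate, cfg$shared_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (abs(sum(cfg$class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  if (!setequal(names(cfg$class_fractions), CHROMATIN_CLASSES))
    stop("class_fractions must name the five chromatin classes")
  if (is.null(names(cfg$chrom_sizes))) stop("chrom_sizes must be named")
  class(cfg) <- "SimulationConfig"
  cfg
}

## Run code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

## Draw peak intervals: chromosome proportional to size, start uniform.
draw_intervals <- function(n, chrom_sizes, width_meanlog, width_sdlog) {
  w <- pmin(pmax(round(stats::rlnorm(n, width_meanlog, width_sdlog)), 50),
            5000)
  chr <- sample(names(chrom_sizes), n, replace = TRUE,
                prob = chrom_sizes / sum(chrom_sizes))
  start <- floor(stats::runif(n) * (chrom_sizes[chr] - w))
  list(chrom = chr, start = unname(start), end = unname(start + w))
}

#' Simulate transcript models
#'
#' Transcript lengths are log-normal (median ~3 kb, clamped to
#' \code{[800, 20000]} bp so most are usable for pause ratios) and strands
#' random. Each chromosome is divided into equal slots and one transcript is
#' placed per slot at a random offset, so transcripts never overlap and
#' polymerase rates from neighboring genes do not stack. A logical
#' \code{paused} column plants the paused gene class
#' (\code{paused_fraction}), consumed by \code{\link{simulate_tracks}} and
#' \code{\link{simulate_replicate_peaks}}.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return transcript \code{GRanges} with a \code{paused} metadata column.
#' @export
simulate_transcripts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  with_seed(config$seed + 1L, {
    n <- config$n_genes
    sizes <- config$chrom_sizes
    n_per <- round(n * sizes / sum(sizes))
    n_per[1] <- n - sum(n_per[-1])
    rows <- lapply(names(sizes), function(chr) {
      k <- n_per[[chr]]
      if (k <= 0) return(NULL)
      slot <- sizes[[chr]] / k
      bs <- config$bin_size
      # lengths and starts are snapped to the track bin grid so planted
      # TSS/body rate boundaries are representable at bin resolution
      len <- pmin(pmax(round(stats::rlnorm(k, log(3000), 0.5) / bs) * bs, 800),
                  min(20000, (floor(slot) %/% bs - 1) * bs))
      start <- (seq_len(k) - 1) * slot +
        floor(stats::runif(k) * (slot - len))
      data.frame(chrom = chr, start = (floor(start) %/% bs) * bs, len = len)
    })
    df <- do.call(rbind, rows)
    n <- nrow(df)
    tx <- new_transcripts(df$chrom, df$start, df$start + df$len,
                          strand = sample(c("+", "-"), n, replace = TRUE),
                          transcript_id = sprintf("tx_%04d", seq_len(n)),
                          gene_id = sprintf("g_%04d", seq_len(n)))
    S4Vectors::mcols(tx)$paused <- stats::runif(n) < config$paused_fraction
    tx
  })
}

#' Simulate two replicate peak lists with a planted shared subset
#'
#' Shared peaks appear in both replicates at positions jittered by at most
#' \code{jitter} bp and draw \eqn{-\log_{10} p} from a shifted exponential
#' lying above the replicate-specific noise peaks, so truncating the ranked
#' lists is the correct recovery mechanism; replicate-specific rank noise
#' makes the two orderings disagree below the cutoff, which is what gives the
#' overlap curve its interior maximum. A fraction of the shared peaks
#' (\code{tss_peak_fraction}) is planted with its summit
#' \code{summit_tss_offset} bp downstream of a transcript TSS, preferring
#' planted-paused genes (\code{tss_peak_paused_fraction}), emulating
#' co-repressor recruitment at paused promoters; the rest are placed
#' uniformly.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param transcripts transcript \code{GRanges} from
#'   \code{\link{simulate_transcripts}} (regenerated from the config when
#'   omitted, so the default is self-consistent); set
#'   \code{transcripts = NULL} to disable TSS planting.
#' @return list with \code{rep1}, \code{rep2} (peak \code{GRanges}) and
#'   \code{truth}, a data.frame naming the planted shared peaks in each
#'   replicate (rep1 coordinates) with their planted TSS target (if any).
#' @export
simulate_replicate_peaks <- function(config,
                                     transcripts = simulate_transcripts(config)) {
  stopifnot(inherits(config, "SimulationConfig"))
  mean_w <- exp(config$width_meanlog + config$width_sdlog^2 / 2)
  if (config$n_peaks * mean_w > 0.5 * sum(config$chrom_sizes))
    stop("peak demand exceeds genome capacity")
  with_seed(config$seed, {
    n <- config$n_peaks
    ns <- round(config$shared_fraction * n)
    nn <- n - ns
    sh <- draw_intervals(ns, config$chrom_sizes,
                         config$width_meanlog, config$width_sdlog)
    target <- rep(NA_character_, ns)
    if (!is.null(transcripts) && length(transcripts) > 0 && ns > 0) {
      n_tss <- round(config$tss_peak_fraction * ns)
      n_paused <- round(config$tss_peak_paused_fraction * n_tss)
      paused_idx <- which(S4Vectors::mcols(transcripts)$paused)
      other_idx <- which(!S4Vectors::mcols(transcripts)$paused)
      pick <- c(sample(paused_idx, min(n_paused, length(paused_idx))),
                sample(other_idx, min(n_tss - min(n_paused, length(paused_idx)),
                                      length(other_idx))))
      for (k in seq_along(pick)) {
        t_ <- pick[k]
        tss0 <- tss_positions(transcripts[t_]) - 1
        dir <- if (as.character(GenomicRanges::strand(transcripts[t_])) == "+")
          1 else -1
        summit0 <- tss0 + dir * config$summit_tss_offset
        w <- sh$end[k] - sh$start[k]
        sh$chrom[k] <- as.character(GenomicRanges::seqnames(transcripts[t_]))
        sh$start[k] <- max(0, summit0 - floor(w / 2))
        sh$end[k] <- sh$start[k] + w
        target[k] <- S4Vectors::mcols(transcripts)$transcript_id[t_]
      }
    }
    base <- config$shared_shift + stats::rexp(ns, config$shared_rate)
    # planted summit: the TSS-offset point for TSS peaks, the midpoint
    # otherwise; replicates jitter the peak BOUNDARIES (call variability)
    # while the summit, the point of maximal signal, stays nearly fixed
    summit0 <- floor((sh$start + sh$end) / 2)
    reps <- lapply(1:2, function(r) {
      jit1 <- round(stats::runif(ns, -config$jitter, config$jitter))
      jit2 <- round(stats::runif(ns, -config$jitter, config$jitter))
      s_noise <- round(stats::rnorm(ns, 0, config$summit_noise_sd))
      nz <- draw_intervals(nn, config$chrom_sizes,
                           config$width_meanlog, config$width_sdlog)
      p_sh <- pmax(0.01, base + stats::rnorm(ns, 0, config$rank_noise_sd))
      p_nz <- pmin(stats::rexp(nn, config$noise_rate), config$noise_cap)
      start <- pmax(0, sh$start + jit1)
      end <- pmax(sh$end + jit2, start + 50)
      soff <- pmin(pmax(summit0 + s_noise - start, 0), end - start - 1)
      chrom <- c(sh$chrom, nz$chrom)
      nm <- c(if (ns > 0) sprintf("r%d_shared_%04d", r, seq_len(ns)),
              if (nn > 0) sprintf("r%d_noise_%04d", r, seq_len(nn)))
      new_peaks(chrom, c(start, nz$start), c(end, nz$end), name = nm,
                summit_offset = c(soff,
                                  floor((nz$end - nz$start) / 2)),
                neg_log10_p = c(p_sh, p_nz))
    })
    truth <- data.frame(name_rep1 = sprintf("r1_shared_%04d", seq_len(ns)),
                        name_rep2 = sprintf("r2_shared_%04d", seq_len(ns)),
                        chrom = sh$chrom, start = sh$start, end = sh$end,
                        summit = summit0,
                        target_transcript = target,
                        neg_log10_p_base = base,
                        stringsAsFactors = FALSE)
    list(rep1 = reps[[1]], rep2 = reps[[2]], truth = truth)
  })
}

## Add `rate` (per bin) over the 0-based interval [start, end), pro-rating
## partial bins.
add_rate <- function(v, bin_size, start, end, rate) {
  start <- max(0, start); end <- min(end, length(v) * bin_size)
  if (start >= end) return(v)
  i0 <- floor(start / bin_size); i1 <- ceiling(end / bin_size) - 1
  idx <- i0:i1
  lo <- pmax(start, idx * bin_size); hi <- pmin(end, (idx + 1) * bin_size)
  v[idx + 1] <- v[idx + 1] + rate * (hi - lo) / bin_size
  v
}

#' Simulate coverage tracks with planted pausing and acetylation dips
#'
#' Counts are Poisson per bin (no overdispersion; pass
#' \code{dispersion} to switch to negative-binomial draws with that size
#' parameter, since real ChIP-seq counts are overdispersed). The polymerase
#' track receives the background everywhere, \code{body_rate} per bin over
#' gene bodies and \code{PR * body_rate} over the 250 bp TSS window, where PR
#' is \code{pr_paused} for the planted paused genes and \code{pr_unpaused}
#' otherwise. The acetylation track runs at \code{acetyl_rate} scaled down by
#' \code{1 - acetyl_dip} inside peak intervals; the input track is background
#' only.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param transcripts transcript \code{GRanges} on the simulated genome.
#' @param peaks peak \code{GRanges} on the simulated genome.
#' @param tss_window TSS window length (bp), matching the pause-ratio window.
#' @param dispersion \code{NULL} for Poisson (default) or a negative-binomial
#'   size parameter.
#' @return list with \code{rnap}, \code{acetyl}, \code{input}
#'   (\code{\link{binned_track}}s) and \code{truth} (data.frame
#'   \code{transcript_id}, \code{paused}, \code{pr_target}).
#' @export
simulate_tracks <- function(config, transcripts, peaks, tss_window = 250,
                            dispersion = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  bs <- config$bin_size
  with_seed(config$seed + 2L, {
    nbins <- ceiling(config$chrom_sizes / bs)
    zero <- lapply(nbins, numeric)
    rnap <- lapply(zero, function(v) v + config$rnap_background)
    acet <- lapply(zero, function(v) v + config$acetyl_rate)
    inp <- lapply(zero, function(v) v + config$background_rate)

    n <- length(transcripts)
    paused <- S4Vectors::mcols(transcripts)$paused
    if (is.null(paused)) paused <- stats::runif(n) < config$paused_fraction
    pr <- ifelse(paused, config$pr_paused, config$pr_unpaused)
    chr <- as.character(GenomicRanges::seqnames(transcripts))
    std <- as.character(GenomicRanges::strand(transcripts))
    s0 <- GenomicRanges::start(transcripts) - 1
    e0 <- GenomicRanges::end(transcripts)
    for (i in seq_len(n)) {
      if (!chr[i] %in% names(rnap)) next
      tw <- if (std[i] == "+") c(s0[i], min(s0[i] + tss_window, e0[i]))
            else c(max(e0[i] - tss_window, s0[i]), e0[i])
      body <- if (std[i] == "+") c(tw[2], e0[i]) else c(s0[i], tw[1])
      rnap[[chr[i]]] <- add_rate(rnap[[chr[i]]], bs, body[1], body[2],
                                 config$body_rate)
      rnap[[chr[i]]] <- add_rate(rnap[[chr[i]]], bs, tw[1], tw[2],
                                 pr[i] * config$body_rate)
    }
    pchr <- as.character(GenomicRanges::seqnames(peaks))
    ps0 <- GenomicRanges::start(peaks) - 1
    pe0 <- GenomicRanges::end(peaks)
    for (i in seq_along(peaks)) {
      if (!pchr[i] %in% names(acet)) next
      acet[[pchr[i]]] <- add_rate(acet[[pchr[i]]], bs, ps0[i], pe0[i],
                                  -config$acetyl_dip * config$acetyl_rate)
    }
    acet <- lapply(acet, function(v) pmax(v, 0))

    draw <- function(rates) {
      counts <- lapply(rates, function(mu) {
        if (is.null(dispersion)) stats::rpois(length(mu), mu)
        else stats::rnbinom(length(mu), size = dispersion, mu = mu)
      })
      binned_track(counts, config$chrom_sizes, bs)
    }
    list(rnap = draw(rnap), acetyl = draw(acet), input = draw(inp),
         truth = data.frame(
           transcript_id = S4Vectors::mcols(transcripts)$transcript_id,
           paused = paused, pr_target = pr, stringsAsFactors = FALSE))
  })
}

#' Simulate a five-class chromatin segmentation
#'
#' Tiles each chromosome with fixed-length segments and assigns tiles (in a
#' seed-shuffled order) greedily to the class with the largest remaining
#' base-pair deficit, so realized genome fractions land within a tile length
#' of the requested fractions.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return segmentation \code{GRanges}.
#' @export
simulate_segmentation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (abs(sum(config$class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  fr <- config$class_fractions[CHROMATIN_CLASSES]
  with_seed(config$seed + 3L, {
    tiles <- do.call(rbind, lapply(names(config$chrom_sizes), function(chr) {
      size <- config$chrom_sizes[[chr]]
      s <- seq(0, size - 1, by = config$seg_tile)
      data.frame(chrom = chr, start = s, end = pmin(s + config$seg_tile, size))
    }))
    total <- sum(tiles$end - tiles$start)
    deficit <- fr * total
    ord <- sample.int(nrow(tiles))
    lab <- character(nrow(tiles))
    for (i in ord) {
      k <- which.max(deficit)
      lab[i] <- CHROMATIN_CLASSES[k]
      deficit[k] <- deficit[k] - (tiles$end[i] - tiles$start[i])
    }
    new_segmentation(tiles$chrom, tiles$start, tiles$end, lab)
  })
}
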