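## End-to-end orchestration: simulate (or load) inputs, then run
## concordance -> superset -> widths -> annotate -> profile -> pause ->
## enrich, writing tab-separated tables with provenance headers. A
## "tables-only" mode runs just the peak-table stages when no coverage
## tracks are available.

pkg_version <- function() {
  as.character(utils::packageVersion("corepeak"))
}

write_tsv_prov <- function(df, path, inputs, params) {
  hdr <- c(sprintf("# corepeak %s", pkg_version()),
           sprintf("# input: %s", inputs),
           sprintf("# param: %s", params))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_pipeline_config <- function(cfg) {
  required <- c("mode", "outdir")
  allowed <- c(required, "seed", "sim", "peaks", "rep_a", "rep_b", "others",
               "transcripts", "tracks", "segmentation", "rank_grid",
               "flank", "width_threshold", "hist_bin", "cluster_window",
               "tss_window", "min_body", "uq_quantile", "summit_window")
  missing <- setdiff(required, names(cfg))
  unknown <- setdiff(names(cfg), allowed)
  if (length(missing) || length(unknown))
    stop("config schema violation; missing keys: [",
         paste(missing, collapse = ", "), "]; unknown keys: [",
         paste(unknown, collapse = ", "), "]")
  if (!cfg$mode %in% c("simulate", "tables-only", "files"))
    stop("mode must be one of simulate, tables-only, files")
  for (f in intersect(c("rep_a", "rep_b", "transcripts", "segmentation"),
                      names(cfg)))
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("missing file: ", cfg[[f]])
  cfg
}

#' Run the full analysis pipeline
#'
#' In \code{mode = "simulate"} all inputs are generated by the synthetic-data
#' module under the config seed; in \code{mode = "files"} they are read from
#' the paths in the config; \code{mode = "tables-only"} runs only the stages
#' that need peak tables (concordance/superset/widths/venn), for the case
#' where coverage tracks are unavailable. Every output table carries a
#' provenance header (package version, inputs, parameters). Given the same
#' config and seed the run is deterministic.
#'
#' @param config path to a YAML file or a named list. Keys: \code{mode},
#'   \code{outdir}, \code{seed}, optional \code{sim} (overrides for
#'   \code{\link{simulation_config}}), input paths (\code{rep_a},
#'   \code{rep_b}, \code{transcripts}, \code{segmentation}) and stage
#'   parameters (\code{rank_grid}, \code{flank}, \code{width_threshold},
#'   \code{hist_bin}, \code{cluster_window}, \code{tss_window},
#'   \code{min_body}, \code{uq_quantile}, \code{summit_window}).
#' @return invisibly, a named list of the result objects (also written as
#'   TSV under \code{outdir}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing file: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  log_ <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_ <<- c(log_, msg)
    message("[corepeak] ", msg)
  }

  if (cfg$mode == "simulate") {
    sim_args <- c(list(seed = seed), cfg$sim)
    scfg <- do.call(simulation_config, sim_args)
    say("simulating inputs (seed ", seed, ")")
    pk <- simulate_replicate_peaks(scfg)
    tx <- simulate_transcripts(scfg)
    seg <- simulate_segmentation(scfg)
    rep_a <- pk$rep1; rep_b <- pk$rep2
    trk <- NULL
  } else {
    rep_a <- read_peaks(cfg$rep_a, format = "narrowPeak")
    rep_b <- read_peaks(cfg$rep_b, format = "narrowPeak")
    tx <- if (!is.null(cfg$transcripts))
      read_transcripts(cfg$transcripts, format = "gff3") else NULL
    seg <- if (!is.null(cfg$segmentation))
      read_segmentation(cfg$segmentation) else NULL
    scfg <- NULL
  }

  grid <- if (!is.null(cfg$rank_grid)) cfg$rank_grid else NULL
  inputs_tag <- if (cfg$mode == "simulate")
    sprintf("simulated(seed=%d)", seed)
  else paste(cfg$rep_a, cfg$rep_b, sep = ",")

  say("concordance on ", length(rep_a), " + ", length(rep_b), " peaks")
  curve <- max_overlap_cutoff(rep_a, rep_b, rank_grid = grid)
  cons <- consensus_peaks(rep_a, rep_b, curve)
  sup <- superset(cons, list(rep_b))
  write_tsv_prov(as.data.frame(curve), file.path(cfg$outdir, "curve.tsv"),
                 inputs_tag, sprintf("cutoff_rank=%d", curve$cutoff_rank))
  write_peaks(cons, file.path(cfg$outdir, "consensus.narrowPeak"))
  write_peaks(sup, file.path(cfg$outdir, "superset.narrowPeak"))

  thr <- if (is.null(cfg$width_threshold)) 2000 else cfg$width_threshold
  ws <- width_stats(cons, threshold = thr)
  wh <- width_histogram(cons, bin = if (is.null(cfg$hist_bin)) 100
                        else cfg$hist_bin)
  prox <- proximity_counts(cons, window = if (is.null(cfg$cluster_window))
                           5000 else cfg$cluster_window)
  write_tsv_prov(as.data.frame(ws), file.path(cfg$outdir, "width_stats.tsv"),
                 inputs_tag, sprintf("threshold=%d", thr))
  write_tsv_prov(wh, file.path(cfg$outdir, "width_histogram.tsv"),
                 inputs_tag, "bins")
  write_tsv_prov(data.frame(peak = S4Vectors::mcols(cons)$name,
                            neighbors = prox),
                 file.path(cfg$outdir, "proximity.tsv"), inputs_tag,
                 "window")
  vn <- venn_overlap(rep_a, rep_b)
  write_tsv_prov(as.data.frame(vn), file.path(cfg$outdir, "venn.tsv"),
                 inputs_tag, "overlap>=1bp")

  res <- list(curve = curve, consensus = cons, superset = sup,
              width_stats = ws, width_histogram = wh, proximity = prox,
              venn = vn)

  if (cfg$mode != "tables-only" && !is.null(tx)) {
    say("annotating ", length(cons), " consensus peaks against ",
        length(tx), " transcripts")
    ann <- annotate_peaks(cons, tx)
    comp <- category_composition(ann)
    write_tsv_prov(ann, file.path(cfg$outdir, "annotation.tsv"),
                   inputs_tag, "nearest_by=summit")
    write_tsv_prov(comp, file.path(cfg$outdir, "categories.tsv"),
                   inputs_tag, "nearest_by=summit")
    res$annotation <- ann
    res$categories <- comp
  }

  if (cfg$mode == "simulate") {
    say("simulating tracks and computing profiles / pausing")
    trk <- simulate_tracks(scfg, tx, cons)
    q <- if (is.null(cfg$uq_quantile)) 0.95 else cfg$uq_quantile
    norm <- upper_quantile_normalize(list(rnap = trk$rnap,
                                          acetyl = trk$acetyl,
                                          input = trk$input), q = q)
    flank <- if (is.null(cfg$flank)) 2000 else cfg$flank
    prof <- meta_profile(norm$tracks$acetyl, cons, flank = flank,
                         strand_source = tx)
    write_tsv_prov(data.frame(offset = prof$offsets, mean = prof$profile),
                   file.path(cfg$outdir, "profile_acetyl.tsv"),
                   inputs_tag, sprintf("flank=%d,uq=%g", flank, q))
    pr <- pause_ratios(norm$tracks$rnap, tx,
                       tss_window = if (is.null(cfg$tss_window)) 250
                       else cfg$tss_window,
                       min_body = if (is.null(cfg$min_body)) 500
                       else cfg$min_body)
    pr <- pause_deciles(pr)
    enr <- peak_pause_enrichment(res$annotation, pr)
    write_tsv_prov(pr, file.path(cfg$outdir, "pause.tsv"), inputs_tag,
                   "tss_window=250,min_body=500,pseudocount=1")
    write_tsv_prov(enr, file.path(cfg$outdir, "pause_enrichment.tsv"),
                   inputs_tag, "category=overlapStart")
    res$normalization <- norm
    res$profile <- prof
    res$pause <- pr
    res$pause_enrichment <- enr
  }

  if (!is.null(seg)) {
    say("chromatin-class enrichment")
    cc <- class_composition(cons, seg,
                            summit_window = if (is.null(cfg$summit_window))
                              100 else cfg$summit_window)
    write_tsv_prov(cc, file.path(cfg$outdir, "class_enrichment.tsv"),
                   inputs_tag, "summit_window")
    res$class_enrichment <- cc
  }

  writeLines(log_, file.path(cfg$outdir, "run_log.txt"))
  say("done; outputs in ", cfg$outdir)
  invisible(res)
}
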