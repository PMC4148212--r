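# corepeak

Downstream analysis of co-repressor ChIP-seq experiments in R.

Co-repressors such as Groucho/TLE do not bind DNA themselves; they are
recruited by sequence-specific transcription factors, and profiling them by
ChIP-seq raises a characteristic set of downstream questions once reads are
aligned and peaks are called. Are the binding events discrete point-source
peaks or multi-kilobase spreading domains? How concordant are biological
replicates, and which peaks are reproducible? Where do peaks sit relative
to transcription start sites (TSSs), and in which chromatin classes? Do the
bound promoters show RNA polymerase II promoter-proximal pausing?
`corepeak` implements that analysis layer for computational biologists
working from called peaks (narrowPeak/BED), transcript models (GTF/GFF3),
binned coverage (bedGraph, 100 bp bins) and five-class chromatin
segmentations (BED4).

## The core procedures

**Replicate concordance by maximum percent overlap.** Both replicates' peak
lists are ranked by significance (descending −log₁₀ *p*, positional
tie-break) and, for each rank *r* on a grid, the percent overlap between
the two top-*r* lists is

> O(r) = 100 · ½ · ( |{a ∈ Aᵣ overlapping Bᵣ}| / r + |{b ∈ Bᵣ overlapping Aᵣ}| / r )

with overlap meaning ≥ 1 shared bp. O(r) rises while the replicate rankings
disagree, peaks at the reproducible set, and falls as irreproducible calls
enter; the smallest rank attaining the maximum is the cutoff, and the
consensus list is the reference replicate's top-r\* overlapping the other's
top-r\*. A `superset()` across more than two datasets keeps reference peaks
present in every other set.

**Peak geometry.** Width statistics and 100 bp width histograms,
counts of peaks above a width threshold (default 2 kb), and clustering as
the number of other peaks within 5 kb (nearest-edge gap).

**Annotation.** Each peak is assigned to the transcript with the nearest
TSS to its summit; the signed distance is strand-adjusted (positive
downstream in the direction of transcription) and the category is one of
`includeFeature`, `overlapStart`, `overlapEnd`, `inside`, `upstream`,
`downstream`.

**Signal.** Upper-quantile normalization across tracks (0.95 quantile of
nonzero bins, geometric-mean reference), summit- or TSS-anchored
meta-profiles with strand-aware mirroring, width-ordered heatmap matrices,
and locus profiles.

**Pausing.** Per-transcript pause ratios — signal density over the first
250 bp downstream of the TSS divided by density over the remaining gene
body — with decile classification and the decile composition of
peak-associated promoters.

**Enrichment.** Chromatin-class composition of 100 bp summit windows versus
the genomic base-pair composition, and directional Venn overlap counts
between peak sets.

**Simulation.** A seeded generator (`simulation_config()`,
`simulate_replicate_peaks()`, `simulate_transcripts()`,
`simulate_tracks()`, `simulate_segmentation()`) produces all inputs with
planted ground truth: a shared peak subset with ordered p-values, peaks
planted at TSSs of paused genes, Poisson coverage with planted pause
ratios and acetylation dips at peaks, and a five-class segmentation.

See the methods vignette (`vignettes/corepeak-methods.Rmd`) for the models,
conventions, parameter defaults, and known limitations.

## Worked example

Simulate a two-replicate experiment with 60% planted shared peaks, run the
concordance procedure, and characterize the consensus peaks:

```r
library(corepeak)

cfg <- simulation_config(seed = 1, shared_fraction = 0.6)
tx  <- simulate_transcripts(cfg)
pk  <- simulate_replicate_peaks(cfg, tx)

curve <- max_overlap_cutoff(pk$rep1, pk$rep2, rank_grid = seq(10, 200, by = 2))
curve
#> OverlapCurve: 96 ranks in [10, 200]; max overlap 98.3% at cutoff rank 118

cons <- consensus_peaks(pk$rep1, pk$rep2, curve)
length(cons)          # 116 peaks recovered of 120 planted shared peaks
#> [1] 116

str(width_stats(cons, threshold = 2000))
#> List of 6
#>  $ n                      : int 116
#>  $ mean                   : num 849
#>  $ median                 : num 740
#>  $ max                    : int 2864
#>  $ count_over_threshold   : int 3
#>  $ fraction_over_threshold: num 0.0259

category_composition(annotate_peaks(cons, tx))
#>         category  n percent
#> 1 includeFeature  0    0.00
#> 2   overlapStart 49   42.24
#> 3     overlapEnd  3    2.59
#> 4         inside  2    1.72
#> 5       upstream 35   30.17
#> 6     downstream 27   23.28
```

Reading the output: the overlap curve peaks at rank 118, within 2% of the
120 planted shared peaks; the consensus widths (mean 849 bp, median 740 bp,
2.6% over 2 kb) reflect the generator's point-source width distribution;
and 42% of consensus peaks overlap a TSS, matching the planted 40% TSS
fraction. `run_pipeline()` chains all stages (concordance → superset →
widths → annotation → profiles → pausing → enrichment) from a YAML or list
config and writes provenance-headed TSV tables; `inst/scripts/corepeak` is
a thin command-line wrapper over the same functions.

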