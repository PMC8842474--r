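# lclear

Coverage-reliability filtering and differential-expression bias
diagnostics for limiting-cell RNA-seq.

## The problem

Sequencing the transcriptome of rare cell populations — a few hundred
FACS-isolated cells, or RNA input diluted to ~10–100 pg — produces
libraries in which low-abundance transcripts are captured incompletely and
partially degraded. The failure has a spatial signature: as a transcript's
abundance drops, its read coverage stops being uniform along the
transcript body and piles up at the 5' and 3' ends. Counts for such
transcripts are unreliable; keeping them inflates replicate-to-replicate
variability (CV) and distorts differential-expression (DE) calls. A
related problem is platform bias: the single-cell DE convention (Wilcoxon
rank-sum on log-normalized values, Bonferroni over all features, small
fold-change threshold) and the bulk convention (negative-binomial Wald
test, BH FDR, |log2FC| ≥ 1) detect systematically different kinds of
genes from the same biology — high-count/moderate-fold-change versus
moderate-count/high-fold-change.

`lclear` is for analysts working in this low-input regime. It provides:

* **The positional-mean statistic and reliability filter.** For each
  transcript, μ = Σ d·x / Σ d with x = (p − 0.5)/L — the depth-weighted
  mean position of coverage, normalized to transcript length: 0.5 for
  uniform coverage, pushed toward 0/1 by end pile-up. Transcripts are
  ordered by expression and cut into bins of 250 μ values; each bin is
  fitted by EM to the two-parameter beta mixture
  `w·Beta(a, a) + (1 − w)·Beta(0.5, 0.5)` (intact, centre-peaked vs
  degraded, end-piled). Both free parameters are isotonically smoothed
  down the expression ranking and thresholded (w ≥ 0.5, a ≥ 2); genes
  above the first failing bin pass, and only genes passing in all samples
  are analysed downstream.
* **Two DE engines** (Wilcoxon/Bonferroni and a simplified NB Wald/BH,
  both calibration-tested on null simulations) and a random-assignment
  permutation null.
* **Bias diagnostics**: count-rank distributions of DEGs vs non-DEGs,
  fold-change comparisons, set-overlap accounting with explicit
  denominators, and replicate-CV summaries before/after filtering.
* **Seeded simulators** for degradation-biased coverage (valid
  BedGraph + GTF), input-level-dependent bulk counts and capture-thinned
  single-cell counts sharing one DEG ground truth.

## Worked example

Simulate a 1000-gene ground truth, coverage with a degradation transition,
filter it, and call DEGs on filtered 100 pg-analogue counts:

```r
library(lclear)

truth  <- simulateTruth(nGenes = 1000, degFraction = 0.1, seed = 7)
sim    <- simulateCoverage(truth, seed = 8)        # BedGraph + GTF + truth
models <- readTranscriptModels(sim$gtf)
cov    <- readCoverage(sim$bedgraph)
stats  <- coverageTable(models, cov)
head(stats, 3)
#>   transcript_id expression        mu detected
#> 1         g0949    4676800 0.4991259     TRUE
#> 2         g0744    4638900 0.5021914     TRUE
#> 3         g0263    3378700 0.5002440     TRUE

clear <- clearFilter(stats, sampleId = "rep1")
clear
#> ClearResult 'rep1': 4 bins, 500 transcripts pass
#> cutoff at bin 3 (expression cutoff 5.28e+04)
as.data.frame(binFits(clear))[, c("bin", "n", "w", "a")]
#>   bin   n         w          a
#> 1   1 250 1.0000000 499.999946
#> 2   2 250 1.0000000  23.382438
#> 3   3 250 1.0000000   1.794127
#> 4   4 250 0.9999999   1.220182
```

High-expression bins fit a sharply centre-peaked intact component
(a in the tens to hundreds); below the degradation transition the best
"intact" component collapses toward uniform (a ≈ 1.2–1.8) — no genuinely
intact population left — and those bins fail the shape threshold, so the
500 transcripts above the cutoff pass.

```r
bulk <- simulateBulkCounts(truth, "lvl_100pg", nReplicates = 3, seed = 9)
bulk <- applyGeneFilter(bulk, passIds(clear))
sf   <- medianOfRatios(bulk, pseudoReference = TRUE)
deg  <- nbWaldDEG(bulk, sf, estimateDispersionsNB(bulk, sf))
sum(deg$is_deg)
#> [1] 38
head(deg[deg$is_deg, c("gene", "mean_A", "mean_B", "log2fc", "p_adj")], 3)
#>     gene    mean_A    mean_B   log2fc        p_adj
#> 37 g0062  67.59393  179.3593 1.401364 6.098886e-04
#> 43 g0068 405.56359 1293.3618 1.671923 2.245955e-06
#> 46 g0071 107.95342  454.1576 2.067777 7.744062e-09
```

38 of the 100 planted DEGs are recovered at this input level (3 vs 3
replicates, |log2FC| ≥ 1, q < 0.05); the calls are genuine spikes, e.g.
`g0062` roughly triples between groups. Filtering also improves
reproducibility — the median replicate CV at this level drops from 0.279
(unfiltered) to 0.250 (filter-restricted):

```r
cvRaw <- cvReport(bulk <- simulateBulkCounts(truth, "lvl_100pg", 3, seed = 9))
cvFil <- cvReport(bulk, clearSet = passIds(clear))
round(c(raw = median(cvRaw$median_cv), filtered = median(cvFil$median_cv)), 3)
#>      raw filtered
#>    0.279    0.250
```

`runWorkflow()` composes all stages from one YAML/list config and
`writeReport()` serializes the bundle (JSON summary + TSV tables);
`inst/scripts/lclear.R` wraps them for shell use with exit codes
0/1/2 (success / analysis failure / config error).

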