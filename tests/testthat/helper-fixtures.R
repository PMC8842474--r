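# fixture builders shared across test files; heavyweight simulations are
# memoized so several test files can reuse one run

writeGtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

gtfExon <- function(chrom, start, end, strand = "+", tx = "t1", gene = tx) {
  paste(chrom, "test", "exon", start, end, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s";', gene, tx),
        sep = "\t")
}

writeBedGraph <- function(lines) {
  f <- tempfile(fileext = ".bedGraph")
  writeLines(lines, f)
  f
}

# toy count matrix with known structure
toyCounts <- function(counts, design = NULL, modality = "bulk") {
  if (is.null(design)) design <- rep(c("A", "B"), length.out = ncol(counts))
  CountMatrix(counts, design = design, modality = modality)
}

.fixtureEnv <- new.env(parent = emptyenv())

# degradation coverage simulation with the transition planted at rank 500
# of 1000 grid transcripts, plus its stats table and filter result
fixtureGridCoverage <- function() {
  if (is.null(.fixtureEnv$grid)) {
    sim0 <- simulateCoverage(nTranscripts = 1000, seed = 101)
    tau <- log10(sort(sim0$truth$n_reads, decreasing = TRUE)[500])
    sim <- simulateCoverage(nTranscripts = 1000, tau = tau, seed = 101)
    stats <- coverageTable(readTranscriptModels(sim$gtf),
                           readCoverage(sim$bedgraph))
    .fixtureEnv$grid <- list(sim = sim, stats = stats,
                             clear = clearFilter(stats))
  }
  .fixtureEnv$grid
}

# gene-level truth shared between the coverage simulation and the count
# simulators (the cross-platform study design)
fixtureSharedTruth <- function() {
  if (is.null(.fixtureEnv$shared)) {
    truth <- simulateTruth(nGenes = 2000, seed = 301)
    cov <- simulateCoverage(truth, seed = 302)
    stats <- coverageTable(readTranscriptModels(cov$gtf),
                           readCoverage(cov$bedgraph))
    .fixtureEnv$shared <- list(truth = truth, cov = cov, stats = stats,
                               clear = clearFilter(stats))
  }
  .fixtureEnv$shared
}

# homogeneous (no true DEG effect) single-cell matrix
fixtureNullSc <- function(nGenes = 1000, nCells = 100, seed = 401) {
  truth <- simulateTruth(nGenes = nGenes, seed = seed)
  truth$true_fc <- 1
  truth$is_deg <- FALSE
  truth$direction <- "none"
  simulateScCounts(truth, nCells = nCells, seed = seed + 1)
}

# independent dense grid-search oracle for the beta-mixture likelihood
gridSearchMixture <- function(x, wGrid = seq(0, 1, 0.01),
                              aGrid = exp(seq(log(1), log(500),
                                              length.out = 120))) {
  x <- pmin(pmax(x, 1e-4), 1 - 1e-4)
  f0 <- dbeta(x, 0.5, 0.5)
  best <- list(ll = -Inf)
  for (a in aGrid) {
    f1 <- dbeta(x, a, a)
    for (w in wGrid) {
      ll <- sum(log(w * f1 + (1 - w) * f0))
      if (ll > best$ll) best <- list(ll = ll, w = w, a = a)
    }
  }
  best
}
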