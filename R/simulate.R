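#' Input-level presets for the bulk count simulator
#'
#' Simulator constants emulating the qualitative effect of shrinking RNA
#' input from the 1 ng (bulk-like) level down to 100 pg and 10 pg:
#' replicate dispersion (`alpha`) rises and the detection parameter
#' (`lambda`; dropout probability is `exp(-lambda * mean)`) falls, so
#' detection worsens, level by level. These are synthetic presets chosen to
#' produce that monotone ordering; they are not estimates fitted to any
#' dataset.
#'
#' @return Named list of presets `lvl_1ng`, `lvl_100pg`, `lvl_10pg`, each
#'   with `alpha` and `lambda`.
#' @export
inputLevelPresets <- function() {
  list(lvl_1ng   = list(alpha = 0.03, lambda = 3),
       lvl_100pg = list(alpha = 0.08, lambda = 1),
       lvl_10pg  = list(alpha = 0.15, lambda = 0.3))
}

#' Simulate a differential-expression ground truth
#'
#' Draws per-gene baseline means from a log-normal, assigns DEG flags
#' uniformly across the deciles of the mean distribution (so true DEGs span
#' the whole expression spectrum, the property the bias diagnostics probe),
#' draws fold changes log-uniformly in `fcRange`, and assigns up/down
#' direction 50/50. `true_fc` is the multiplier applied to group B
#' (`1/fc` for down-regulated genes); non-DEGs have `true_fc = 1`.
#'
#' @param nGenes number of genes.
#' @param degFraction fraction of DEGs, in the open interval (0, 1).
#' @param fcRange fold-change magnitude range, a subset of (1, Inf).
#' @param meanlog,sdlog log-normal parameters of the baseline means
#'   (defaults 4 and 1.5: median around 55 counts, heavy right tail).
#' @param seed RNG seed; the truth table is fully reproducible from it.
#' @return A `data.frame`: `gene`, `base_mean`, `decile`, `is_deg`,
#'   `direction`, `true_fc`; attribute `seed`.
#' @export
simulateTruth <- function(nGenes = 2000, degFraction = 0.1,
                          fcRange = c(1.5, 6), meanlog = 4, sdlog = 1.5,
                          seed = 1) {
  if (degFraction <= 0 || degFraction >= 1)
    stop("degFraction must lie in the open interval (0, 1)")
  if (fcRange[1] <= 1 || fcRange[2] <= fcRange[1])
    stop("fcRange must satisfy 1 < low < high")
  set.seed(seed)
  baseMean <- rlnorm(nGenes, meanlog = meanlog, sdlog = sdlog)
  decile <- ceiling(rank(baseMean, ties.method = "first") / nGenes * 10)
  nDeg <- round(nGenes * degFraction)
  quota <- rep(nDeg %/% 10, 10)
  extra <- nDeg %% 10
  if (extra > 0) {
    bump <- sample.int(10, extra)
    quota[bump] <- quota[bump] + 1
  }
  isDeg <- logical(nGenes)
  for (d in 1:10) {
    idx <- which(decile == d)
    take <- min(quota[d], length(idx))
    if (take > 0) isDeg[sample(idx, take)] <- TRUE
  }
  # top up if some decile was too small
  short <- nDeg - sum(isDeg)
  if (short > 0) {
    pool <- which(!isDeg)
    isDeg[sample(pool, short)] <- TRUE
  }
  fcMag <- exp(runif(nGenes, log(fcRange[1]), log(fcRange[2])))
  up <- runif(nGenes) < 0.5
  trueFc <- ifelse(isDeg, ifelse(up, fcMag, 1 / fcMag), 1)
  out <- data.frame(
    gene = sprintf("g%04d", seq_len(nGenes)), base_mean = baseMean,
    decile = decile, is_deg = isDeg,
    direction = ifelse(!isDeg, "none", ifelse(up, "up", "down")),
    true_fc = trueFc, stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}

#' Simulate degradation-biased per-base coverage
#'
#' Generates one single-exon transcript per gene on a toy chromosome, lays
#' down `n_g` reads per transcript (proportional to a log-spaced expression
#' grid), and biases read starts: with probability `1 - delta_g` a read
#' starts uniformly along the transcript, with probability `delta_g` its
#' start is drawn from a Beta(5, 1) rescaled to the transcript (piling
#' coverage toward the 3' end). The degradation strength follows a logistic
#' in log10 expression,
#' \deqn{\delta_g = \mathrm{plogis}((\tau - \log_{10} n_g)/\kappa),}
#' so \eqn{\delta \to 1} as expression falls below the midpoint
#' \eqn{\tau} -- the premise the reliability filter detects. Output is a
#' valid BedGraph + GTF pair plus a truth table.
#'
#' @param truth optional truth table from [simulateTruth()]: one transcript
#'   per gene, with `n_g = round(depthFactor * base_mean)` reads, so the
#'   coverage simulation and the count simulators share one ground truth.
#'   When `NULL`, `nTranscripts` anonymous transcripts take their read
#'   counts from a log-spaced grid over `exprRange`.
#' @param nTranscripts number of transcripts (ignored when `truth` is
#'   given).
#' @param exprRange range of reads per transcript for the grid mode.
#' @param depthFactor reads per unit of `base_mean` in truth mode
#'   (default 10).
#' @param lengthRange transcript length range (nt), drawn uniformly.
#' @param readLength read length in nt (default 100).
#' @param tau degradation midpoint on the log10 expression scale; default is
#'   the grid midpoint. Set it to `log10` of the expression at a chosen rank
#'   to place the transition there.
#' @param kappa logistic steepness in log10 units (default 0.1: a sharp
#'   transition, a fraction of one expression bin wide at default sizes).
#' @param endBiasShape Beta shape parameters of the biased start positions
#'   (default `c(5, 1)`).
#' @param outDir directory for `coverage.bedGraph`, `transcripts.gtf`,
#'   `truth.tsv`.
#' @param seed RNG seed.
#' @return A list: `bedgraph`, `gtf`, `truth_tsv` (paths) and `truth`
#'   (`data.frame` with `transcript_id`, `length`, `n_reads`, `delta`).
#' @export
simulateCoverage <- function(truth = NULL, nTranscripts = 1000,
                             exprRange = c(3, 30000), depthFactor = 10,
                             lengthRange = c(500, 3000), readLength = 100,
                             tau = NULL, kappa = 0.1,
                             endBiasShape = c(5, 1),
                             outDir = tempfile("simcov"), seed = 1) {
  stopifnot(lengthRange[1] >= readLength)
  set.seed(seed)
  if (!is.null(truth)) {
    nTranscripts <- nrow(truth)
    nReads <- round(depthFactor * truth$base_mean)
    ids <- truth$gene
  } else {
    stopifnot(nTranscripts >= 1, exprRange[1] > 0)
    nReads <- round(10^seq(log10(exprRange[2]), log10(exprRange[1]),
                           length.out = nTranscripts))
    ids <- sprintf("t%04d", seq_len(nTranscripts))
  }
  if (is.null(tau)) tau <- median(log10(pmax(nReads, 1)))
  delta <- stats::plogis((tau - log10(pmax(nReads, 1))) / kappa)
  delta[nReads == 0] <- 1
  len <- round(runif(nTranscripts, lengthRange[1], lengthRange[2]))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  gap <- 10L
  offset <- 0L  # 0-based genomic start of current transcript
  gtfLines <- character(0)
  bgCon <- file(file.path(outDir, "coverage.bedGraph"), open = "w")
  on.exit(close(bgCon), add = TRUE)
  for (i in seq_len(nTranscripts)) {
    L <- len[i]; n <- nReads[i]
    gtfLines <- c(gtfLines,
      sprintf("chrSim\tsim\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\";",
              offset + 1L, offset + L, ids[i], ids[i]))
    if (n > 0) {
      maxStart <- max(1L, L - readLength + 1L)
      biased <- runif(n) < delta[i]
      starts <- integer(n)
      nb <- sum(biased)
      if (nb > 0)
        starts[biased] <- pmin(maxStart,
          floor(rbeta(nb, endBiasShape[1], endBiasShape[2]) * maxStart) + 1L)
      if (nb < n)
        starts[!biased] <- sample.int(maxStart, n - nb, replace = TRUE)
      cnt <- tabulate(starts, nbins = L)
      S <- cumsum(cnt)
      depth <- S - c(rep(0, readLength), S)[seq_len(L)]
      r <- rle(depth)
      ends <- cumsum(r$lengths)
      startsR <- ends - r$lengths  # 0-based within transcript
      nz <- r$values > 0
      if (any(nz))
        writeLines(sprintf("chrSim\t%d\t%d\t%d",
                           offset + startsR[nz], offset + ends[nz],
                           r$values[nz]), bgCon)
    }
    offset <- offset + L + gap
  }
  writeLines(gtfLines, file.path(outDir, "transcripts.gtf"))
  truth <- data.frame(transcript_id = ids, length = len, n_reads = nReads,
                      delta = delta, stringsAsFactors = FALSE)
  truthPath <- file.path(outDir, "truth.tsv")
  write.table(truth, truthPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(bedgraph = file.path(outDir, "coverage.bedGraph"),
       gtf = file.path(outDir, "transcripts.gtf"),
       truth_tsv = truthPath, truth = truth, tau = tau, seed = seed)
}

#' Simulate bulk replicate counts at an RNA input level
#'
#' Counts are negative binomial around the ground-truth means (group B means
#' are `base_mean * true_fc`), with the preset dispersion for the input
#' level, then thinned by per-entry dropout with probability
#' `exp(-lambda * base_mean)`: low-count genes vanish first, and they vanish
#' more often as input falls.
#'
#' @param truth a truth table from [simulateTruth()].
#' @param inputLevel one of `"lvl_1ng"`, `"lvl_100pg"`, `"lvl_10pg"`.
#' @param nReplicates replicates per group (>= 2, default 3).
#' @param seed RNG seed.
#' @return A bulk [CountMatrix-class] with groups `"A"` and `"B"`;
#'   `metadata` records `input_level`, `alpha`, `lambda`, `seed`.
#' @export
simulateBulkCounts <- function(truth, inputLevel = "lvl_1ng",
                               nReplicates = 3, seed = 1) {
  presets <- inputLevelPresets()
  if (!inputLevel %in% names(presets))
    stop("unknown input level '", inputLevel, "'; available: ",
         paste(names(presets), collapse = ", "))
  if (nReplicates < 2) stop("nReplicates must be >= 2")
  p <- presets[[inputLevel]]
  set.seed(seed)
  nG <- nrow(truth)
  mu <- cbind(matrix(truth$base_mean, nG, nReplicates),
              matrix(truth$base_mean * truth$true_fc, nG, nReplicates))
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / p$alpha),
                nG, 2 * nReplicates)
  pDrop <- exp(-p$lambda * truth$base_mean)
  drop <- matrix(runif(length(cnt)) < pDrop, nG, 2 * nReplicates)
  cnt[drop] <- 0L
  dimnames(cnt) <- list(truth$gene,
                        c(paste0("A_rep", seq_len(nReplicates)),
                          paste0("B_rep", seq_len(nReplicates))))
  m <- CountMatrix(cnt, design = rep(c("A", "B"), each = nReplicates),
                   modality = "bulk")
  metadata(m)$input_level <- inputLevel
  metadata(m)$alpha <- p$alpha
  metadata(m)$lambda <- p$lambda
  metadata(m)$seed <- seed
  metadata(m)$note <- "synthetic preset; not fitted to any dataset"
  m
}

#' Simulate capture-thinned single-cell counts
#'
#' Each cell gets a capture efficiency `eps_i` drawn log-normally; each
#' gene's true per-cell load is negative binomial around the ground-truth
#' mean (group B: `base_mean * true_fc`) with a biological dispersion, and
#' the observed count is a binomial thinning `Binomial(load, eps_i)`. The
#' thinning couples the dropout rate to expression level, producing the
#' zero inflation characteristic of droplet data without a separate
#' zero-inflation parameter.
#'
#' @param truth a truth table from [simulateTruth()].
#' @param nCells cells per group (>= 10, default 300).
#' @param captureMeanlog,captureSdlog log-normal parameters of the per-cell
#'   capture efficiency (defaults `log(0.05)` and 0.3: mean capture around
#'   5\%).
#' @param bioDispersion biological NB dispersion of the per-cell load
#'   (default 0.1); `0` gives Poisson-like loads.
#' @param seed RNG seed.
#' @return A single-cell [CountMatrix-class] with groups `"A"` and `"B"`;
#'   `metadata` records the capture parameters and seed.
#' @export
simulateScCounts <- function(truth, nCells = 300,
                             captureMeanlog = log(0.05),
                             captureSdlog = 0.3, bioDispersion = 0.1,
                             seed = 1) {
  if (nCells < 10) stop("need at least 10 cells per group")
  set.seed(seed)
  nG <- nrow(truth)
  nTot <- 2L * nCells
  eps <- pmin(1, rlnorm(nTot, captureMeanlog, captureSdlog))
  mu <- cbind(matrix(truth$base_mean, nG, nCells),
              matrix(truth$base_mean * truth$true_fc, nG, nCells))
  size <- if (bioDispersion > 0) 1 / bioDispersion else Inf
  load <- if (is.finite(size))
    matrix(rnbinom(length(mu), mu = mu, size = size), nG, nTot)
  else
    matrix(stats::rpois(length(mu), lambda = mu), nG, nTot)
  epsM <- matrix(eps, nG, nTot, byrow = TRUE)
  cnt <- matrix(rbinom(length(load), size = load, prob = epsM), nG, nTot)
  dimnames(cnt) <- list(truth$gene,
                        c(paste0("A_cell", seq_len(nCells)),
                          paste0("B_cell", seq_len(nCells))))
  m <- CountMatrix(cnt, design = rep(c("A", "B"), each = nCells),
                   modality = "single_cell")
  metadata(m)$capture_meanlog <- captureMeanlog
  metadata(m)$capture_sdlog <- captureSdlog
  metadata(m)$bio_dispersion <- bioDispersion
  metadata(m)$seed <- seed
  m
}
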