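# ---- rank-sum machinery -----------------------------------------------------

# index combinations for exact enumeration, cached per (nx, n)
.combCache <- new.env(parent = emptyenv())
.combIndices <- function(nx, n) {
  key <- paste(nx, n, sep = "_")
  if (is.null(.combCache[[key]]))
    .combCache[[key]] <- combn(n, nx)
  .combCache[[key]]
}

# two-sided rank-sum p for x vs y.
# Exact path: full enumeration of all C(n, nx) group assignments; a labeling
# is at least as extreme as the observed one when its rank sum deviates from
# the null mean by at least as much (ties in the data handled naturally
# because ranks are midranks).
# Approximate path: normal approximation with tie and continuity correction.
.rankSumTest <- function(x, y, exactMax = 10) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (nx <= exactMax && ny <= exactMax) {
    cmb <- .combIndices(nx, n)
    S <- colSums(matrix(r[cmb], nrow = nx))
    p <- mean(abs(S - mu) >= abs(W - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(W = W, p = 1))
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(W = W, p = p)
}

.twoGroups <- function(groups) {
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2)
    stop("exactly two groups are required, got ", length(lv))
  lv
}

# ---- Wilcoxon engine --------------------------------------------------------

#' Wilcoxon rank-sum differential expression (single-cell convention)
#'
#' For each gene, compares the two design groups on log-normalized values
#' with a two-sided Wilcoxon rank-sum test: exact by full enumeration of
#' group assignments when both groups have at most `exactMax` members, else
#' normal approximation with tie and continuity correction. Adjusted
#' p-values are Bonferroni over all features in the dataset
#' (`p_adj = min(1, p * nFeaturesBonferroni)`), the single-cell convention.
#'
#' Genes are prefiltered before testing (the single-cell convention again):
#' a gene is tested only if expressed (value > 0) in at least `minPct` of
#' the cells of one group, and `|log2fc| >= lfcMin`, where
#' `log2fc = log2((mA + 1)/(mB + 1))` with `mX` the group mean of de-logged
#' normalized expression (counts per `scale` units). `log2fc` is reported
#' for every gene; `p` is `NA` for untested genes. Positive `log2fc` means
#' higher in group A (the alphabetically first label).
#'
#' @param norm a [NormalizedMatrix-class] with method `"log_cp_scale"`.
#' @param groups optional group labels overriding the stored design (used by
#'   the permutation null).
#' @param lfcMin minimum absolute log2 fold change (default 0.36).
#' @param alpha adjusted-significance threshold (default 0.05).
#' @param minPct minimum expressing fraction in at least one group
#'   (default 0.1).
#' @param nFeaturesBonferroni Bonferroni denominator; defaults to the number
#'   of features in the dataset (pre-prefilter).
#' @param exactMax largest per-group size for the exact test (default 10).
#' @return A `data.frame`: `gene`, `mean_A`, `mean_B`, `log2fc`,
#'   `statistic` (rank sum of group A), `p_raw`, `p_adj`, `is_deg`,
#'   `direction`.
#' @export
wilcoxonDEG <- function(norm, groups = NULL, lfcMin = 0.36, alpha = 0.05,
                        minPct = 0.1, nFeaturesBonferroni = NULL,
                        exactMax = 10) {
  stopifnot(is(norm, "NormalizedMatrix"))
  v <- normalizedMatrix(norm)
  if (is.null(groups)) groups <- designGroups(norm)
  lv <- .twoGroups(groups)
  ia <- which(groups == lv[1]); ib <- which(groups == lv[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 columns")
  if (is.null(nFeaturesBonferroni)) nFeaturesBonferroni <- nrow(v)
  expr <- expm1(v)  # back to counts-per-scale
  mA <- rowMeans(expr[, ia, drop = FALSE])
  mB <- rowMeans(expr[, ib, drop = FALSE])
  lfc <- log2((mA + 1) / (mB + 1))
  pctA <- rowMeans(v[, ia, drop = FALSE] > 0)
  pctB <- rowMeans(v[, ib, drop = FALSE] > 0)
  tested <- (pmax(pctA, pctB) >= minPct) & (abs(lfc) >= lfcMin)
  W <- rep(NA_real_, nrow(v)); p <- rep(NA_real_, nrow(v))
  for (g in which(tested)) {
    res <- .rankSumTest(v[g, ia], v[g, ib], exactMax = exactMax)
    W[g] <- res$W; p[g] <- res$p
  }
  padj <- pmin(1, p * nFeaturesBonferroni)
  isDeg <- !is.na(padj) & padj < alpha & abs(lfc) >= lfcMin
  data.frame(
    gene = rownames(v), mean_A = mA, mean_B = mB, log2fc = lfc,
    statistic = W, p_raw = p, p_adj = padj, is_deg = isDeg,
    direction = ifelse(lfc > 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE)
}

# ---- NB engine --------------------------------------------------------------

#' Method-of-moments dispersion estimation with a 1/mean trend
#'
#' On size-factor-normalized counts `y = c / s`, the gene-wise
#' method-of-moments dispersion equates the within-group variance to the
#' NB mean-variance relation `var = mu + alpha * mu^2` and solves for
#' `alpha` pooling over design groups,
#' \deqn{\hat\alpha_g = \frac{\sum_j (n_j - 1)(v_{gj} - m_{gj})}
#'   {\sum_j (n_j - 1) m_{gj}^2},}
#' floored at 1e-8 (group means `m`, group variances `v`; pooling within
#' groups keeps a genuine expression difference between groups out of the
#' gene's dispersion). A trend `alpha(mu) = a0 + a1/mu` is fitted by robust
#' least squares over genes with a positive raw estimate, and the final
#' per-gene dispersion is the trend value unless the gene-wise estimate
#' exceeds 10x the trend (a dispersion outlier, which keeps its own
#' estimate).
#'
#' @param m a [CountMatrix-class] with at least 2 columns; groups with at
#'   least 2 columns contribute to the within-group moments.
#' @param sf size factors from [medianOfRatios()].
#' @return A list: `mean` (per-gene normalized mean), `genewise`, `trend`
#'   (coefficients `a0`, `a1`), `final` (dispersion used by the Wald test).
#' @export
estimateDispersionsNB <- function(m, sf) {
  stopifnot(is(m, "CountMatrix"))
  if (ncol(m) < 2) stop("need at least 2 samples")
  cnt <- countsMatrix(m)
  stopifnot(length(sf) == ncol(cnt))
  y <- sweep(cnt, 2, sf, `/`)
  mu <- rowMeans(y)
  groups <- designGroups(m)
  use <- names(table(groups))[table(groups) >= 2]
  if (length(use) == 0) use <- unique(groups)
  num <- 0; den <- 0
  for (g in use) {
    yg <- y[, groups == g, drop = FALSE]
    nj <- ncol(yg)
    mg <- rowMeans(yg)
    vg <- apply(yg, 1, var)
    num <- num + (nj - 1) * (vg - mg)
    den <- den + (nj - 1) * mg^2
  }
  raw <- num / den
  raw[!is.finite(raw)] <- 0
  genewise <- pmax(raw, 1e-8)
  use <- raw > 0 & mu > 0
  if (sum(use) >= 10) {
    df <- data.frame(a = raw[use], im = 1 / mu[use])
    fit <- tryCatch(MASS::rlm(a ~ im, data = df, maxit = 50),
                    error = function(e) stats::lm(a ~ im, data = df))
    co <- stats::coef(fit)
  } else {
    co <- c(median(genewise), 0)
  }
  a0 <- unname(co[1]); a1 <- unname(co[2])
  trendVal <- pmax(1e-8, a0 + a1 / pmax(mu, 1e-8))
  final <- ifelse(genewise > 10 * trendVal, genewise, trendVal)
  list(mean = mu, genewise = genewise, trend = c(a0 = a0, a1 = a1),
       final = pmax(1e-8, final))
}

#' Negative-binomial Wald differential expression (bulk convention)
#'
#' A deliberately simplified bulk DE procedure: per-group mean normalized
#' counts `qX = sum(c) / sum(s)`, `log2fc = log2((qB + pc)/(qA + pc))` with
#' pseudocount `pc = 0.5 / mean(s)`, a delta-method standard error on the
#' log2 scale using NB variance `q * sum(s) + alpha * q^2 * sum(s^2)` per
#' group, a two-sided normal p-value on the Wald ratio, and
#' Benjamini-Hochberg FDR. A gene is a DEG when `q-value < alpha` and
#' `|log2fc| >= lfcMin`. There is no outlier handling, shrinkage or
#' independent filtering; calibration is established by simulation.
#' Positive `log2fc` means higher in group B (the alphabetically second
#' label).
#'
#' Genes with zero counts in both groups are flagged untestable (`NA`
#' p-values) and excluded from the FDR denominator.
#'
#' @param m a [CountMatrix-class]; two design groups with >= 2 samples each.
#' @param sf size factors from [medianOfRatios()].
#' @param disp dispersion model from [estimateDispersionsNB()].
#' @param groups optional group labels overriding the stored design.
#' @param lfcMin minimum absolute log2 fold change (default 1).
#' @param alpha FDR threshold (default 0.05).
#' @return A `data.frame`: `gene`, `mean_A`, `mean_B`, `log2fc`,
#'   `statistic` (Wald z), `p_raw`, `p_adj` (BH q), `is_deg`, `direction`.
#' @export
nbWaldDEG <- function(m, sf, disp, groups = NULL, lfcMin = 1,
                      alpha = 0.05) {
  stopifnot(is(m, "CountMatrix"))
  cnt <- countsMatrix(m)
  if (is.null(groups)) groups <- designGroups(m)
  lv <- .twoGroups(groups)
  ia <- which(groups == lv[1]); ib <- which(groups == lv[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 samples")
  alphaG <- disp$final
  stopifnot(length(alphaG) == nrow(cnt), length(sf) == ncol(cnt))
  sA <- sum(sf[ia]); sB <- sum(sf[ib])
  s2A <- sum(sf[ia]^2); s2B <- sum(sf[ib]^2)
  qA <- rowSums(cnt[, ia, drop = FALSE]) / sA
  qB <- rowSums(cnt[, ib, drop = FALSE]) / sB
  pc <- 0.5 / mean(sf)
  lfc <- log2((qB + pc) / (qA + pc))
  varA <- (qA * sA + alphaG * qA^2 * s2A) / sA^2
  varB <- (qB * sB + alphaG * qB^2 * s2B) / sB^2
  seA <- sqrt(varA) / ((qA + pc) * log(2))
  seB <- sqrt(varB) / ((qB + pc) * log(2))
  se <- sqrt(seA^2 + seB^2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(se > 0, 2 * pnorm(-abs(z)), ifelse(lfc == 0, 1, 0))
  untestable <- qA == 0 & qB == 0
  p[untestable] <- NA_real_
  z[untestable] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!untestable] <- p.adjust(p[!untestable], method = "BH")
  isDeg <- !is.na(q) & q < alpha & abs(lfc) >= lfcMin
  data.frame(
    gene = rownames(cnt), mean_A = qA, mean_B = qB, log2fc = lfc,
    statistic = z, p_raw = p, p_adj = q, is_deg = isDeg,
    direction = ifelse(lfc > 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE)
}

# ---- permutation null -------------------------------------------------------

#' Random-assignment permutation null for a DEG engine
#'
#' Probes a dataset's propensity for false-positive DEG calls: columns are
#' repeatedly split into two balanced groups uniformly at random, the
#' configured engine is run on each split, and the DEG count and log2
#' fold-change extrema are recorded. On homogeneous data (no true group
#' structure) the expected outcome is zero DEGs in (nearly) every split --
#' no gene should clear the fold-change threshold.
#'
#' @param x a [NormalizedMatrix-class] (engine `"wilcoxon"`) or a
#'   [CountMatrix-class] (engine `"nb_wald"`).
#' @param nPerm number of random splits (>= 1).
#' @param seed RNG seed; the report is reproducible given the seed.
#' @param engine `"wilcoxon"` or `"nb_wald"`.
#' @param ... further arguments passed to the engine
#'   ([wilcoxonDEG()] or [nbWaldDEG()]).
#' @return A list: `engine`, `n_perm`, `seed`, `deg_counts` (per
#'   permutation), `lfc_min`, `lfc_max` (per-permutation log2fc extrema over
#'   all genes).
#' @export
permutationNull <- function(x, nPerm, seed = 1,
                            engine = c("wilcoxon", "nb_wald"), ...) {
  engine <- match.arg(engine)
  if (nPerm < 1) stop("nPerm must be >= 1")
  n <- ncol(x)
  if (n < 4) stop("need at least 4 columns")
  set.seed(seed)
  nA <- floor(n / 2)
  degCounts <- integer(nPerm)
  lfcMinV <- numeric(nPerm); lfcMaxV <- numeric(nPerm)
  if (engine == "nb_wald") {
    sf <- medianOfRatios(x, pseudoReference = TRUE)
    disp <- estimateDispersionsNB(x, sf)
  }
  for (i in seq_len(nPerm)) {
    pick <- sample.int(n, nA)
    groups <- rep("permB", n)
    groups[pick] <- "permA"
    tab <- if (engine == "wilcoxon")
      wilcoxonDEG(x, groups = groups, ...)
    else
      nbWaldDEG(x, sf, disp, groups = groups, ...)
    degCounts[i] <- sum(tab$is_deg)
    lfcMinV[i] <- min(tab$log2fc)
    lfcMaxV[i] <- max(tab$log2fc)
  }
  list(engine = engine, n_perm = as.integer(nPerm), seed = seed,
       deg_counts = degCounts, lfc_min = lfcMinV, lfc_max = lfcMaxV)
}
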