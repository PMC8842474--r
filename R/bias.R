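#' Mean-count ranks over detected genes
#'
#' Computes each gene's mean count across columns, drops genes not expressed
#' in any column (so zero inflation cannot bias the comparison), and assigns
#' ascending ranks with ties mid-ranked: rank 1 is the lowest detected mean
#' count. The direction is recorded so downstream comparisons are
#' unambiguous.
#'
#' @param m a [CountMatrix-class].
#' @return A `data.frame`: `gene`, `mean_count`, `rank`; attribute
#'   `rank_direction = "ascending"`.
#' @export
countRanks <- function(m) {
  stopifnot(is(m, "CountMatrix"))
  mc <- rowMeans(countsMatrix(m))
  keep <- mc > 0
  if (!any(keep)) stop("all genes have zero counts")
  out <- data.frame(gene = rownames(m)[keep], mean_count = mc[keep],
                    rank = rank(mc[keep]), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "rank_direction") <- "ascending"
  out
}

#' Count-rank bias of DEGs versus non-DEGs
#'
#' Compares the count ranks of DEGs against non-DEGs with a two-sided
#' Mann-Whitney (rank-sum) test: a strong upward shift of DEG ranks is the
#' signature of an engine biased towards high-count genes. Exact by
#' enumeration when both sets are small, normal approximation otherwise.
#'
#' @param ranks the table from [countRanks()].
#' @param degIds character vector of DEG gene ids.
#' @param exactMax largest per-group size for the exact test (default 10).
#' @return A list: `n_deg`, `n_nondeg`, `median_deg`, `median_nondeg`,
#'   `median_deg_pctile`, `median_nondeg_pctile` (medians as fractions of
#'   the ranked gene count), `U`, `p`.
#' @export
rankBiasTest <- function(ranks, degIds, exactMax = 10) {
  isDeg <- ranks$gene %in% degIds
  if (!any(isDeg) || all(isDeg))
    stop("both a DEG and a non-DEG set are required among ranked genes")
  rd <- ranks$rank[isDeg]; rn <- ranks$rank[!isDeg]
  res <- .rankSumTest(rd, rn, exactMax = exactMax)
  nG <- nrow(ranks)
  U <- res$W - length(rd) * (length(rd) + 1) / 2
  list(n_deg = length(rd), n_nondeg = length(rn),
       median_deg = median(rd), median_nondeg = median(rn),
       median_deg_pctile = median(rd) / nG,
       median_nondeg_pctile = median(rn) / nG,
       U = U, p = res$p)
}

#' Compare DEG fold-change magnitudes between two engines or platforms
#'
#' Compares the `|log2fc|` distributions of the DEGs of two result tables
#' (means, medians, two-sided rank-sum p): the platform-bias signature is a
#' larger typical fold change in the bulk table than in the single-cell
#' table.
#'
#' @param degA,degB DEG tables from [wilcoxonDEG()] or [nbWaldDEG()].
#' @param exactMax largest per-group size for the exact test (default 10).
#' @return A list: `n_A`, `n_B`, `mean_abs_lfc_A/B`, `median_abs_lfc_A/B`,
#'   `p`.
#' @export
fcCompare <- function(degA, degB, exactMax = 10) {
  fa <- abs(degA$log2fc[degA$is_deg])
  fb <- abs(degB$log2fc[degB$is_deg])
  if (length(fa) == 0 || length(fb) == 0)
    stop("both tables must contain at least one DEG")
  res <- .rankSumTest(fa, fb, exactMax = exactMax)
  list(n_A = length(fa), n_B = length(fb),
       mean_abs_lfc_A = mean(fa), mean_abs_lfc_B = mean(fb),
       median_abs_lfc_A = median(fa), median_abs_lfc_B = median(fb),
       p = res$p)
}

#' Overlap accounting for two or three DEG sets
#'
#' All intersection and unique cardinalities for named id sets, plus Jaccard
#' and per-set overlap percentages. Both conventions are always reported
#' because a bare "overlap percentage" does not state its denominator:
#' `jaccard = |A n B| / |A u B|`, while `pct_of_<name>` divides by that
#' set's own size.
#'
#' @param sets named list of 2 or 3 character vectors (duplicates removed).
#' @return A list: `sizes`, `pairwise` (data.frame with `a`, `b`,
#'   `intersection`, `union`, `unique_a`, `unique_b`, `jaccard`,
#'   `pct_of_a`, `pct_of_b`), and for 3 sets `common_all`.
#' @examples
#' ov <- overlapSets(list(sc = as.character(1:299),
#'                        bulk = as.character(207:996)))
#' ov$pairwise$intersection  # 93
#' @export
overlapSets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be a named list")
  if (!length(sets) %in% c(2L, 3L)) stop("2 or 3 sets are supported")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  nm <- names(sets)
  pairs <- combn(nm, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    i <- length(intersect(sets[[a]], sets[[b]]))
    u <- length(union(sets[[a]], sets[[b]]))
    data.frame(a = a, b = b, intersection = i, union = u,
               unique_a = length(sets[[a]]) - i,
               unique_b = length(sets[[b]]) - i,
               jaccard = if (u > 0) i / u else 0,
               pct_of_a = if (length(sets[[a]])) 100 * i / length(sets[[a]]) else 0,
               pct_of_b = if (length(sets[[b]])) 100 * i / length(sets[[b]]) else 0,
               stringsAsFactors = FALSE)
  }))
  out <- list(sizes = vapply(sets, length, integer(1)), pairwise = pw)
  if (length(sets) == 3L)
    out$common_all <- length(Reduce(intersect, sets))
  out
}

#' Replicate coefficient-of-variation report
#'
#' For each replicate group, computes the per-gene coefficient of variation
#' (sample standard deviation over mean, n-1 denominator) on
#' size-factor-normalized counts, restricted to genes detected (count > 0)
#' in every column of the group; optionally restricted further to a
#' reliability-filter pass set. The group medians are the reproducibility
#' summary: they rise as RNA input falls, and filtering lowers them.
#'
#' @param m a [CountMatrix-class].
#' @param replicateGroups named list mapping a group label to the column
#'   names (or indices) of its replicates; every group needs >= 2 columns.
#'   Defaults to the stored design.
#' @param clearSet optional character vector of gene ids (e.g.
#'   [intersectClear()] output) to restrict to.
#' @param sf optional size factors; computed per group by
#'   [medianOfRatios()] (pseudo-reference fallback allowed) when missing.
#' @return A `data.frame`: `group`, `n_genes`, `median_cv`, `mean_cv`,
#'   `filtered`.
#' @export
cvReport <- function(m, replicateGroups = NULL, clearSet = NULL, sf = NULL) {
  stopifnot(is(m, "CountMatrix"))
  cnt <- countsMatrix(m)
  if (is.null(replicateGroups)) {
    g <- designGroups(m)
    replicateGroups <- split(seq_len(ncol(cnt)), g)
  }
  if (is.null(sf)) sf <- medianOfRatios(m, pseudoReference = TRUE)
  y <- sweep(cnt, 2, sf, `/`)
  rows <- lapply(names(replicateGroups), function(gname) {
    cols <- replicateGroups[[gname]]
    if (length(cols) < 2)
      stop("replicate group '", gname, "' has fewer than 2 columns")
    yg <- y[, cols, drop = FALSE]
    keep <- rowSums(cnt[, cols, drop = FALSE] > 0) == length(cols)
    if (!is.null(clearSet))
      keep <- keep & rownames(cnt) %in% clearSet
    yg <- yg[keep, , drop = FALSE]
    if (nrow(yg) == 0)
      return(data.frame(group = gname, n_genes = 0L,
                        median_cv = NA_real_, mean_cv = NA_real_,
                        filtered = !is.null(clearSet),
                        stringsAsFactors = FALSE))
    cv <- apply(yg, 1, sd) / rowMeans(yg)
    data.frame(group = gname, n_genes = nrow(yg),
               median_cv = median(cv), mean_cv = mean(cv),
               filtered = !is.null(clearSet), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
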