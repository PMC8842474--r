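#' Read a count matrix from TSV or MatrixMarket triplet files
#'
#' `format = "tsv"` expects genes in rows and samples in columns with a
#' header row and gene ids in the first column. `format = "mtx_triplet"`
#' expects a MatrixMarket coordinate file plus `features.tsv` and
#' `barcodes.tsv` sidecars in the same directory (or given explicitly), the
#' layout emitted by droplet single-cell pipelines.
#'
#' @param path path to the TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @param design group label per column; defaults to a single group
#'   `"all"`.
#' @param modality `"bulk"` or `"single_cell"`.
#' @param features,barcodes sidecar paths for `mtx_triplet` (default:
#'   `features.tsv` / `barcodes.tsv` next to the `.mtx` file).
#' @return A [CountMatrix-class].
#' @export
readCounts <- function(path, format = c("tsv", "mtx_triplet"),
                       design = NULL,
                       modality = c("bulk", "single_cell"),
                       features = NULL, barcodes = NULL) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (format == "tsv") {
    tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab)
  } else {
    dir <- dirname(path)
    if (is.null(features)) features <- file.path(dir, "features.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dir, "barcodes.tsv")
    if (!file.exists(features)) stop("features sidecar not found: ", features)
    if (!file.exists(barcodes)) stop("barcodes sidecar not found: ", barcodes)
    sm <- Matrix::readMM(path)
    feat <- read.table(features, header = FALSE, sep = "\t",
                       stringsAsFactors = FALSE)[[1]]
    bc <- read.table(barcodes, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)[[1]]
    if (length(feat) != nrow(sm))
      stop("features sidecar has ", length(feat), " rows but matrix has ",
           nrow(sm))
    if (length(bc) != ncol(sm))
      stop("barcodes sidecar has ", length(bc), " rows but matrix has ",
           ncol(sm), " columns")
    m <- as.matrix(sm)
    dimnames(m) <- list(feat, bc)
  }
  if (anyNA(m)) stop("NA entries in counts: ", path)
  if (!is.numeric(m)) stop("non-numeric entries in counts: ", path)
  if (any(m < 0)) stop("negative entries in counts: ", path)
  if (any(m != round(m))) stop("non-integer entries in counts: ", path)
  if (is.null(design)) design <- rep("all", ncol(m))
  CountMatrix(m, design = design, modality = modality)
}

#' Filter cells by unique feature count
#'
#' Removes damaged cells and multiplets by the standard feature-count bounds:
#' cells with a unique feature count (number of genes with count > 0) above
#' `maxFeatures` or below `minFeatures` are excluded; the bounds themselves
#' are kept.
#'
#' @param m a single-cell [CountMatrix-class].
#' @param minFeatures,maxFeatures inclusive keep bounds (defaults 1000 and
#'   2500).
#' @return The column-subset `CountMatrix`.
#' @export
filterCells <- function(m, minFeatures = 1000, maxFeatures = 2500) {
  stopifnot(is(m, "CountMatrix"))
  if (modality(m) != "single_cell")
    stop("filterCells applies to single_cell matrices")
  nfeat <- colSums(countsMatrix(m) > 0)
  keep <- nfeat >= minFeatures & nfeat <= maxFeatures
  if (!any(keep))
    stop("all cells removed by the feature-count filter")
  m[, keep]
}

#' Library-size log-normalization
#'
#' The single-cell convention: each column is rescaled to a fixed library
#' size `scale`, then natural-log transformed with a pseudocount of 1,
#' \deqn{v_{gj} = \ln(1 + \mathrm{scale} \cdot c_{gj} / \mathrm{total}_j).}
#' Zero counts map to exactly zero.
#'
#' @param m a [CountMatrix-class].
#' @param scale target library size (default 10000).
#' @return A [NormalizedMatrix-class] with method `"log_cp_scale"`.
#' @export
logNormalize <- function(m, scale = 10000) {
  stopifnot(is(m, "CountMatrix"))
  cnt <- countsMatrix(m)
  tot <- colSums(cnt)
  if (any(tot == 0))
    stop("zero-total column(s): ",
         paste(colnames(cnt)[tot == 0], collapse = ", "))
  v <- log1p(sweep(cnt, 2, scale / tot, `*`))
  se <- SummarizedExperiment(assays = list(normalized = v),
                             colData = colData(m))
  metadata(se)$method <- "log_cp_scale"
  metadata(se)$scale <- scale
  new("NormalizedMatrix", se)
}

#' Median-of-ratios size factors
#'
#' The bulk-normalization convention: a reference pseudo-sample is the
#' geometric mean of each gene across samples, restricted to genes with
#' strictly positive counts everywhere; each sample's size factor is the
#' median ratio of its counts to the reference.
#'
#' @param m a [CountMatrix-class].
#' @param pseudoReference if `TRUE`, fall back to genes positive in at least
#'   90\% of samples (geometric mean over their positive entries), for
#'   sparse matrices with no all-positive gene. Off by default.
#' @return Named numeric vector of positive size factors, one per column.
#' @export
medianOfRatios <- function(m, pseudoReference = FALSE) {
  stopifnot(is(m, "CountMatrix"))
  cnt <- countsMatrix(m)
  allPos <- rowSums(cnt > 0) == ncol(cnt)
  if (!any(allPos)) {
    if (!pseudoReference)
      stop("no gene with positive counts in every sample; ",
           "consider pseudoReference = TRUE")
    use <- rowMeans(cnt > 0) >= 0.9
    if (!any(use)) stop("no gene positive in >= 90% of samples")
    ref <- apply(cnt[use, , drop = FALSE], 1,
                 function(x) exp(mean(log(x[x > 0]))))
    sub <- cnt[use, , drop = FALSE]
  } else {
    sub <- cnt[allPos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
  }
  sf <- apply(sub, 2, function(x) median((x / ref)[x > 0]))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("degenerate size factors")
  sf
}

#' Restrict a count matrix to a gene set
#'
#' Row-subsets a matrix to the genes of `keep` (e.g. the cross-sample
#' intersection of reliability-filter pass lists), preserving column order.
#' Ids in `keep` absent from the matrix are warned about and ignored.
#'
#' @param m a [CountMatrix-class].
#' @param keep character vector of gene ids to retain.
#' @return The row-subset `CountMatrix`.
#' @export
applyGeneFilter <- function(m, keep) {
  stopifnot(is(m, "CountMatrix"))
  keep <- as.character(keep)
  missing <- setdiff(keep, rownames(m))
  if (length(missing))
    warning(length(missing), " ids in keep are not in the matrix; ignored")
  present <- intersect(rownames(m), keep)
  if (length(present) == 0L)
    stop("gene filter removes every gene")
  m[rownames(m) %in% present, ]
}

#' Net capture-rate summary
#'
#' Capture rate as a percentage of loaded cells that were recovered,
#' truncated (rounded down) to one decimal place -- e.g. 26916 of 41805
#' loaded is 64.38...%, reported as 64.3.
#'
#' @param loaded number of cells loaded (> 0).
#' @param recovered number of cells recovered (`0 <= recovered <= loaded`).
#' @return A list with `loaded`, `recovered`, `capture_rate_pct`.
#' @examples
#' qcSummary(41805, 26916)$capture_rate_pct  # 64.3
#' @export
qcSummary <- function(loaded, recovered) {
  if (loaded <= 0) stop("loaded must be > 0")
  if (recovered < 0 || recovered > loaded)
    stop("recovered must be between 0 and loaded")
  rate <- floor(1000 * recovered / loaded) / 10
  list(loaded = as.integer(loaded), recovered = as.integer(recovered),
       capture_rate_pct = rate)
}
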