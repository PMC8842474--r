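#' CountMatrix: an integer count matrix with a two-level (or multi-level)
#' group design
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `counts` assay of non-negative integers, a `group` column in `colData`
#' giving the design, and a `modality` flag (`"bulk"` or `"single_cell"`) in
#' `metadata`. Columns are bulk samples or single cells depending on the
#' modality.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]
#' @aliases CountMatrix-class
#' @exportClass CountMatrix
setClass("CountMatrix", contains = "SummarizedExperiment")

setValidity("CountMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (anyNA(m)) msg <- c(msg, "counts contain NA")
    else {
      if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(m != round(m))) msg <- c(msg, "counts must be integers")
    }
  }
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'group' (the design) is required")
  mod <- metadata(object)$modality
  if (is.null(mod) || !mod %in% c("bulk", "single_cell"))
    msg <- c(msg, "metadata 'modality' must be 'bulk' or 'single_cell'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts numeric matrix of non-negative integer counts, genes in rows
#'   (rownames = gene ids), samples or cells in columns.
#' @param design group label per column (character or factor, recycled never);
#'   stored as `colData(x)$group`.
#' @param modality `"bulk"` or `"single_cell"`.
#' @return A [CountMatrix-class] object.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' cm <- CountMatrix(m, design = c("A", "B"), modality = "bulk")
#' designGroups(cm)
#' @export
CountMatrix <- function(counts, design, modality = c("bulk", "single_cell")) {
  modality <- match.arg(modality)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (length(design) != ncol(counts))
    stop("design must give one group label per column")
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(group = as.character(design),
                        row.names = colnames(counts)))
  metadata(se)$modality <- modality
  new("CountMatrix", se)
}

#' @describeIn CountMatrix group labels (the design) of a CountMatrix or
#'   NormalizedMatrix.
#' @param x a `CountMatrix` or `NormalizedMatrix`.
#' @export
designGroups <- function(x) as.character(colData(x)$group)

#' @describeIn CountMatrix modality flag (`"bulk"` or `"single_cell"`).
#' @export
modality <- function(x) metadata(x)$modality

#' @describeIn CountMatrix counts assay as a plain matrix.
#' @export
countsMatrix <- function(x) assay(x, "counts")

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix (%s): %d genes x %d columns\n",
              metadata(object)$modality, nrow(object), ncol(object)))
  tab <- table(designGroups(object))
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
})

#' NormalizedMatrix: normalized expression values with the design retained
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `normalized` assay of non-negative reals and a `method` flag in metadata:
#' `"log_cp_scale"` (per-column counts rescaled to a fixed library size, then
#' `log1p`-transformed) or `"size_factor"` (counts divided by median-of-ratios
#' size factors). Zero counts stay exactly zero under `log_cp_scale`.
#'
#' @aliases NormalizedMatrix-class
#' @exportClass NormalizedMatrix
setClass("NormalizedMatrix", contains = "SummarizedExperiment")

setValidity("NormalizedMatrix", function(object) {
  msg <- character()
  if (!"normalized" %in% assayNames(object))
    msg <- c(msg, "assay 'normalized' is required")
  else if (any(assay(object, "normalized") < 0))
    msg <- c(msg, "normalized values must be non-negative")
  meth <- metadata(object)$method
  if (is.null(meth) || !meth %in% c("log_cp_scale", "size_factor"))
    msg <- c(msg, "metadata 'method' must be 'log_cp_scale' or 'size_factor'")
  if (length(msg)) msg else TRUE
})

#' @describeIn NormalizedMatrix normalized assay as a plain matrix.
#' @param x a `NormalizedMatrix`.
#' @export
normalizedMatrix <- function(x) assay(x, "normalized")

setMethod("show", "NormalizedMatrix", function(object) {
  cat(sprintf("NormalizedMatrix (%s): %d genes x %d columns\n",
              metadata(object)$method, nrow(object), ncol(object)))
})

#' BetaMixtureFit: EM fit of the two-component beta mixture
#'
#' Result of fitting positional means to
#' `w * Beta(a, a) + (1 - w) * Beta(0.5, 0.5)`: a symmetric, centre-peaked
#' "intact" component against a fixed arcsine "degraded" component whose mass
#' piles at both ends, modelling 5'/3' read pile-up. The two free parameters
#' are the intact-class weight `w` and the intact shape `a`.
#'
#' @slot w intact-component weight in `[0, 1]`.
#' @slot a intact-component symmetric shape, `>= 1`.
#' @slot loglik maximized log-likelihood.
#' @slot converged whether EM converged (FALSE for the degenerate
#'   zero-variance fallback).
#' @slot nIter number of EM iterations of the best start.
#' @slot n number of values fitted.
#' @aliases BetaMixtureFit-class
#' @exportClass BetaMixtureFit
setClass("BetaMixtureFit",
  representation(w = "numeric", a = "numeric", loglik = "numeric",
                 converged = "logical", nIter = "integer", n = "integer"))

setValidity("BetaMixtureFit", function(object) {
  msg <- character()
  if (object@w < 0 || object@w > 1) msg <- c(msg, "w must lie in [0, 1]")
  if (object@a < 1) msg <- c(msg, "a must be >= 1")
  if (object@converged && !is.finite(object@loglik))
    msg <- c(msg, "loglik must be finite when converged")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BetaMixtureFit", function(object) {
  cat(sprintf(
    "BetaMixtureFit: w = %.3f, a = %.2f, loglik = %.3f (%s, %d iter, n = %d)\n",
    object@w, object@a, object@loglik,
    if (object@converged) "converged" else "NOT converged",
    object@nIter, object@n))
})

#' @describeIn BetaMixtureFit intact-component weight.
#' @param x a `BetaMixtureFit`.
#' @export
intactWeight <- function(x) x@w

#' @describeIn BetaMixtureFit intact-component shape.
#' @export
intactShape <- function(x) x@a

#' ClearResult: per-sample outcome of the coverage-reliability filter
#'
#' @slot sampleId sample label.
#' @slot binFits `DataFrame` with one row per expression bin: `bin`, `n`,
#'   `exprMin`, `exprMax`, fitted `w`, `a`, `loglik`, `converged`,
#'   `smoothedW` (isotonic non-increasing smoothing of `w` over bins).
#' @slot cutoffBin index of the first bin whose smoothed weight falls below
#'   `wMin` (`NA` if none fails).
#' @slot expressionCutoff minimum expression among passing transcripts (`NA`
#'   if no transcript passes).
#' @slot passIds transcript ids passing the filter.
#' @slot config list: `binSize`, `wMin`, `minLastBin`.
#' @aliases ClearResult-class
#' @exportClass ClearResult
setClass("ClearResult",
  representation(sampleId = "character", binFits = "DataFrame",
                 cutoffBin = "integer", expressionCutoff = "numeric",
                 passIds = "character", config = "list"))

setMethod("show", "ClearResult", function(object) {
  cat(sprintf("ClearResult '%s': %d bins, %d transcripts pass\n",
              object@sampleId, nrow(object@binFits),
              length(object@passIds)))
  if (is.na(object@cutoffBin)) {
    cat("no failing bin (all bins pass)\n")
  } else {
    cat(sprintf("cutoff at bin %d (expression cutoff %.4g)\n",
                object@cutoffBin, object@expressionCutoff))
  }
})

#' @describeIn ClearResult ids of transcripts passing the filter.
#' @param x a `ClearResult`.
#' @export
passIds <- function(x) x@passIds

#' @describeIn ClearResult index of the first failing bin (`NA` if none).
#' @export
cutoffBin <- function(x) x@cutoffBin

#' @describeIn ClearResult per-bin fit table.
#' @export
binFits <- function(x) x@binFits
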