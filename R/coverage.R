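#' Read transcript models from a GTF file
#'
#' Imports exon records and assembles one transcript model per
#' `transcript_id`, represented as a [GenomicRanges::GRangesList] with one
#' `GRanges` of exons per transcript (exons sorted by genomic start, strand
#' recorded on the ranges). GTF coordinates are 1-based closed; the returned
#' ranges keep that convention (the native `GRanges` one), so a GTF exon
#' `11..20` has `start = 11`, `end = 20`, `width = 10`.
#'
#' @param path path to a GTF file with `exon` features carrying
#'   `transcript_id` attributes.
#' @return A named `GRangesList`, one element per transcript.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "src", "exon", "11", "20", ".", "+", ".",
#'                  "gene_id \"g1\"; transcript_id \"t1\";", sep = "\t"), gtf)
#' tx <- readTranscriptModels(gtf)
#' sum(GenomicRanges::width(tx[["t1"]]))  # 10
#' @export
readTranscriptModels <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("GTF parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  ex <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(ex) == 0) stop("no exon features in GTF: ", path)
  if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
    stop("exon records without transcript_id in GTF: ", path)
  id <- ex$transcript_id
  ex <- ex[order(id, GenomicRanges::start(ex))]
  id <- ex$transcript_id
  # vectorized per-transcript validity checks on the flat, sorted exon set
  if (length(unique(paste0(id, "\r", seqnames(ex)))) > length(unique(id)))
    stop("transcript on multiple chromosomes")
  if (length(unique(paste0(id, "\r", strand(ex)))) > length(unique(id)))
    stop("transcript with mixed strand")
  same <- id[-1L] == id[-length(id)]
  if (any(same &
          GenomicRanges::start(ex)[-1L] <= GenomicRanges::end(ex)[-length(ex)]))
    stop("overlapping exons within one transcript ",
         "(duplicate transcript_id with conflicting exons?)")
  S4Vectors::split(ex, id)
}

#' Read a per-base coverage map
#'
#' Reads a coverage map produced by a genome-coverage utility into a
#' run-length encoded per-chromosome depth vector ([IRanges::RleList]).
#' Two dialects are auto-detected:
#' \itemize{
#'   \item 4-column BedGraph: `chrom start end depth`, 0-based half-open;
#'   \item per-base depth: `chrom pos depth` (1-based position) or
#'     `pos depth` (single unnamed chromosome `"."`).
#' }
#' Absent positions report depth 0. Overlapping intervals with equal depth
#' are merged; overlapping intervals with conflicting depth are an error, as
#' is any negative depth.
#'
#' @param path path to the coverage file.
#' @return An `RleList`, one run-length encoded depth vector per chromosome.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t0\t5\t3", f)
#' cov <- readCoverage(f)
#' as.numeric(cov[["chr1"]])  # 3 3 3 3 3
#' @export
readCoverage <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  if (file.size(path) == 0L)
    return(RleList(compress = FALSE))
  first <- scan(path, what = "character", nlines = 1L, quiet = TRUE)
  ncol1 <- length(first)
  if (ncol1 == 4L) {
    gr <- tryCatch(
      rtracklayer::import(path, format = "bedGraph"),
      error = function(e) stop("BedGraph parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  } else if (ncol1 %in% c(2L, 3L)) {
    tab <- read.table(path, header = FALSE, sep = "",
                      stringsAsFactors = FALSE)
    if (ncol1 == 2L)
      tab <- data.frame(V1 = ".", V2 = tab[[1]], V3 = tab[[2]])
    if (!is.numeric(tab[[2]]) || !is.numeric(tab[[3]]))
      stop("coverage parse error in '", path,
           "': non-numeric position or depth")
    gr <- GRanges(tab[[1]], IRanges(tab[[2]], width = 1L),
                  score = tab[[3]])
  } else {
    stop("coverage parse error in '", path, "': expected 2-4 columns, got ",
         ncol1)
  }
  if (anyNA(gr$score)) stop("NA depth in coverage file: ", path)
  if (any(gr$score < 0)) stop("negative depth in coverage file: ", path)
  gr <- gr[gr$score > 0]
  if (length(gr) == 0L) return(RleList(compress = FALSE))
  hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits)) {
    conflict <- gr$score[S4Vectors::queryHits(hits)] !=
      gr$score[S4Vectors::subjectHits(hits)]
    if (any(conflict))
      stop("overlapping intervals with conflicting depth in: ", path)
    # equal-depth overlaps: merge per depth value so coverage() does not sum
    parts <- S4Vectors::split(gr, gr$score)
    parts <- lapply(seq_along(parts), function(i) {
      g <- reduce(parts[[i]])
      g$score <- as.numeric(names(parts)[i])
      g
    })
    gr <- do.call(c, parts)
  }
  coverage(gr, weight = "score")
}

#' Positional-mean coverage statistic for one transcript
#'
#' Builds the transcript-coordinate depth vector `d[1..L]` by concatenating
#' exon depths in 5'-to-3' order (genomic order is reversed for minus-strand
#' transcripts unless `unstranded = TRUE`), then computes
#' \deqn{\mu = \sum_p d_p x_p / \sum_p d_p, \qquad x_p = (p - 0.5)/L,}
#' the depth-weighted mean transcript position under the bin-centre
#' convention, so perfectly uniform coverage gives exactly 0.5 and coverage
#' piled at the 3' end pushes \eqn{\mu} towards 1. `expression` is the total
#' depth over the transcript; transcripts with zero total depth are
#' undetected and get `mu = NA`.
#'
#' @param model a `GRanges` of exons for one transcript (an element of
#'   [readTranscriptModels()]'s return value).
#' @param cov an `RleList` from [readCoverage()].
#' @param unstranded if `TRUE`, never reverse minus-strand transcripts
#'   (report the genomic-order mean).
#' @return A one-row `data.frame` with columns `expression`, `mu`,
#'   `detected`.
#' @export
positionalMean <- function(model, cov, unstranded = FALSE) {
  .positionalMeanDepth(
    .transcriptDepth(model, cov, unstranded = unstranded))
}

.positionalMeanDepth <- function(d) {
  expr <- sum(d)
  if (expr > 0) {
    L <- length(d)
    x <- (seq_len(L) - 0.5) / L
    mu <- sum(d * x) / expr
    data.frame(expression = expr, mu = mu, detected = TRUE)
  } else {
    data.frame(expression = 0, mu = NA_real_, detected = FALSE)
  }
}

# depth vector in transcript coordinates, 5'->3'.
# `chromDepth`, if supplied, is the chromosome's fully decompressed depth
# vector (used by coverageTable to avoid per-transcript Rle access).
.transcriptDepth <- function(model, cov, unstranded = FALSE,
                             chromDepth = NULL) {
  chrom <- as.character(seqnames(model))[1L]
  L <- sum(width(model))
  if (is.null(chromDepth)) {
    if (!chrom %in% names(cov)) return(numeric(L))
    chromDepth <- as.numeric(cov[[chrom]])
  }
  clen <- length(chromDepth)
  pos <- unlist(lapply(seq_along(model), function(i)
    seq.int(start(model)[i], end(model)[i])), use.names = FALSE)
  d <- numeric(L)
  inb <- pos <= clen
  d[inb] <- chromDepth[pos[inb]]
  minus <- as.character(strand(model))[1L] == "-"
  if (minus && !unstranded) d <- rev(d)
  d
}

#' Positional-mean table for a set of transcripts
#'
#' Applies [positionalMean()] to every transcript and returns a table sorted
#' by descending expression (ties broken by transcript id, stable), the input
#' order required by the expression-binning stage. Undetected transcripts
#' (zero coverage) are flagged and sort last; downstream binning uses only
#' detected rows.
#'
#' @param models a `GRangesList` from [readTranscriptModels()].
#' @param cov an `RleList` from [readCoverage()].
#' @param expression optional named numeric vector of external expression
#'   values (e.g. gene counts) overriding the coverage sums for ordering;
#'   names must cover the transcript ids.
#' @inheritParams positionalMean
#' @return A `data.frame` with columns `transcript_id`, `expression`, `mu`,
#'   `detected`, sorted by descending expression then id.
#' @export
coverageTable <- function(models, cov, unstranded = FALSE,
                          expression = NULL) {
  if (length(models) == 0L) stop("empty transcript model set")
  flat <- unlist(models, use.names = FALSE)
  txOf <- rep(names(models), lengths(models))
  # plain-vector views of the exon set; per-transcript work is then base R
  exStart <- GenomicRanges::start(flat)
  exEnd <- GenomicRanges::end(flat)
  exChrom <- as.character(seqnames(flat))
  exMinus <- as.character(strand(flat)) == "-"
  byTx <- split(seq_along(flat), txOf)[names(models)]
  chroms <- unique(exChrom)
  # decompress each chromosome's depth once; per-transcript access is then
  # plain vector indexing
  depths <- lapply(setNames(chroms, chroms), function(ch)
    if (ch %in% names(cov)) as.numeric(cov[[ch]]) else numeric(0))
  rows <- lapply(names(models), function(id) {
    ii <- byTx[[id]]
    chromDepth <- depths[[exChrom[ii[1L]]]]
    pos <- unlist(lapply(ii, function(i) seq.int(exStart[i], exEnd[i])),
                  use.names = FALSE)
    d <- numeric(length(pos))
    inb <- pos <= length(chromDepth)
    d[inb] <- chromDepth[pos[inb]]
    if (exMinus[ii[1L]] && !unstranded) d <- rev(d)
    cbind(transcript_id = id, .positionalMeanDepth(d))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(expression)) {
    miss <- setdiff(tab$transcript_id, names(expression))
    if (length(miss))
      stop("external expression missing for ", length(miss), " transcripts")
    tab$expression <- as.numeric(expression[tab$transcript_id])
    tab$detected <- tab$detected & tab$expression > 0
  }
  ord <- order(-tab$expression, tab$transcript_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  if (!any(tab$detected))
    warning("no detected transcripts: 0 binnable rows")
  tab
}
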