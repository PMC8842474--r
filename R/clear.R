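#' Cut a positional-mean table into sequential expression bins
#'
#' Detected transcripts, already ordered by descending expression, are cut
#' into consecutive bins of `binSize` positional means (bin 1 = highest
#' expression). A trailing partial bin with fewer than `minLastBin` values is
#' merged into the previous bin: too few points to fit the two mixture
#' parameters stably.
#'
#' @param stats the table from [coverageTable()] (or any data.frame with
#'   `transcript_id`, `expression`, `mu`, `detected`, sorted by descending
#'   expression).
#' @param binSize number of values per bin (default 250).
#' @param minLastBin minimum size of a standalone final bin (default 50).
#' @return A list of bins; each bin is a list with `bin` (index),
#'   `transcript_ids`, `mu`, `exprMin`, `exprMax`.
#' @export
binByExpression <- function(stats, binSize = 250, minLastBin = 50) {
  if (binSize < 2) stop("binSize must be >= 2")
  det <- stats[stats$detected, , drop = FALSE]
  n <- nrow(det)
  if (n < minLastBin)
    stop("insufficient transcripts for CLEAR: ", n, " detected, need >= ",
         minLastBin)
  if (is.unsorted(-det$expression))
    stop("stats must be sorted by descending expression")
  idx <- ceiling(seq_len(n) / binSize)
  nbin <- max(idx)
  if (nbin > 1L && sum(idx == nbin) < minLastBin)
    idx[idx == nbin] <- nbin - 1L
  lapply(seq_len(max(idx)), function(k) {
    rows <- det[idx == k, , drop = FALSE]
    list(bin = k, transcript_ids = rows$transcript_id, mu = rows$mu,
         exprMin = min(rows$expression), exprMax = max(rows$expression))
  })
}

# log-density of the fixed degraded component Beta(0.5, 0.5)
.ldeg <- function(x) dbeta(x, 0.5, 0.5, log = TRUE)

# mixture log-likelihood at (w, a)
.mixLoglik <- function(x, w, a) {
  sum(log(w * dbeta(x, a, a) + (1 - w) * exp(.ldeg(x))))
}

#' Fit a bin's positional means to the two-component beta mixture
#'
#' Maximizes
#' \deqn{\sum_i \log[\, w\,\mathrm{Beta}(\mu_i; a, a) +
#'   (1-w)\,\mathrm{Beta}(\mu_i; 0.5, 0.5)\,]}
#' over \eqn{w \in [0,1]} (intact-class weight) and \eqn{a \in [1, 500]}
#' (intact shape) by EM: the E-step computes intact-class responsibilities,
#' the M-step sets `w` to their mean and updates `a` by 1-D numeric
#' maximization of the responsibility-weighted intact log-likelihood. Three
#' starts (`a = 2, 10, 50`; `w = 0.5`) guard against local optima; the best
#' final likelihood wins. Convergence: log-likelihood improvement below
#' `tol`; the likelihood is checked to be non-decreasing at every iteration.
#' Values are clamped into `[1e-4, 1 - 1e-4]` so neither component's
#' log-density is infinite at the boundary.
#'
#' A zero-variance input cannot identify the mixture: the fit is returned
#' with `converged = FALSE` and `w = 1` if all values lie within 0.05 of 0.5
#' (pure intact), else `w = 0`.
#'
#' @param mu numeric vector of positional means in `[0, 1]`.
#' @param maxIter maximum EM iterations per start (default 500).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param aStarts initial intact shapes for the multi-start.
#' @return A [BetaMixtureFit-class].
#' @examples
#' set.seed(1)
#' fit <- fitBetaMixture(rbeta(250, 20, 20))
#' intactWeight(fit)  # close to 1
#' @export
fitBetaMixture <- function(mu, maxIter = 500, tol = 1e-6,
                           aStarts = c(2, 10, 50)) {
  x <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
  n <- length(x)
  if (var(x) == 0) {
    w <- if (all(abs(x - 0.5) <= 0.05)) 1 else 0
    return(new("BetaMixtureFit", w = w, a = 1, loglik = NA_real_,
               converged = FALSE, nIter = 0L, n = n))
  }
  ldeg <- .ldeg(x)
  best <- NULL
  for (a0 in aStarts) {
    w <- 0.5; a <- a0
    ll <- .mixLoglik(x, w, a)
    iter <- 0L; converged <- FALSE
    while (iter < maxIter) {
      iter <- iter + 1L
      f1 <- w * dbeta(x, a, a)
      f0 <- (1 - w) * exp(ldeg)
      r <- f1 / (f1 + f0)
      w <- mean(r)
      if (w > 0 && sum(r) > 0) {
        a <- optimize(function(aa) sum(r * dbeta(x, aa, aa, log = TRUE)),
                      c(1, 500), maximum = TRUE)$maximum
      }
      llNew <- .mixLoglik(x, w, a)
      if (llNew < ll - 1e-6 * (abs(ll) + 1))
        stop("EM log-likelihood decreased (", ll, " -> ", llNew, ")")
      if (llNew - ll < tol) { ll <- llNew; converged <- TRUE; break }
      ll <- llNew
    }
    if (is.null(best) || ll > best$ll)
      best <- list(w = w, a = a, ll = ll, iter = iter,
                   converged = converged)
  }
  new("BetaMixtureFit", w = min(max(best$w, 0), 1), a = max(best$a, 1),
      loglik = best$ll, converged = best$converged, nIter = best$iter,
      n = n)
}

#' Threshold the smoothed mixture parameters into a pass/fail cutoff
#'
#' Both free parameters of the per-bin fits are thresholded. The intact-class
#' weights are smoothed by isotonic non-increasing regression over bin
#' index -- degradation bias only grows as expression falls, so a single
#' noisy mid-bin should not truncate the pass set -- and a bin fails when its
#' smoothed weight drops below `wMin`. The intact shapes are smoothed the
#' same way (on the log scale) and a bin also fails when its smoothed shape
#' drops below `aMin`: if the fitted "intact" component is no more
#' centre-concentrated than `Beta(aMin, aMin)`, the fit found no genuine
#' intact population in that bin (end-shifted coverage drives the maximum
#' likelihood to a near-uniform intact component with `a` close to 1, not to
#' a low weight). The first failing bin defines the cutoff; transcripts in
#' earlier bins pass, and if no bin fails everything passes.
#'
#' @param bins list of bins from [binByExpression()].
#' @param fits list of [BetaMixtureFit-class] objects, parallel to `bins`.
#' @param wMin intact-weight threshold (default 0.5: the majority of a bin's
#'   transcripts must look intact).
#' @param aMin intact-shape threshold (default 2: the weakest
#'   centre-peaked beta accepted as an intact class).
#' @param sampleId label stored in the result.
#' @param binSize,minLastBin configuration echoed into the result.
#' @return A [ClearResult-class].
#' @export
deriveCutoff <- function(bins, fits, wMin = 0.5, aMin = 2,
                         sampleId = "sample",
                         binSize = 250, minLastBin = 50) {
  stopifnot(length(bins) == length(fits), length(bins) >= 1)
  w <- vapply(fits, intactWeight, numeric(1))
  a <- vapply(fits, intactShape, numeric(1))
  k <- length(w)
  smoothed <- if (k == 1L) w else -isoreg(seq_len(k), -w)$yf
  smoothedA <- if (k == 1L) a else exp(-isoreg(seq_len(k), -log(a))$yf)
  fail <- which(smoothed < wMin | smoothedA < aMin)
  cutoff <- if (length(fail)) fail[1L] else NA_integer_
  passBins <- if (is.na(cutoff)) seq_len(k) else seq_len(cutoff - 1L)
  ids <- unlist(lapply(bins[passBins], `[[`, "transcript_ids"),
                use.names = FALSE)
  if (length(ids) == 0L)
    warning("first bin fails the intact-weight threshold: empty pass set")
  exprCut <- if (length(passBins))
    min(vapply(bins[passBins], `[[`, numeric(1), "exprMin"))
  else NA_real_
  tab <- DataFrame(
    bin = vapply(bins, `[[`, numeric(1), "bin"),
    n = vapply(bins, function(b) length(b$mu), numeric(1)),
    exprMin = vapply(bins, `[[`, numeric(1), "exprMin"),
    exprMax = vapply(bins, `[[`, numeric(1), "exprMax"),
    w = w,
    a = a,
    loglik = vapply(fits, function(f) f@loglik, numeric(1)),
    converged = vapply(fits, function(f) f@converged, logical(1)),
    smoothedW = smoothed,
    smoothedA = smoothedA)
  new("ClearResult", sampleId = sampleId, binFits = tab,
      cutoffBin = as.integer(cutoff), expressionCutoff = exprCut,
      passIds = as.character(ids),
      config = list(binSize = binSize, wMin = wMin, aMin = aMin,
                    minLastBin = minLastBin))
}

#' Run the full coverage-reliability filter on one sample
#'
#' Convenience wrapper: [binByExpression()] then [fitBetaMixture()] per bin
#' then [deriveCutoff()].
#'
#' @inheritParams binByExpression
#' @inheritParams deriveCutoff
#' @return A [ClearResult-class].
#' @export
clearFilter <- function(stats, binSize = 250, wMin = 0.5, aMin = 2,
                        minLastBin = 50, sampleId = "sample") {
  bins <- binByExpression(stats, binSize = binSize, minLastBin = minLastBin)
  fits <- lapply(bins, function(b) fitBetaMixture(b$mu))
  deriveCutoff(bins, fits, wMin = wMin, aMin = aMin, sampleId = sampleId,
               binSize = binSize, minLastBin = minLastBin)
}

#' Intersect pass sets across samples
#'
#' Only genes passing the filter in every sample are kept for downstream
#' analysis.
#'
#' @param results list of [ClearResult-class] objects (or plain character
#'   vectors of ids).
#' @return Character vector of ids passing in all samples.
#' @export
intersectClear <- function(results) {
  if (length(results) < 1) stop("need at least one ClearResult")
  sets <- lapply(results, function(r)
    if (is(r, "ClearResult")) passIds(r) else as.character(r))
  out <- Reduce(intersect, sets)
  if (length(out) == 0L)
    warning("empty intersection of pass sets")
  out
}
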