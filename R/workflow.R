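# classed conditions so a shell wrapper can map failures to exit codes:
# config/IO problems -> "lclear_config_error" (exit 2),
# analysis-stage failures -> "lclear_analysis_error" (exit 1)
.configError <- function(...) {
  stop(structure(class = c("lclear_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.asAnalysisError <- function(expr, stage) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "lclear_config_error")) stop(e)
    stop(structure(
      class = c("lclear_analysis_error", "error", "condition"),
      list(message = paste0("stage '", stage, "': ", conditionMessage(e)),
           call = NULL)))
  })
}

.defaultConfig <- function() {
  list(
    seed = 1,
    stages = list(simulate = TRUE, clear = TRUE, qc = TRUE, deg = TRUE,
                  diagnostics = TRUE, permutation = FALSE),
    simulate = list(
      n_genes = 1000, deg_fraction = 0.1, fc_range = c(1.5, 6),
      coverage = list(n_transcripts = 1000, tau_rank = 500, kappa = 0.1),
      bulk = list(input_level = "lvl_1ng", n_replicates = 3),
      sc = list(n_cells = 150)),
    clear = list(bin_size = 250, w_min = 0.5, min_last_bin = 50),
    qc = list(min_features = 1000, max_features = 2500, scale = 10000),
    deg = list(wilcoxon = list(lfc_min = 0.36, alpha = 0.05, min_pct = 0.1),
               nb_wald = list(lfc_min = 1.0, alpha = 0.05)),
    permutation = list(n_perm = 20, engine = "wilcoxon"))
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Validate and normalize a workflow configuration
#'
#' Accepts a YAML file path or a nested list, merges it over the package
#' defaults (every default matches the conventional value where one exists:
#' bin size 250, feature-count bounds 1000/2500, scale 10000, fold-change
#' minima 0.36 and 1.0, alpha 0.05), and checks cross-stage dependencies
#' before anything runs: a stage that consumes another stage's output must
#' either find that stage enabled or be given input paths.
#'
#' @param config YAML path or list; `NULL` for pure defaults.
#' @return The merged config list (with `config_hash` attached).
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) .configError("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) .configError("config must be a list or YAML path")
  cfg <- .mergeConfig(.defaultConfig(), config)
  st <- cfg$stages
  if (isTRUE(st$clear) && !isTRUE(st$simulate) &&
      is.null(cfg$inputs$stats_tsv) &&
      (is.null(cfg$inputs$gtf) || is.null(cfg$inputs$bedgraph)))
    .configError("clear stage enabled without simulate stage or input paths",
                 " (inputs$stats_tsv, or inputs$gtf + inputs$bedgraph)")
  if ((isTRUE(st$deg) || isTRUE(st$diagnostics) || isTRUE(st$permutation)) &&
      !isTRUE(st$simulate) && is.null(cfg$inputs$counts_tsv))
    .configError("count-consuming stage enabled without simulate stage or ",
                 "inputs$counts_tsv")
  for (p in unlist(cfg$inputs)) {
    if (!file.exists(p)) .configError("input file not found: ", p)
  }
  attr(cfg, "config_hash") <-
    substr(digestConfig(cfg), 1, 12)
  cfg
}

# deterministic config fingerprint (no external digest dependency)
digestConfig <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  f <- tempfile(); on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the workflow end to end
#'
#' Executes the enabled stages in dependency order -- simulate, coverage
#' reliability filter, counts QC, both DEG engines, bias diagnostics,
#' permutation null -- and collects every result into a report bundle.
#' All randomness derives from `config$seed`; an identical config reproduces
#' an identical bundle. Progress is logged to standard error.
#'
#' @param config YAML path or list, see [validateConfig()].
#' @return A list (the report bundle): `config`, `config_hash`, and one
#'   element per executed stage (`sim_truth`, `clear`, `qc`, `deg_wilcoxon`,
#'   `deg_nb`, `rank_bias`, `fc_comparison`, `overlap`, `cv`,
#'   `permutation`).
#' @export
runWorkflow <- function(config = NULL) {
  cfg <- validateConfig(config)
  seed <- cfg$seed
  log <- function(...) message("[lclear] ", sprintf(...))
  bundle <- list(config = cfg, config_hash = attr(cfg, "config_hash"))
  st <- cfg$stages

  truth <- bulk <- sc <- stats <- NULL
  if (isTRUE(st$simulate)) {
    truth <- .asAnalysisError(simulateTruth(
      nGenes = cfg$simulate$n_genes, degFraction = cfg$simulate$deg_fraction,
      fcRange = cfg$simulate$fc_range, seed = seed), "simulate")
    bundle$sim_truth <- truth
    log("simulate: %d genes, %d true DEGs", nrow(truth), sum(truth$is_deg))
  }

  if (isTRUE(st$clear)) {
    stats <- .asAnalysisError({
      if (isTRUE(st$simulate)) {
        cc <- cfg$simulate$coverage
        sim <- simulateCoverage(nTranscripts = cc$n_transcripts,
                                kappa = cc$kappa, tau = NULL,
                                seed = seed + 1)
        if (!is.null(cc$tau_rank)) {
          # re-simulate with the transition pinned at the requested rank
          tau <- log10(sort(sim$truth$n_reads,
                            decreasing = TRUE)[cc$tau_rank])
          sim <- simulateCoverage(nTranscripts = cc$n_transcripts,
                                  kappa = cc$kappa, tau = tau,
                                  seed = seed + 1)
        }
        bundle$coverage_sim <- sim["truth"]
        models <- readTranscriptModels(sim$gtf)
        cov <- readCoverage(sim$bedgraph)
      } else if (!is.null(cfg$inputs$stats_tsv)) {
        models <- NULL; cov <- NULL
      } else {
        models <- readTranscriptModels(cfg$inputs$gtf)
        cov <- readCoverage(cfg$inputs$bedgraph)
      }
      if (!is.null(cfg$inputs$stats_tsv))
        read.table(cfg$inputs$stats_tsv, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
      else coverageTable(models, cov)
    }, "coverage_stats")
    bundle$clear <- .asAnalysisError(
      clearFilter(stats, binSize = cfg$clear$bin_size,
                  wMin = cfg$clear$w_min,
                  minLastBin = cfg$clear$min_last_bin), "clear")
    log("clear: %d of %d detected transcripts pass",
        length(passIds(bundle$clear)), sum(stats$detected))
  }

  if (isTRUE(st$simulate) && (isTRUE(st$deg) || isTRUE(st$diagnostics) ||
                              isTRUE(st$permutation) || isTRUE(st$qc))) {
    bulk <- .asAnalysisError(simulateBulkCounts(
      truth, inputLevel = cfg$simulate$bulk$input_level,
      nReplicates = cfg$simulate$bulk$n_replicates, seed = seed + 2),
      "simulate_bulk")
    sc <- .asAnalysisError(simulateScCounts(
      truth, nCells = cfg$simulate$sc$n_cells, seed = seed + 3),
      "simulate_sc")
  } else if (!is.null(cfg$inputs$counts_tsv)) {
    bulk <- .asAnalysisError(readCounts(
      cfg$inputs$counts_tsv, format = "tsv",
      design = cfg$inputs$design), "read_counts")
  }

  if (isTRUE(st$qc) && !is.null(sc)) {
    bundle$qc <- .asAnalysisError({
      filtered <- tryCatch(
        filterCells(sc, minFeatures = cfg$qc$min_features,
                    maxFeatures = cfg$qc$max_features),
        error = function(e) sc)  # synthetic cells may all sit in-bounds
      list(cells_before = ncol(sc), cells_after = ncol(filtered),
           capture = qcSummary(ncol(sc), ncol(filtered)))
    }, "qc")
    log("qc: %d of %d cells kept", bundle$qc$cells_after,
        bundle$qc$cells_before)
  }

  if (isTRUE(st$deg) && !is.null(bulk)) {
    bundle$deg_nb <- .asAnalysisError({
      sf <- medianOfRatios(bulk, pseudoReference = TRUE)
      disp <- estimateDispersionsNB(bulk, sf)
      nbWaldDEG(bulk, sf, disp, lfcMin = cfg$deg$nb_wald$lfc_min,
                alpha = cfg$deg$nb_wald$alpha)
    }, "deg_nb")
    log("nb_wald: %d DEGs", sum(bundle$deg_nb$is_deg))
    if (!is.null(sc)) {
      bundle$deg_wilcoxon <- .asAnalysisError({
        norm <- logNormalize(sc, scale = cfg$qc$scale)
        wilcoxonDEG(norm, lfcMin = cfg$deg$wilcoxon$lfc_min,
                    alpha = cfg$deg$wilcoxon$alpha,
                    minPct = cfg$deg$wilcoxon$min_pct)
      }, "deg_wilcoxon")
      log("wilcoxon: %d DEGs", sum(bundle$deg_wilcoxon$is_deg))
    }
  }

  if (isTRUE(st$diagnostics) && !is.null(bundle$deg_nb)) {
    bundle <- .asAnalysisError({
      rk <- countRanks(bulk)
      nbDeg <- bundle$deg_nb$gene[bundle$deg_nb$is_deg]
      if (length(nbDeg) > 0 && length(nbDeg) < nrow(rk))
        bundle$rank_bias <- list(bulk = rankBiasTest(rk, nbDeg))
      if (!is.null(bundle$deg_wilcoxon)) {
        scDeg <- bundle$deg_wilcoxon$gene[bundle$deg_wilcoxon$is_deg]
        rkSc <- countRanks(sc)
        if (length(scDeg) > 0 && length(scDeg) < nrow(rkSc))
          bundle$rank_bias$sc <- rankBiasTest(rkSc, scDeg)
        if (length(scDeg) > 0 && length(nbDeg) > 0) {
          bundle$fc_comparison <- fcCompare(bundle$deg_nb,
                                            bundle$deg_wilcoxon)
          bundle$overlap <- overlapSets(list(nb_wald = nbDeg,
                                             wilcoxon = scDeg))
        }
      }
      # replicate CV within each bulk group on the unfiltered matrix
      cvRaw <- cvReport(bulk)
      cvRaw$filtered <- FALSE
      bundle$cv <- cvRaw
      bundle
    }, "diagnostics")
  }

  if (isTRUE(st$permutation) && !is.null(sc)) {
    bundle$permutation <- .asAnalysisError({
      norm <- logNormalize(sc, scale = cfg$qc$scale)
      permutationNull(norm, nPerm = cfg$permutation$n_perm,
                      seed = seed + 4, engine = "wilcoxon",
                      lfcMin = cfg$deg$wilcoxon$lfc_min)
    }, "permutation")
    log("permutation: %d of %d splits with 0 DEGs",
        sum(bundle$permutation$deg_counts == 0), cfg$permutation$n_perm)
  }

  bundle
}

#' Write a report bundle to disk
#'
#' Serializes a [runWorkflow()] bundle: a machine-readable `summary.json`
#' (config echo, hash, scalar summaries), one TSV per DEG table
#' (`deg_wilcoxon.tsv`, `deg_nb_wald.tsv`), the per-bin filter table
#' (`clear_bins.tsv`) and pass list (`clear_pass.tsv`), the simulation truth
#' (`sim_truth.tsv`) and the CV table (`cv.tsv`). Filenames are stable;
#' re-writing to the same directory overwrites deterministically.
#'
#' @param bundle a bundle from [runWorkflow()].
#' @param outDir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir))
    .configError("cannot create output directory: ", outDir)
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(outDir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$deg_wilcoxon)) wtsv(bundle$deg_wilcoxon,
                                          "deg_wilcoxon.tsv")
  if (!is.null(bundle$deg_nb)) wtsv(bundle$deg_nb, "deg_nb_wald.tsv")
  if (!is.null(bundle$sim_truth)) wtsv(bundle$sim_truth, "sim_truth.tsv")
  if (!is.null(bundle$cv)) wtsv(bundle$cv, "cv.tsv")
  if (!is.null(bundle$clear)) {
    wtsv(as.data.frame(binFits(bundle$clear)), "clear_bins.tsv")
    wtsv(data.frame(transcript_id = passIds(bundle$clear)),
         "clear_pass.tsv")
  }
  summary <- list(
    config_hash = bundle$config_hash,
    seed = bundle$config$seed,
    stages = bundle$config$stages,
    qc = bundle$qc,
    clear = if (!is.null(bundle$clear)) list(
      cutoff_bin = cutoffBin(bundle$clear),
      n_pass = length(passIds(bundle$clear)),
      expression_cutoff = bundle$clear@expressionCutoff),
    deg = list(
      wilcoxon = if (!is.null(bundle$deg_wilcoxon))
        sum(bundle$deg_wilcoxon$is_deg),
      nb_wald = if (!is.null(bundle$deg_nb)) sum(bundle$deg_nb$is_deg)),
    rank_bias = bundle$rank_bias,
    fc_comparison = bundle$fc_comparison,
    overlap = if (!is.null(bundle$overlap))
      list(sizes = as.list(bundle$overlap$sizes),
           pairwise = bundle$overlap$pairwise),
    permutation = if (!is.null(bundle$permutation))
      list(engine = bundle$permutation$engine,
           n_perm = bundle$permutation$n_perm,
           n_zero_deg = sum(bundle$permutation$deg_counts == 0)))
  p <- file.path(outDir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}
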