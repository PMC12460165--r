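#' Pipeline configuration
#'
#' Exactly one of (a) input file paths (\code{countsFile}, \code{lengthsFile},
#' \code{samplesFile}) or (b) a \linkS4class{SimConfig} must be supplied.
#'
#' @param countsFile,lengthsFile,samplesFile input paths.
#' @param simConfig a \linkS4class{SimConfig} (or path to a flat key-value
#'   config file) to simulate the inputs instead.
#' @param alpha DE FDR threshold in (0, 1).
#' @param minSize minimum exclusive-set size for scoring.
#' @param signMode intersection sign policy (see
#'   \code{\link{buildDrivenSets}}).
#' @param logTPM correlate log2(TPM + 1) (default) instead of raw TPM; see
#'   \code{\link{scoreAll}}.
#' @param epsilon fold-change guard on the control mean score.
#' @param outDir output directory (one directory per run).
#' @param seed RNG seed; overrides the SimConfig seed when simulating.
#' @return validated config list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(countsFile = NULL, lengthsFile = NULL,
                           samplesFile = NULL, simConfig = NULL,
                           alpha = 0.05, minSize = 10,
                           signMode = "concordant", logTPM = TRUE,
                           epsilon = 0.05, outDir, seed = 1L) {
  havePaths <- !is.null(countsFile) || !is.null(samplesFile)
  if (havePaths && !is.null(simConfig))
    stop("provide either input paths or a SimConfig, not both",
         call. = FALSE)
  if (!havePaths && is.null(simConfig))
    stop("provide input paths or a SimConfig", call. = FALSE)
  if (havePaths && (is.null(countsFile) || is.null(samplesFile) ||
                    is.null(lengthsFile)))
    stop("path input needs countsFile, lengthsFile and samplesFile",
         call. = FALSE)
  .assertScalarNum(alpha, "alpha", min = 0, max = 1)
  if (alpha == 0 || alpha == 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (is.character(simConfig)) simConfig <- readSimConfig(simConfig)
  structure(list(countsFile = countsFile, lengthsFile = lengthsFile,
                 samplesFile = samplesFile, simConfig = simConfig,
                 alpha = alpha, minSize = minSize, signMode = signMode,
                 logTPM = logTPM, epsilon = epsilon, outDir = outDir,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full STAT-score pipeline
#'
#' Stages: (optional) simulate inputs -> DE of every reference condition
#' versus control -> driven / exclusive signature sets -> TPM -> per-sample
#' STAT scores -> condition means and fold changes versus control -> PCA.
#' All interface files are written under \code{config$outDir} together with a
#' run manifest (config snapshot, package version, seed, md5 checksum of
#' every emitted file). Deterministic given config and seed.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outDir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$simConfig)) {
    sc <- config$simConfig
    sc@seed <- config$seed
    sim <- stage("simulate", simulateExperiment(sc))
    experiment <- sim$experiment
    truth <- sim$truth
    stage("simulate", writeFixture(experiment, truth, config$outDir))
  } else {
    experiment <- stage("read", readCytokineExperiment(
      config$countsFile, config$samplesFile, config$lengthsFile))
  }

  refStat <- referenceStats(experiment)
  deSets <- list()
  for (cn in names(refStat)) {
    tab <- stage(paste0("de:", cn),
                 deTest(experiment, cn, alpha = config$alpha))
    .writeTSV(tab, out(paste0("de_", cn, ".tsv")))
    sig <- tab[tab$significant, , drop = FALSE]
    deSets[[cn]] <- stats::setNames(as.numeric(sig$sign), sig$gene)
  }

  driven <- stage("signatures",
                  buildDrivenSets(deSets, refStat, signMode = config$signMode))
  sigs <- stage("signatures", buildSignatureSets(driven, refStat))
  report <- validateSignatures(sigs, minSize = config$minSize)
  report$reference_conditions <- vapply(
    sigs, function(s) paste(s@referenceConditions, collapse = ","), "")
  .writeTSV(report, out("signature_summary.tsv"))
  for (stat in names(sigs)) {
    s <- sigs[[stat]]
    .writeTSV(data.frame(gene = names(s@driven), sign = unname(s@driven),
                         in_exclusive = names(s@driven) %in% s@exclusive),
              out(paste0("signature_", stat, ".tsv")))
  }

  tpmMat <- stage("tpm", tpmMatrix(experiment))
  scores <- stage("score", scoreAll(tpmMat, sigs, sampleSheet(experiment),
                                    minSize = config$minSize,
                                    logTPM = config$logTPM))
  .writeTSV(sampleScores(scores), out("scores.tsv"))
  fc <- stage("fold_change",
              scoreFoldChange(scores, epsilon = config$epsilon))
  .writeTSV(fc, out("condition_scores.tsv"))

  pca <- stage("pca", tryCatch(pcaScores(scores), error = function(e) NULL))
  if (!is.null(pca)) {
    .writeTSV(data.frame(sample = rownames(pca$coordinates),
                         pca$coordinates, check.names = FALSE),
              out("pca.tsv"))
    .writeTSV(data.frame(component = paste0("PC",
                                            seq_along(pca$varianceExplained)),
                         fraction = pca$varianceExplained),
              out("pca_variance.tsv"))
  }

  files <- sort(setdiff(list.files(config$outDir), "run_manifest.json"))
  checksums <- as.list(tools::md5sum(out(files)))
  names(checksums) <- files
  manifest <- list(
    package = "STATscore",
    version = as.character(utils::packageVersion("STATscore")),
    seed = config$seed,
    config = list(alpha = config$alpha, min_size = config$minSize,
                  sign_mode = config$signMode, log_tpm = config$logTPM,
                  epsilon = config$epsilon,
                  simulated = !is.null(config$simConfig)),
    checksums = checksums,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Verify a run directory against its manifest
#'
#' Re-checksums every file recorded in \code{run_manifest.json}; any
#' single-byte mutation of an intermediate file changes its md5 and is
#' reported.
#'
#' @param dir a completed run directory.
#' @return data.frame: file, recorded, current, ok.
#' @export
verifyManifest <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "run_manifest.json"))
  files <- names(mf$checksums)
  current <- unname(tools::md5sum(file.path(dir, files)))
  data.frame(file = files,
             recorded = unlist(mf$checksums, use.names = FALSE),
             current = current,
             ok = unlist(mf$checksums, use.names = FALSE) == current,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Plain-text summary report of a completed run
#'
#' Collates signature sizes, condition-mean scores, fold changes versus
#' control, and the PCA variance table into \code{report.txt}. Timestamps are
#' deliberately excluded so a deterministic run yields a byte-identical
#' report body.
#'
#' @param dir a completed run directory.
#' @return the report lines, invisibly.
#' @export
pipelineReport <- function(dir) {
  need <- c("signature_summary.tsv", "scores.tsv", "condition_scores.tsv")
  absent <- need[!file.exists(file.path(dir, need))]
  if (length(absent))
    stop("missing stage output(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE)
  sig <- rd("signature_summary.tsv")
  fc <- rd("condition_scores.tsv")
  lines <- c("STATscore run report", strrep("=", 60), "",
             "Signature sets:")
  for (i in seq_len(nrow(sig))) {
    lines <- c(lines, sprintf(
      "  %s: %d driven, %d exclusive (%s)%s", sig$stat[i], sig$n_driven[i],
      sig$n_exclusive[i], sig$reference_conditions[i],
      if (sig$flagged[i])
        sprintf("  [FLAGGED: below minimum size; scores reported missing]")
      else ""))
  }
  lines <- c(lines, "", "Condition-mean scores and fold change vs control:")
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  lines <- c(lines, sprintf("  %-16s %-6s %10s %10s %10s", "condition",
                            "stat", "mean", "FC", "diff"))
  for (i in seq_len(nrow(fc)))
    lines <- c(lines, sprintf("  %-16s %-6s %10s %10s %10s",
                              fc$condition[i], fc$stat[i],
                              fmt(fc$mean_score[i]), fmt(fc$fold_change[i]),
                              fmt(fc$difference[i])))
  pv <- file.path(dir, "pca_variance.tsv")
  if (file.exists(pv)) {
    v <- rd("pca_variance.tsv")
    lines <- c(lines, "", "PCA variance explained:",
               sprintf("  %s: %.4f", v$component, v$fraction))
  }
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(lines)
}
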