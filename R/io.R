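## Strict TSV reader: every row must have the header's field count; errors
## name the first offending line so truncated files fail loudly.
.readStrictTSV <- function(path, what) {
  lines <- readLines(path)
  if (!length(lines)) stop(what, ": empty file '", path, "'", call. = FALSE)
  ## sentinel keeps trailing empty fields that strsplit would drop
  fields <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  nCol <- length(fields[[1]])
  nf <- lengths(fields)
  bad <- which(nf != nCol)
  if (length(bad))
    stop(what, ": parse error at line ", bad[1], " of '", path, "': ",
         nf[bad[1]], " fields, expected ", nCol, call. = FALSE)
  header <- fields[[1]]
  body <- fields[-1]
  mat <- matrix(unlist(body), ncol = nCol, byrow = TRUE)
  colnames(mat) <- header
  mat
}

#' Read a counts + sample-sheet (+ lengths) file set
#'
#' \code{counts.tsv}: first column gene id, remaining columns one per sample,
#' integer cells. \code{samples.tsv}: columns sample, condition, role,
#' reference_stat (empty allowed). \code{lengths.tsv}: columns gene, length.
#' Cross-file consistency (samples and genes present in both files) is
#' enforced.
#'
#' @param countsFile,samplesFile,lengthsFile paths; \code{lengthsFile} may be
#'   NULL when TPM is not needed.
#' @return a \linkS4class{CytokineExperiment}.
#' @export
readCytokineExperiment <- function(countsFile, samplesFile,
                                   lengthsFile = NULL) {
  cm <- .readStrictTSV(countsFile, "counts")
  genes <- cm[, 1]
  if (anyDuplicated(genes))
    stop("counts: duplicated gene ids in '", countsFile, "'", call. = FALSE)
  num <- cm[, -1, drop = FALSE]
  counts <- matrix(suppressWarnings(as.numeric(num)), nrow = nrow(num),
                   dimnames = list(genes, colnames(num)))
  if (anyNA(counts))
    stop("counts: non-numeric cell in '", countsFile, "'", call. = FALSE)
  sm <- .readStrictTSV(samplesFile, "samples")
  need <- c("sample", "condition", "role", "reference_stat")
  if (!all(need %in% colnames(sm)))
    stop("samples: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  sheet <- as.data.frame(sm, stringsAsFactors = FALSE)
  lens <- NULL
  if (!is.null(lengthsFile)) {
    lm <- .readStrictTSV(lengthsFile, "lengths")
    lens <- stats::setNames(as.integer(lm[, 2]), lm[, 1])
  }
  CytokineExperiment(counts, sheet, geneLengths = lens)
}

#' Serialize a SimTruth to JSON
#'
#' Schema (stable key order): \code{programs} (STAT -> {gene: sign}),
#' \code{offtarget} (condition -> [genes]), \code{activation} (condition ->
#' {STAT: alpha}), \code{baseline_means}, \code{gene_lengths},
#' \code{depth_factors}.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path output path.
#' @export
writeSimTruth <- function(truth, path) {
  obj <- list(
    programs = lapply(truth@programMembers, as.list),
    offtarget = lapply(truth@offtargetMembers, as.list),
    activation = apply(truth@conditionActivation, 1, as.list,
                       simplify = FALSE),
    baseline_means = as.list(truth@baselineMeans),
    gene_lengths = as.list(truth@geneLengths),
    depth_factors = as.list(truth@depthFactors))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(path) {
  obj <- jsonlite::read_json(path)
  toNum <- function(x) vapply(x, as.numeric, 1)
  act <- t(vapply(obj$activation, toNum,
                  numeric(length(obj$activation[[1]]))))
  dimnames(act) <- list(names(obj$activation), names(obj$activation[[1]]))
  new("SimTruth",
      programMembers = lapply(obj$programs, toNum),
      conditionActivation = act,
      baselineMeans = toNum(obj$baseline_means),
      geneLengths = vapply(obj$gene_lengths, as.integer, 1L),
      offtargetMembers = lapply(obj$offtarget,
                                function(x) unlist(lapply(x, as.character))),
      depthFactors = toNum(obj$depth_factors))
}

#' Write a simulated experiment as a plain-text fixture
#'
#' Emits \code{counts.tsv}, \code{lengths.tsv}, \code{samples.tsv} and
#' \code{truth.json} under \code{dir}; the file set round-trips losslessly
#' through \code{\link{readCytokineExperiment}} / \code{\link{readSimTruth}}.
#'
#' @param experiment a \linkS4class{CytokineExperiment}.
#' @param truth optional \linkS4class{SimTruth}.
#' @param dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
writeFixture <- function(experiment, truth = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cts <- counts(experiment)
  df <- data.frame(gene = rownames(cts), cts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  paths <- file.path(dir, c("counts.tsv", "lengths.tsv", "samples.tsv"))
  .writeTSV(df, paths[1])
  .writeTSV(data.frame(gene = rownames(cts),
                       length = unname(geneLengths(experiment))), paths[2])
  sheet <- sampleSheet(experiment)
  sheet$reference_stat[is.na(sheet$reference_stat)] <- ""  # empty allowed
  .writeTSV(sheet, paths[3])
  if (!is.null(truth)) {
    tp <- file.path(dir, "truth.json")
    writeSimTruth(truth, tp)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Read/write a SimConfig in a flat key-value text format
#'
#' Scalar fields are \code{key = value} lines; vector fields are
#' comma-separated; program sizes are \code{STAT:size} pairs; each condition
#' is one \code{condition = name|role|reference_stat|STAT:alpha,...} line
#' (empty reference_stat and activation allowed).
#'
#' @param path file path.
#' @return \code{readSimConfig}: a \linkS4class{SimConfig}.
#' @export
readSimConfig <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- regmatches(lines, regexec("^\\s*([a-z0-9_]+)\\s*=\\s*(.*?)\\s*$",
                                  lines, perl = TRUE))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    stop("config: cannot parse line '", lines[bad[1]], "'", call. = FALSE)
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  getOne <- function(key, default = NULL) {
    i <- which(keys == key)
    if (!length(i)) return(default)
    vals[i[1]]
  }
  num <- function(key, default) as.numeric(getOne(key, default))
  pairs <- function(x) {
    parts <- strsplit(strsplit(x, ",")[[1]], ":")
    stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                    trimws(vapply(parts, `[`, "", 1)))
  }
  sizes <- pairs(getOne("program_sizes",
                        "STAT1:200,STAT3:200,STAT5:200,STAT6:200"))
  condLines <- vals[keys == "condition"]
  conditions <- NULL; activation <- NULL
  if (length(condLines)) {
    parts <- strsplit(condLines, "|", fixed = TRUE)
    ## strsplit drops trailing empty fields; pad back to 4
    parts <- lapply(parts, function(p) {
      if (length(p) > 4L)
        stop("config: condition lines need name|role|reference_stat|",
             "activation", call. = FALSE)
      c(p, rep("", 4L - length(p)))
    })
    conditions <- data.frame(
      name = trimws(vapply(parts, `[`, "", 1)),
      role = trimws(vapply(parts, `[`, "", 2)),
      reference_stat = trimws(vapply(parts, `[`, "", 3)),
      stringsAsFactors = FALSE)
    conditions$reference_stat[conditions$reference_stat == ""] <-
      NA_character_
    activation <- matrix(0, nrow(conditions), length(.STATS),
                         dimnames = list(conditions$name, .STATS))
    for (i in seq_along(parts)) {
      spec <- trimws(parts[[i]][4])
      if (nzchar(spec)) {
        a <- pairs(spec)
        activation[i, names(a)] <- a
      }
    }
  }
  simConfig(
    nGenes = num("n_genes", 2000),
    programSizes = sizes,
    overlapFraction = num("overlap_fraction", 0),
    fracRepressed = num("frac_repressed", 0.3),
    effectLog2FC = num("effect_log2fc", 2),
    dispersion = num("dispersion", 0.1),
    baselineLog2Mean = num("baseline_log2_mean", 6),
    baselineLog2SD = num("baseline_log2_sd", 2),
    libSizeRange = as.numeric(strsplit(getOne("library_size_range",
                                              "0.7,1.3"), ",")[[1]]),
    nReplicates = num("n_replicates", 3),
    conditions = conditions, activation = activation,
    offtargetFraction = num("offtarget_fraction", 0.1),
    geneLengthRange = as.integer(strsplit(getOne("gene_length_range",
                                                 "500,10000"), ",")[[1]]),
    seed = num("seed", 1))
}

#' @rdname readSimConfig
#' @param config a \linkS4class{SimConfig} to serialize.
#' @export
writeSimConfig <- function(config, path) {
  fmtPairs <- function(x) paste(names(x), x, sep = ":", collapse = ",")
  lines <- c(
    paste("n_genes =", config@nGenes),
    paste("program_sizes =", fmtPairs(config@programSizes)),
    paste("overlap_fraction =", config@overlapFraction),
    paste("frac_repressed =", config@fracRepressed),
    paste("effect_log2fc =", config@effectLog2FC),
    paste("dispersion =", config@dispersion),
    paste("baseline_log2_mean =", config@baselineLog2Mean),
    paste("baseline_log2_sd =", config@baselineLog2SD),
    paste("library_size_range =", paste(config@libSizeRange, collapse = ",")),
    paste("n_replicates =", config@nReplicates),
    paste("offtarget_fraction =", config@offtargetFraction),
    paste("gene_length_range =",
          paste(config@geneLengthRange, collapse = ",")),
    paste("seed =", config@seed))
  cond <- config@conditions
  for (i in seq_len(nrow(cond))) {
    act <- config@activation[cond$name[i], ]
    act <- act[act > 0]
    rs <- cond$reference_stat[i]
    lines <- c(lines, paste0(
      "condition = ", cond$name[i], "|", cond$role[i], "|",
      if (is.na(rs)) "" else rs, "|",
      if (length(act)) fmtPairs(act) else ""))
  }
  writeLines(lines, path)
  invisible(path)
}
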