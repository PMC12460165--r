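#' Construct a CytokineExperiment
#'
#' @param counts integer gene x sample matrix with row and column names.
#' @param sampleData data.frame with one row per sample (rownames or a
#'   \code{sample} column matching \code{colnames(counts)}) and columns
#'   \code{condition}, \code{role}, \code{reference_stat} (NA for non-reference
#'   conditions; empty strings are read as NA).
#' @param geneLengths optional named vector of gene lengths in bases.
#' @return A \linkS4class{CytokineExperiment}.
#' @examples
#' cts <- matrix(rpois(40, 20), nrow = 10,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' sd <- data.frame(sample = paste0("s", 1:4),
#'                  condition = rep(c("ctrl", "IFNa"), each = 2),
#'                  role = rep(c("control", "reference"), each = 2),
#'                  reference_stat = rep(c(NA, "STAT1"), each = 2))
#' ce <- CytokineExperiment(cts, sd)
#' @export
CytokineExperiment <- function(counts, sampleData, geneLengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if ("sample" %in% colnames(sampleData))
    rownames(sampleData) <- sampleData$sample
  missing <- setdiff(colnames(counts), rownames(sampleData))
  if (length(missing))
    stop("samples absent from sample sheet: ", paste(missing, collapse = ", "))
  extra <- setdiff(rownames(sampleData), colnames(counts))
  if (length(extra))
    stop("sample sheet lists samples absent from counts: ",
         paste(extra, collapse = ", "))
  sampleData <- sampleData[colnames(counts), , drop = FALSE]
  rs <- as.character(sampleData$reference_stat)
  rs[!is.na(rs) & rs == ""] <- NA_character_
  cd <- DataFrame(condition = as.character(sampleData$condition),
                  role = as.character(sampleData$role),
                  reference_stat = rs,
                  row.names = colnames(counts))
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(geneLengths)) {
    miss <- setdiff(rownames(counts), names(geneLengths))
    if (length(miss))
      stop("gene lengths missing for: ", paste(utils::head(miss, 5),
                                               collapse = ", "))
    rd$gene_length <- as.integer(geneLengths[rownames(counts)])
  }
  se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                             colData = cd, rowData = rd)
  new("CytokineExperiment", se)
}

#' @describeIn CytokineExperiment-accessors raw count matrix
#' @export
setMethod("counts", "CytokineExperiment",
          function(object, ...) assay(object, "counts"))

#' Accessors for CytokineExperiment
#'
#' \code{conditions} returns the per-sample condition vector;
#' \code{conditionRoles} a condition -> role map; \code{controlCondition} the
#' unique control condition; \code{referenceStats} a condition ->
#' reference-STAT map over reference conditions; \code{geneLengths} the
#' per-gene lengths in bases; \code{sampleSheet} the design as a data.frame.
#'
#' @param object a \linkS4class{CytokineExperiment}.
#' @param ... unused.
#' @name CytokineExperiment-accessors
NULL

#' @rdname CytokineExperiment-accessors
#' @export
conditions <- function(object) {
  stats::setNames(colData(object)$condition, colnames(object))
}

#' @rdname CytokineExperiment-accessors
#' @export
conditionRoles <- function(object) {
  cd <- colData(object)
  idx <- !duplicated(cd$condition)
  stats::setNames(cd$role[idx], cd$condition[idx])
}

#' @rdname CytokineExperiment-accessors
#' @export
controlCondition <- function(object) {
  cd <- colData(object)
  unique(cd$condition[cd$role == "control"])
}

#' @rdname CytokineExperiment-accessors
#' @export
referenceStats <- function(object) {
  cd <- colData(object)
  ref <- cd[cd$role == "reference", , drop = FALSE]
  idx <- !duplicated(ref$condition)
  stats::setNames(ref$reference_stat[idx], ref$condition[idx])
}

#' @rdname CytokineExperiment-accessors
#' @export
geneLengths <- function(object) {
  rd <- rowData(object)
  if (!"gene_length" %in% colnames(rd))
    stop("no gene lengths attached to this experiment")
  stats::setNames(as.integer(rd$gene_length), rownames(object))
}

#' @rdname CytokineExperiment-accessors
#' @export
sampleSheet <- function(object) {
  cd <- colData(object)
  data.frame(sample = colnames(object),
             condition = cd$condition,
             role = cd$role,
             reference_stat = cd$reference_stat,
             stringsAsFactors = FALSE)
}

setMethod("show", "CytokineExperiment", function(object) {
  cd <- colData(object)
  cat("CytokineExperiment:", nrow(object), "genes x", ncol(object),
      "samples\n")
  cat("  control condition:", controlCondition(object), "\n")
  tab <- table(cd$condition)
  cat("  conditions (", length(tab), "):",
      paste(utils::head(names(tab), 8), collapse = ", "),
      if (length(tab) > 8) "...", "\n")
})
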