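#' @import methods
#' @importFrom BiocGenerics counts
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

## STATs carrying a gene signature. STAT4 has no single- or paired-cytokine
## reference in the six-condition design and is deliberately absent.
.STATS <- c("STAT1", "STAT3", "STAT5", "STAT6")

.ROLES <- c("control", "reference", "query")

#' Cytokine-stimulation expression experiment
#'
#' A \linkS4class{SummarizedExperiment} holding a gene x sample integer count
#' matrix (assay \code{"counts"}), per-gene lengths in bases
#' (\code{rowData(x)$gene_length}), and per-sample design columns
#' \code{condition}, \code{role} (one of \code{control}, \code{reference},
#' \code{query}) and \code{reference_stat} (the STAT whose reference panel a
#' reference condition belongs to; \code{NA} otherwise).
#'
#' Exactly one condition must have role \code{control}: the unstimulated
#' baseline against which differential expression and score fold changes are
#' computed.
#'
#' @export
setClass("CytokineExperiment", contains = "SummarizedExperiment")

setValidity("CytokineExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(cts - round(cts)) > 1e-8))
      msg <- c(msg, "counts must be integers")
  }
  cd <- colData(object)
  need <- c("condition", "role", "reference_stat")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(c(msg, paste("missing colData columns:",
                        paste(miss, collapse = ", "))))
  if (!all(cd$role %in% .ROLES))
    msg <- c(msg, paste("role must be one of",
                        paste(.ROLES, collapse = ", ")))
  ctrl <- unique(cd$condition[cd$role == "control"])
  if (length(ctrl) != 1L)
    msg <- c(msg, "exactly one condition must have role 'control'")
  bycond <- split(as.character(cd$role), as.character(cd$condition))
  if (any(vapply(bycond, function(r) length(unique(r)), 1L) > 1L))
    msg <- c(msg, "each condition must have a single role")
  rs <- cd$reference_stat[cd$role == "reference"]
  if (any(is.na(rs)) || !all(rs %in% .STATS))
    msg <- c(msg, "reference conditions need reference_stat in STAT1/3/5/6")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic cytokine-stimulation experiment: gene counts
#' are drawn from a negative binomial with variance \eqn{\mu + \phi \mu^2}
#' around condition-specific means
#' \deqn{\mu_{gs} = b_g \, 2^{\sum_k s_{gk} \alpha_{ck} \beta \, 1[g \in P_k]}
#'   \, d_s}
#' where \eqn{b_g} is a log2-normal baseline, \eqn{P_k} the STAT-k program
#' with per-gene sign \eqn{s_{gk} \in \{+1,-1\}}, \eqn{\alpha_{ck} \in [0,1]}
#' the activation (attenuation) of STAT k in condition c, \eqn{\beta} the full
#' log2 effect size and \eqn{d_s} a uniform per-sample depth factor.
#'
#' @slot nGenes total number of genes.
#' @slot programSizes named vector, genes per STAT program.
#' @slot overlapFraction fraction of each program shared with its predecessor
#'   program (0 = disjoint).
#' @slot fracRepressed fraction of program genes repressed (sign -1).
#' @slot effectLog2FC log2 fold change magnitude at full activation.
#' @slot dispersion NB dispersion phi.
#' @slot baselineLog2Mean,baselineLog2SD log2-scale baseline distribution.
#' @slot libSizeRange uniform range of per-sample depth factors.
#' @slot nReplicates replicates per condition.
#' @slot conditions data.frame with columns name, role, reference_stat.
#' @slot activation condition x STAT matrix of activations in [0,1].
#' @slot offtargetFraction size of each paired reference cytokine's private
#'   off-target program, as a fraction of its STAT program size.
#' @slot geneLengthRange uniform integer range of gene lengths (bases).
#' @slot seed RNG seed.
#' @export
setClass("SimConfig", representation(
  nGenes = "integer",
  programSizes = "numeric",
  overlapFraction = "numeric",
  fracRepressed = "numeric",
  effectLog2FC = "numeric",
  dispersion = "numeric",
  baselineLog2Mean = "numeric",
  baselineLog2SD = "numeric",
  libSizeRange = "numeric",
  nReplicates = "integer",
  conditions = "data.frame",
  activation = "matrix",
  offtargetFraction = "numeric",
  geneLengthRange = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
  if (any(object@programSizes < 1))
    msg <- c(msg, "program sizes must be positive")
  if (sum(object@programSizes) > object@nGenes)
    msg <- c(msg, "sum of program sizes exceeds nGenes")
  if (object@overlapFraction < 0 || object@overlapFraction >= 1)
    msg <- c(msg, "overlapFraction must be in [0, 1)")
  if (object@fracRepressed < 0 || object@fracRepressed > 1)
    msg <- c(msg, "fracRepressed must be in [0, 1]")
  if (object@effectLog2FC <= 0) msg <- c(msg, "effectLog2FC must be positive")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be non-negative")
  if (object@nReplicates < 2L) msg <- c(msg, "nReplicates must be >= 2")
  if (any(object@libSizeRange <= 0) || length(object@libSizeRange) != 2L)
    msg <- c(msg, "libSizeRange must be two positive reals")
  if (length(object@geneLengthRange) != 2L || any(object@geneLengthRange < 1L))
    msg <- c(msg, "geneLengthRange must be two positive integers")
  cond <- object@conditions
  if (!all(c("name", "role", "reference_stat") %in% colnames(cond)))
    return(c(msg, "conditions needs columns name, role, reference_stat"))
  if (!all(cond$role %in% .ROLES)) msg <- c(msg, "bad condition role")
  if (sum(cond$role == "control") != 1L)
    msg <- c(msg, "exactly one control condition required")
  act <- object@activation
  if (!identical(rownames(act), cond$name))
    msg <- c(msg, "activation rows must match condition names")
  if (!all(colnames(act) %in% names(object@programSizes)))
    msg <- c(msg, "activation STATs must appear in programSizes")
  if (any(act < 0 | act > 1)) msg <- c(msg, "activations must lie in [0, 1]")
  ctrl <- cond$name[cond$role == "control"]
  if (length(ctrl) == 1L && any(act[ctrl, ] != 0))
    msg <- c(msg, "control condition must have all activations 0")
  refs <- cond[cond$role == "reference", , drop = FALSE]
  if (any(is.na(refs$reference_stat)))
    msg <- c(msg, "reference conditions need a reference_stat")
  if (any(!is.na(cond$reference_stat[cond$role == "query"])))
    msg <- c(msg, "query conditions must have reference_stat NA")
  if (length(msg)) msg else TRUE
})

#' Simulation ground truth
#'
#' Per-STAT program membership with signs, per-condition activation, the
#' baseline means, gene lengths, the per-condition private off-target gene
#' sets, and the per-sample depth factors actually drawn. Used by recovery
#' tests to compare inferred signatures and scores against the truth.
#'
#' @export
setClass("SimTruth", representation(
  programMembers = "list",       # STAT -> named numeric (+1/-1 per gene)
  conditionActivation = "matrix",
  baselineMeans = "numeric",
  geneLengths = "integer",
  offtargetMembers = "list",     # condition -> character gene ids
  depthFactors = "numeric"
))

setValidity("SimTruth", function(object) {
  bad <- vapply(object@programMembers,
                function(p) any(!p %in% c(-1, 1)), logical(1))
  if (any(bad)) "program signs must be +1 or -1" else TRUE
})

#' STAT gene signature
#'
#' The driven set (genes differentially regulated by the STAT's reference
#' cytokines versus control, with signs) and the cross-STAT-exclusive subset
#' over which scores are computed, together with the reference conditions
#' whose samples form the correlation panel.
#'
#' @export
setClass("SignatureSet", representation(
  stat = "character",
  driven = "numeric",            # named: gene -> +1/-1
  exclusive = "character",
  referenceConditions = "character"
))

setValidity("SignatureSet", function(object) {
  msg <- character()
  if (!object@stat %in% .STATS)
    msg <- c(msg, paste("stat must be one of", paste(.STATS, collapse = ", ")))
  if (!all(object@exclusive %in% names(object@driven)))
    msg <- c(msg, "exclusive genes must be a subset of driven genes")
  if (!length(object@referenceConditions))
    msg <- c(msg, "referenceConditions must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Per-sample and per-condition STAT scores
#'
#' \code{sampleScores} holds one row per sample x STAT (score, genes used,
#' reference panel size, reason code); \code{conditionMeans} the per-condition
#' arithmetic mean scores; \code{control} names the control condition.
#'
#' @export
setClass("ScoreTable", representation(
  sampleScores = "data.frame",
  conditionMeans = "data.frame",
  control = "character"
))
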