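#' Build per-STAT driven gene sets from per-cytokine DE results
#'
#' Single-cytokine STATs take the cytokine's signed DE set directly
#' (IFNa -> STAT1, IL-4 -> STAT6); STATs covered by two cytokines take the
#' gene-id intersection of the two sets (IL-10 and IL-21 -> STAT3, IL-2 and
#' IL-7 -> STAT5). In \code{signMode = "concordant"} (default) a gene whose
#' signs disagree between intersected cytokines is dropped with a message;
#' \code{"id-only"} keeps it with the first cytokine's sign.
#'
#' @param deResults named list, condition -> signed gene vector
#'   (names = genes, values +1/-1), one entry per reference condition.
#' @param conditionStat named character, condition -> STAT
#'   (e.g. from \code{\link{referenceStats}}).
#' @param signMode "concordant" or "id-only".
#' @return named list, STAT -> signed gene vector.
#' @examples
#' buildDrivenSets(
#'   list(IL10 = c(a = 1, b = 1, c = -1), IL21 = c(b = 1, c = -1, d = 1)),
#'   c(IL10 = "STAT3", IL21 = "STAT3"))
#' @export
buildDrivenSets <- function(deResults, conditionStat,
                            signMode = c("concordant", "id-only")) {
  signMode <- match.arg(signMode)
  missing <- setdiff(names(conditionStat), names(deResults))
  if (length(missing))
    stop("missing DE results for reference condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  driven <- list()
  for (stat in unique(conditionStat)) {
    conds <- names(conditionStat)[conditionStat == stat]
    sets <- deResults[conds]
    ids <- Reduce(intersect, lapply(sets, names))
    set <- sets[[1]][ids]
    if (length(sets) > 1L && length(ids)) {
      signs <- vapply(sets, function(s) s[ids], numeric(length(ids)))
      if (length(ids) == 1L) signs <- matrix(signs, nrow = 1)
      concordant <- apply(signs, 1, function(r) length(unique(r)) == 1L)
      nDisc <- sum(!concordant)
      if (nDisc && signMode == "concordant") {
        message(stat, ": dropped ", nDisc,
                " sign-discordant gene(s) from the intersection")
        set <- set[concordant]
      }
    }
    driven[[stat]] <- set
  }
  driven
}

#' Cross-STAT-exclusive gene set
#'
#' Genes driven by \code{stat} but not driven by any other STAT: the gene ids
#' of \code{driven[[stat]]} minus the union of all other STATs' driven ids.
#'
#' @param stat STAT id present in \code{driven}.
#' @param driven named list, STAT -> signed gene vector.
#' @return character vector of exclusive gene ids.
#' @export
exclusiveSet <- function(stat, driven) {
  if (!stat %in% names(driven))
    stop("unknown STAT '", stat, "'", call. = FALSE)
  others <- unlist(lapply(driven[setdiff(names(driven), stat)], names))
  excl <- setdiff(names(driven[[stat]]), others)
  if (!length(excl))
    warning("exclusive set for ", stat, " is empty", call. = FALSE)
  excl
}

#' Assemble SignatureSet objects
#'
#' @param driven named list, STAT -> signed gene vector (from
#'   \code{\link{buildDrivenSets}}).
#' @param conditionStat named character, condition -> STAT; each signature's
#'   reference conditions are the conditions mapped to its STAT.
#' @return named list of \linkS4class{SignatureSet}, one per STAT in
#'   \code{driven}.
#' @export
buildSignatureSets <- function(driven, conditionStat) {
  out <- list()
  for (stat in names(driven)) {
    refs <- names(conditionStat)[conditionStat == stat]
    out[[stat]] <- new("SignatureSet", stat = stat,
                       driven = driven[[stat]],
                       exclusive = suppressWarnings(
                         exclusiveSet(stat, driven)),
                       referenceConditions = refs)
  }
  out
}

#' Validate signature sets for scoring eligibility
#'
#' Flags STATs whose exclusive set is smaller than \code{minSize}; scoring
#' reports missing values for flagged STATs.
#'
#' @param sets named list of \linkS4class{SignatureSet}.
#' @param minSize minimum exclusive-set size (default 10).
#' @return data.frame: stat, n_driven, n_exclusive, flagged.
#' @export
validateSignatures <- function(sets, minSize = 10) {
  data.frame(
    stat = vapply(sets, function(s) s@stat, ""),
    n_driven = vapply(sets, function(s) length(s@driven), 1L),
    n_exclusive = vapply(sets, function(s) length(s@exclusive), 1L),
    flagged = vapply(sets, function(s) length(s@exclusive) < minSize,
                     logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn buildSignatureSets accessors
#' @param object a \linkS4class{SignatureSet}.
#' @export
drivenGenes <- function(object) object@driven

#' @rdname buildSignatureSets
#' @export
exclusiveGenes <- function(object) object@exclusive

#' @rdname buildSignatureSets
#' @export
referenceConditions <- function(object) object@referenceConditions

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet for", object@stat, "\n",
      " driven:", length(object@driven), "genes (",
      sum(object@driven > 0), "induced /", sum(object@driven < 0),
      "repressed )\n",
      " exclusive:", length(object@exclusive), "genes\n",
      " reference conditions:",
      paste(object@referenceConditions, collapse = ", "), "\n")
})
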