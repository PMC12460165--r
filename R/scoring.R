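#' Transcripts per million
#'
#' \code{rate = count / (length / 1000)} per gene, each column rescaled to
#' sum to 1e6. Invariant to per-sample count rescaling.
#'
#' @param counts non-negative gene x sample matrix.
#' @param lengths named vector of positive gene lengths in bases covering all
#'   genes.
#' @return gene x sample TPM matrix; every column sums to 1e6.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("missing gene length(s): ", paste(utils::head(miss, 5),
                                           collapse = ", "), call. = FALSE)
  len <- lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  rate <- counts / (len / 1000)
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("degenerate input: all-zero sample column(s): ",
         paste(colnames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  sweep(rate, 2, tot, "/") * 1e6
}

#' TPM assay for a CytokineExperiment
#'
#' @param experiment a \linkS4class{CytokineExperiment} with gene lengths.
#' @return TPM matrix (see \code{\link{tpm}}).
#' @export
tpmMatrix <- function(experiment) {
  tpm(counts(experiment), geneLengths(experiment))
}

## Mean Pearson correlation of a query profile to reference profiles over the
## exclusive gene set; degenerate (zero-variance) pairs are dropped.
.statScoreOne <- function(query, refMat) {
  if (stats::sd(query) == 0)
    return(list(score = NA_real_, nRef = 0L, reason = "degenerate_query"))
  ok <- apply(refMat, 2, stats::sd) > 0
  if (!any(ok))
    return(list(score = NA_real_, nRef = 0L, reason = "no_valid_reference"))
  r <- as.numeric(stats::cor(query, refMat[, ok, drop = FALSE]))
  list(score = mean(r), nRef = sum(ok), reason = "ok")
}

#' STAT score of one query sample
#'
#' Restricts query and reference columns to the signature's exclusive gene
#' set, computes the Pearson correlation to each reference sample (the query
#' is excluded from its own reference panel), drops zero-variance pairs, and
#' averages the remaining coefficients. Missing (with a reason code) when the
#' exclusive set is below \code{minSize} or no valid reference pair remains.
#'
#' @param tpmMat TPM gene x sample matrix.
#' @param signature a \linkS4class{SignatureSet}.
#' @param querySample sample (column) name to score.
#' @param referenceSamples names of the signature's reference-panel columns.
#' @param minSize minimum exclusive-set size for a defined score.
#' @return list: score, n_genes_used, n_reference_samples, reason.
#' @export
statScore <- function(tpmMat, signature, querySample, referenceSamples,
                      minSize = 10) {
  excl <- intersect(signature@exclusive, rownames(tpmMat))
  refs <- setdiff(referenceSamples, querySample)
  if (length(excl) < minSize)
    return(list(score = NA_real_, n_genes_used = length(excl),
                n_reference_samples = length(refs),
                reason = "exclusive_set_too_small"))
  if (!length(refs))
    return(list(score = NA_real_, n_genes_used = length(excl),
                n_reference_samples = 0L, reason = "empty_reference_panel"))
  res <- .statScoreOne(tpmMat[excl, querySample],
                       tpmMat[excl, refs, drop = FALSE])
  list(score = res$score, n_genes_used = length(excl),
       n_reference_samples = res$nRef, reason = res$reason)
}

#' Score every sample for every STAT
#'
#' @param tpmMat TPM gene x sample matrix.
#' @param signatures named list of \linkS4class{SignatureSet} (typically all
#'   of STAT1/3/5/6; absent STATs yield missing columns).
#' @param sheet sample sheet data.frame (sample, condition, role,
#'   reference_stat), e.g. \code{\link{sampleSheet}}.
#' @param minSize minimum exclusive-set size.
#' @param logTPM correlate log2(TPM + 1) profiles (default) instead of raw
#'   TPM. On raw TPM the product-moment correlation is dominated by the few
#'   highest-abundance genes of the exclusive set, which compresses and
#'   destabilizes condition differences; the log transform weights genes
#'   more evenly. Set \code{FALSE} to correlate raw TPM.
#' @return a \linkS4class{ScoreTable}.
#' @export
scoreAll <- function(tpmMat, signatures, sheet, minSize = 10,
                     logTPM = TRUE) {
  if (logTPM) tpmMat <- log2(tpmMat + 1)
  ctrl <- unique(sheet$condition[sheet$role == "control"])
  rows <- list()
  for (stat in names(signatures)) {
    sig <- signatures[[stat]]
    refSamples <- sheet$sample[sheet$condition %in% sig@referenceConditions]
    for (s in sheet$sample) {
      r <- statScore(tpmMat, sig, s, refSamples, minSize = minSize)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, condition = sheet$condition[sheet$sample == s],
        stat = stat, score = r$score, n_genes_used = r$n_genes_used,
        n_reference_samples = r$n_reference_samples, reason = r$reason,
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  agg <- stats::aggregate(score ~ condition + stat, data = samples,
                          FUN = mean, na.action = stats::na.pass)
  names(agg)[names(agg) == "score"] <- "mean_score"
  new("ScoreTable", sampleScores = samples, conditionMeans = agg,
      control = ctrl)
}

#' @describeIn scoreAll per-sample score data.frame
#' @param table a \linkS4class{ScoreTable}.
#' @export
sampleScores <- function(table) table@sampleScores

#' @rdname scoreAll
#' @export
conditionMeans <- function(table) table@conditionMeans

#' @rdname scoreAll
#' @export
scoreMatrix <- function(table) {
  df <- table@sampleScores
  stats_ <- unique(df$stat)
  samples <- unique(df$sample)
  m <- matrix(NA_real_, length(samples), length(stats_),
              dimnames = list(samples, stats_))
  m[cbind(df$sample, df$stat)] <- df$score
  m
}

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable:", length(unique(object@sampleScores$sample)),
      "samples x", length(unique(object@sampleScores$stat)), "STATs,",
      "control =", object@control, "\n")
  print(utils::head(object@conditionMeans, 8))
})

#' Fold change of condition-mean STAT scores versus control
#'
#' \code{fold_change = mean_score / control_mean} when the control mean
#' exceeds \code{epsilon} (a correlation ratio is unstable near zero);
#' otherwise the fold change is missing and only the companion
#' \code{difference} column (always emitted) carries the contrast.
#'
#' @param table a \linkS4class{ScoreTable}.
#' @param control control condition; default the table's.
#' @param epsilon guard on the control mean (default 0.05).
#' @return data.frame: condition, stat, mean_score, fold_change, difference.
#' @export
scoreFoldChange <- function(table, control = table@control, epsilon = 0.05) {
  cm <- table@conditionMeans
  ctrl <- cm[cm$condition == control, c("stat", "mean_score")]
  ctrlMean <- stats::setNames(ctrl$mean_score, ctrl$stat)
  base <- ctrlMean[cm$stat]
  cm$fold_change <- ifelse(!is.na(base) & base > epsilon,
                           cm$mean_score / base, NA_real_)
  cm$difference <- cm$mean_score - base
  cm
}

#' PCA of the sample x STAT score matrix
#'
#' Column-centers the complete-case score matrix and decomposes it by
#' singular values: coordinates are the projections \code{U d}; variance
#' fractions \code{d^2 / sum(d^2)} sum to 1. Each component's sign is fixed
#' so its loading vector's largest-magnitude entry is positive. Samples with
#' any missing score are dropped with a message.
#'
#' @param scores sample x STAT numeric matrix (see \code{\link{scoreMatrix}})
#'   or a \linkS4class{ScoreTable}.
#' @return list: \code{coordinates} (samples x PCs), \code{varianceExplained}
#'   (fractions), \code{loadings} (STATs x PCs).
#' @export
pcaScores <- function(scores) {
  if (is(scores, "ScoreTable")) scores <- scoreMatrix(scores)
  complete <- stats::complete.cases(scores)
  if (any(!complete))
    message("dropping ", sum(!complete), " sample(s) with missing scores")
  x <- scores[complete, , drop = FALSE]
  if (nrow(x) < 2L)
    stop("degenerate input: fewer than 2 complete samples", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  if (all(abs(xc) < 1e-12))
    stop("degenerate input: zero total variance", call. = FALSE)
  sv <- svd(xc)
  flip <- apply(sv$v, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  u <- sweep(sv$u, 2, flip, "*")
  v <- sweep(sv$v, 2, flip, "*")
  coords <- u %*% diag(sv$d, length(sv$d))
  dimnames(coords) <- list(rownames(x), paste0("PC", seq_along(sv$d)))
  dimnames(v) <- list(colnames(x), colnames(coords))
  list(coordinates = coords,
       varianceExplained = sv$d^2 / sum(sv$d^2),
       loadings = v)
}
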