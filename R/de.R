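#' Median-of-ratios size factors
#'
#' For each sample, the median over genes with positive counts in every
#' sample of \code{count / geometric-mean(gene)}. If no gene is positive in
#' all samples, falls back to total-count scaling normalized to geometric
#' mean 1.
#'
#' @param counts non-negative gene x sample matrix.
#' @return named positive numeric vector, one factor per sample.
#' @examples
#' computeSizeFactors(cbind(s1 = c(2, 8), s2 = c(4, 16)))
#' @export
computeSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (all(counts == 0))
    stop("degenerate input: all-zero count matrix", call. = FALSE)
  allPos <- rowSums(counts > 0) == ncol(counts)
  if (any(allPos)) {
    logGeo <- rowMeans(log(counts[allPos, , drop = FALSE]))
    sf <- apply(log(counts[allPos, , drop = FALSE]) - logGeo, 2,
                function(z) exp(stats::median(z)))
  } else {
    cs <- colSums(counts)
    if (any(cs == 0))
      stop("degenerate input: sample with zero total counts", call. = FALSE)
    sf <- cs / exp(mean(log(cs)))
  }
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments NB dispersion per gene
#'
#' Per gene, the pooled within-group variance of normalized counts minus the
#' pooled mean, over the pooled mean squared, floored at \code{floor}:
#' \eqn{\hat\phi = \max(\mathrm{floor}, (s^2 - \bar\mu)/\bar\mu^2)}.
#'
#' @param normCounts normalized gene x sample matrix.
#' @param group1,group2 sample name/index vectors; each of length >= 2.
#' @param floor minimum dispersion returned.
#' @return named non-negative numeric vector per gene.
#' @export
estimateDispersion <- function(normCounts, group1, group2, floor = 1e-4) {
  if (length(group1) < 2L || length(group2) < 2L)
    stop("each group needs at least 2 samples", call. = FALSE)
  x1 <- normCounts[, group1, drop = FALSE]
  x2 <- normCounts[, group2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  pooledVar <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  pooledMean <- (rowSums(x1) + rowSums(x2)) / (n1 + n2)
  phi <- ifelse(pooledMean > 0,
                (pooledVar - pooledMean) / pooledMean^2, 0)
  stats::setNames(pmax(floor, phi), rownames(normCounts))
}

#' Per-gene NB Wald test between two groups
#'
#' Log2 fold change of pseudocounted normalized group means,
#' \code{log2((m2 + c) / (m1 + c))}; its standard error from the
#' delta-method NB variance of a log mean,
#' \eqn{\mathrm{Var}(\ln\hat\mu) \approx (1/n)(1/\hat\mu + \phi)} summed over
#' the two groups and rescaled to log2; Wald statistic \code{log2fc / se};
#' two-sided normal p-value. Genes at zero in both groups return
#' \code{log2fc = 0, p = 1}.
#'
#' @param normCounts normalized gene x sample matrix.
#' @param group1 control-group samples; \code{group2} treated.
#' @param group2 treated-group samples.
#' @param dispersion per-gene dispersion (recycled if scalar).
#' @param pseudocount stabilizing constant c on normalized means (0 allowed
#'   for exact fold changes on positive fixtures).
#' @return data.frame: gene, mean_control, mean_treated, log2fc, se, wald, p.
#' @export
nbWaldTest <- function(normCounts, group1, group2, dispersion,
                       pseudocount = 0.5) {
  if (any(dispersion < 0)) stop("dispersion must be >= 0", call. = FALSE)
  .assertScalarNum(pseudocount, "pseudocount", min = 0)
  m1 <- rowMeans(normCounts[, group1, drop = FALSE])
  m2 <- rowMeans(normCounts[, group2, drop = FALSE])
  n1 <- length(group1); n2 <- length(group2)
  phi <- rep_len(dispersion, length(m1))
  c0 <- pseudocount
  log2fc <- log2((m2 + c0) / (m1 + c0))
  ## variance of the log mean needs a positive mean; the pseudocount (or the
  ## floor 0.5 when c = 0) keeps zero-mean genes finite
  s1 <- pmax(m1 + c0, 0.5); s2 <- pmax(m2 + c0, 0.5)
  varLn <- (1 / n1) * (1 / s1 + phi) + (1 / n2) * (1 / s2 + phi)
  se <- sqrt(varLn) / log(2)
  wald <- log2fc / se
  p <- 2 * stats::pnorm(-abs(wald))
  zero <- m1 == 0 & m2 == 0
  log2fc[zero] <- 0; wald[zero] <- 0; p[zero] <- 1
  p[wald == 0] <- 1
  data.frame(gene = rownames(normCounts), mean_control = m1,
             mean_treated = m2, log2fc = log2fc, se = se, wald = wald,
             p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving BH-adjusted p-values, each capped at 1.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values aligned with the input.
#' @export
bhAdjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) ||
      any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Differential expression of a treated condition versus control
#'
#' Runs the full chain on the two conditions' samples: median-of-ratios size
#' factors, method-of-moments dispersion, NB Wald test, and BH adjustment.
#' Genes with \code{padj < alpha} are flagged significant in either
#' direction ("induced or repressed"), with \code{sign = +1} for
#' \code{log2fc > 0} and \code{-1} otherwise.
#'
#' @param experiment a \linkS4class{CytokineExperiment}.
#' @param treated treated condition name (must differ from the control).
#' @param alpha FDR threshold (default 0.05).
#' @param pseudocount see \code{\link{nbWaldTest}}.
#' @param dispersionFloor see \code{\link{estimateDispersion}}.
#' @param minTotalCount optional minimum total count across the two groups;
#'   genes below it are dropped before testing (default 0 = off).
#' @return DE table data.frame: gene, mean_control, mean_treated, log2fc,
#'   se, wald, p, padj, significant, sign.
#' @export
deTest <- function(experiment, treated, alpha = 0.05, pseudocount = 0.5,
                   dispersionFloor = 1e-4, minTotalCount = 0) {
  .assertScalarNum(alpha, "alpha", min = 0, max = 1)
  cond <- conditions(experiment)
  ctrl <- controlCondition(experiment)
  if (!treated %in% cond)
    stop("unknown condition '", treated, "'", call. = FALSE)
  if (identical(treated, ctrl))
    stop("treated condition must differ from the control", call. = FALSE)
  g1 <- names(cond)[cond == ctrl]
  g2 <- names(cond)[cond == treated]
  cts <- counts(experiment)[, c(g1, g2), drop = FALSE]
  if (minTotalCount > 0)
    cts <- cts[rowSums(cts) >= minTotalCount, , drop = FALSE]
  sf <- computeSizeFactors(cts)
  norm <- sweep(cts, 2, sf, "/")
  phi <- estimateDispersion(norm, g1, g2, floor = dispersionFloor)
  res <- nbWaldTest(norm, g1, g2, phi, pseudocount = pseudocount)
  res$padj <- bhAdjust(res$p)
  res$significant <- res$padj < alpha
  res$sign <- ifelse(res$log2fc > 0, 1L, -1L)
  res
}

#' Significant signed gene set for a contrast
#'
#' @inheritParams deTest
#' @return named numeric vector: significant genes -> +1/-1.
#' @export
deGenes <- function(experiment, treated, alpha = 0.05, ...) {
  res <- deTest(experiment, treated, alpha = alpha, ...)
  sig <- res[res$significant, , drop = FALSE]
  stats::setNames(as.numeric(sig$sign), sig$gene)
}
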