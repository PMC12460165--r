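# Small simulated experiments and independent oracles shared across tests.

smallConfig <- function(seed = 1, nGenes = 400,
                        programSizes = c(STAT1 = 40, STAT3 = 40,
                                         STAT5 = 40, STAT6 = 40), ...) {
  simConfig(nGenes = nGenes, programSizes = programSizes, seed = seed, ...)
}

# toy experiment: explicit counts for two conditions (control + one treated)
toyExperiment <- function(ctrlCounts, treatCounts,
                          treated = "IFNa", stat = "STAT1") {
  cts <- cbind(ctrlCounts, treatCounts)
  n1 <- ncol(ctrlCounts); n2 <- ncol(treatCounts)
  colnames(cts) <- c(paste0("c", seq_len(n1)), paste0("t", seq_len(n2)))
  if (is.null(rownames(cts)))
    rownames(cts) <- paste0("g", seq_len(nrow(cts)))
  sheet <- data.frame(
    sample = colnames(cts),
    condition = rep(c("ctrl", treated), c(n1, n2)),
    role = rep(c("control", "reference"), c(n1, n2)),
    reference_stat = rep(c(NA, stat), c(n1, n2)))
  CytokineExperiment(cts, sheet)
}

# independent O(m^2) BH step-up oracle: for each i, the minimum over all
# j with p_j >= p_i of m * p_j / rank(p_j), capped at 1
bhOracle <- function(p) {
  m <- length(p)
  r <- vapply(p, function(x) sum(p <= x), 1L)
  vapply(seq_len(m), function(i) {
    cand <- p >= p[i]
    min(1, min(m * p[cand] / r[cand]))
  }, 1)
}

# two-pass Pearson correlation oracle
pearsonOracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# covariance-eigendecomposition PCA oracle
pcaOracle <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  eg <- eigen(stats::cov(xc), symmetric = TRUE)
  list(coordinates = xc %*% eg$vectors,
       varianceExplained = eg$values / sum(eg$values))
}

chimeraGrid <- sprintf("chimera_a%03d", c(0, 25, 50, 75, 100))
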