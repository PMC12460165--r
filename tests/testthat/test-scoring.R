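test_that("TPM normalizes by length and scales columns to 1e6", {
  one <- matrix(7, 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(tpm(one, c(g1 = 500))[1, ]), c(1e6, 1e6))

  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  t1 <- tpm(m, c(g1 = 1000, g2 = 2000))
  expect_equal(unname(t1[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-6)

  set.seed(61)
  big <- matrix(rpois(500, 50), 50, 10,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  lens <- stats::setNames(sample(500:10000, 50), paste0("g", 1:50))
  tb <- tpm(big, lens)
  expect_true(all(abs(colSums(tb) - 1e6) <= 1e-9 * 1e6))
  # per-sample count scaling leaves TPM unchanged
  big2 <- big; big2[, 4] <- big2[, 4] * 2L
  expect_equal(tpm(big2, lens)[, 4], tb[, 4])

  expect_error(tpm(big, lens[-1]), "missing gene length")
  badLens <- lens; badLens[2] <- 0
  expect_error(tpm(big, badLens), "positive")
  zeroCol <- big; zeroCol[, 2] <- 0
  expect_error(tpm(zeroCol, lens), "all-zero")
})

test_that("stat scores are averaged Pearson correlations with
           self-exclusion", {
  genes <- paste0("g", 1:12)
  sig <- new("SignatureSet", stat = "STAT3",
             driven = stats::setNames(rep(1, 12), genes),
             exclusive = genes, referenceConditions = "IL10")
  base <- 1:12
  mat <- cbind(q = base, r1 = base, r2 = -2 * base + 30)
  rownames(mat) <- genes

  r <- statScore(mat, sig, "q", "r1")
  expect_equal(r$score, 1)          # identical to the single reference
  r2 <- statScore(mat, sig, "q", c("r1", "r2"))
  expect_equal(r2$score, 0)         # mean of {1, -1}
  expect_equal(r2$n_reference_samples, 2L)

  # independent two-pass oracle on noisy vectors
  set.seed(62)
  noisy <- cbind(q = rnorm(12), r1 = rnorm(12))
  rownames(noisy) <- genes
  expect_equal(statScore(noisy, sig, "q", "r1")$score,
               pearsonOracle(noisy[, "q"], noisy[, "r1"]),
               tolerance = 1e-12)

  # floor policy: small exclusive set reports missing with the size
  small <- new("SignatureSet", stat = "STAT3",
               driven = stats::setNames(rep(1, 5), genes[1:5]),
               exclusive = genes[1:5], referenceConditions = "IL10")
  rs <- statScore(mat, small, "q", c("r1", "r2"), minSize = 10)
  expect_true(is.na(rs$score))
  expect_identical(rs$n_genes_used, 5L)
  expect_identical(rs$reason, "exclusive_set_too_small")

  # self-exclusion empties a one-sample panel
  rself <- statScore(mat, sig, "r1", "r1")
  expect_true(is.na(rself$score))
  expect_identical(rself$reason, "empty_reference_panel")

  # degenerate (zero-variance) references are dropped
  flat <- cbind(q = base, r1 = rep(5, 12), r2 = base + 1)
  rownames(flat) <- genes
  rdeg <- statScore(flat, sig, "q", c("r1", "r2"))
  expect_equal(rdeg$n_reference_samples, 1L)
  expect_equal(rdeg$score, 1)
})

test_that("scoreAll recovers condition structure on simulations", {
  sim <- simulateExperiment(simConfig(seed = 71))
  ex <- sim$experiment
  refStat <- referenceStats(ex)
  deSets <- lapply(names(refStat), function(cn) deGenes(ex, cn))
  names(deSets) <- names(refStat)
  driven <- suppressMessages(buildDrivenSets(deSets, refStat))
  sigs <- buildSignatureSets(driven, refStat)
  sc <- scoreAll(tpmMatrix(ex), sigs, sampleSheet(ex))
  ss <- sampleScores(sc)
  expect_true(all(abs(ss$score[!is.na(ss$score)]) <= 1))

  cm <- conditionMeans(sc)
  # each reference condition's arg-max STAT is its own
  for (cn in names(refStat)) {
    sub <- cm[cm$condition == cn, ]
    expect_identical(sub$stat[which.max(sub$mean_score)],
                     unname(refStat[[cn]]))
  }
  # a fully-activated STAT3 chimera scores STAT3 above the other STATs
  chim <- cm[cm$condition == "chimera_a100", ]
  expect_identical(chim$stat[which.max(chim$mean_score)], "STAT3")

  # reference samples scored on their own panel use size - 1 references
  own <- ss[ss$condition == "IL10" & ss$stat == "STAT3", ]
  expect_true(all(own$n_reference_samples == 5L))  # 6 panel samples - self
  expect_true(all(!is.na(own$score)))
})

test_that("null simulation keeps all condition scores near the control", {
  # references keep their programs (signatures must exist); the single
  # null chimera condition is distributionally identical to control
  dflt <- defaultConditions(chimeraAlphas = 0)
  cfg <- simConfig(conditions = dflt$conditions,
                   activation = dflt$activation, seed = 72)
  sim <- simulateExperiment(cfg)
  ex <- sim$experiment
  refStat <- referenceStats(ex)
  deSets <- lapply(names(refStat), function(cn) deGenes(ex, cn))
  names(deSets) <- names(refStat)
  sigs <- buildSignatureSets(
    suppressMessages(buildDrivenSets(deSets, refStat)), refStat)
  cm <- conditionMeans(scoreAll(tpmMatrix(ex), sigs, sampleSheet(ex)))
  for (st in unique(cm$stat)) {
    ctrl <- cm$mean_score[cm$condition == "noICD" & cm$stat == st]
    nullc <- cm$mean_score[cm$condition == "chimera_a000" & cm$stat == st]
    expect_lte(abs(nullc - ctrl), 0.1)
  }
})

test_that("score fold changes are guarded ratios with a difference
           companion", {
  mk <- function(means) new("ScoreTable",
    sampleScores = data.frame(),
    conditionMeans = data.frame(condition = rep(c("ctrl", "treat"), 2),
                                stat = rep(c("STAT1", "STAT3"), each = 2),
                                mean_score = means),
    control = "ctrl")
  fc <- scoreFoldChange(mk(c(0.4, 0.8, 0.5, 0.5)))
  expect_equal(fc$fold_change[fc$condition == "treat" &
                                fc$stat == "STAT1"], 2)
  expect_equal(fc$fold_change[fc$condition == "treat" &
                                fc$stat == "STAT3"], 1)
  expect_equal(fc$fold_change[fc$condition == "ctrl"], c(1, 1))

  low <- scoreFoldChange(mk(c(0.01, 0.8, 0.4, 0.4)))
  expect_true(is.na(low$fold_change[low$condition == "treat" &
                                      low$stat == "STAT1"]))
  expect_equal(low$difference[low$condition == "treat" &
                                low$stat == "STAT1"], 0.79)
})

test_that("PCA matches the covariance-eigendecomposition oracle", {
  set.seed(63)
  for (i in 1:5) {
    x <- matrix(rnorm(48), 12, 4,
                dimnames = list(paste0("s", 1:12),
                                c("STAT1", "STAT3", "STAT5", "STAT6")))
    got <- pcaScores(x)
    want <- pcaOracle(x)
    expect_equal(abs(got$coordinates), abs(want$coordinates),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(got$varianceExplained, want$varianceExplained,
                 tolerance = 1e-8)
    expect_equal(sum(got$varianceExplained), 1)
    # sign convention: dominant loading entry positive
    for (k in 1:4)
      expect_gte(got$loadings[which.max(abs(got$loadings[, k])), k], 0)
  }

  # rank-1: variation along a single STAT column
  r1 <- matrix(0, 6, 4, dimnames = list(paste0("s", 1:6),
                                        c("STAT1", "STAT3", "STAT5",
                                          "STAT6")))
  r1[, 2] <- seq(0.1, 0.6, 0.1)
  expect_equal(pcaScores(r1)$varianceExplained[1], 1)

  # permuting samples permutes coordinates identically
  x <- matrix(rnorm(48), 12, 4,
              dimnames = list(paste0("s", 1:12), c("a", "b", "c", "d")))
  perm <- sample(12)
  expect_equal(pcaScores(x[perm, ])$coordinates,
               pcaScores(x)$coordinates[perm, ], tolerance = 1e-10)

  expect_error(pcaScores(matrix(1, 5, 4)), "zero total variance")
  expect_error(pcaScores(matrix(rnorm(4), 1, 4)), "fewer than 2")
  withNA <- x; withNA[1, 1] <- NA
  expect_message(pcaScores(withNA), "dropping 1")
})

test_that("attenuation grid scores increase monotonically in alpha", {
  sim <- simulateExperiment(simConfig(seed = 73))
  ex <- sim$experiment
  refStat <- referenceStats(ex)
  deSets <- lapply(names(refStat), function(cn) deGenes(ex, cn))
  names(deSets) <- names(refStat)
  sigs <- buildSignatureSets(
    suppressMessages(buildDrivenSets(deSets, refStat)), refStat)
  cm <- conditionMeans(scoreAll(tpmMatrix(ex), sigs, sampleSheet(ex)))
  s3 <- cm[cm$stat == "STAT3" & cm$condition %in% chimeraGrid, ]
  v <- s3$mean_score[match(chimeraGrid, s3$condition)]
  expect_true(all(diff(v) > 0))
  expect_equal(cor(v, seq_along(v), method = "spearman"), 1)
})
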