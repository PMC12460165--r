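test_that("median-of-ratios size factors match hand computations", {
  expect_equal(unname(computeSizeFactors(cbind(s1 = c(5, 9), s2 = c(5, 9)))),
               c(1, 1))
  expect_equal(unname(computeSizeFactors(cbind(c1 = c(2, 8), c2 = c(4, 16)))),
               c(1 / sqrt(2), sqrt(2)))
  # every gene has a zero somewhere -> documented total-count fallback
  m <- cbind(a = c(0, 10, 4), b = c(6, 0, 8), c = c(3, 5, 0))
  sf <- computeSizeFactors(m)
  cs <- colSums(m)
  expect_equal(unname(sf), unname(cs / exp(mean(log(cs)))))
  expect_equal(exp(mean(log(sf))), 1)
  expect_error(computeSizeFactors(matrix(0, 3, 2)), "all-zero")
})

test_that("size factors undo integer rescaling of one sample", {
  set.seed(21)
  m <- matrix(rnbinom(600, mu = 100, size = 10) + 1L, nrow = 100,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  m2 <- m; m2[, 3] <- m2[, 3] * 5L
  norm1 <- sweep(m, 2, computeSizeFactors(m), "/")
  norm2 <- sweep(m2, 2, computeSizeFactors(m2), "/")
  expect_equal(unname(norm1[, 3] / norm2[, 3]),
               rep(norm1[1, 3] / norm2[1, 3], 100))

  # deGenes calls are stable under the same rescaling (all-positive matrix)
  sim <- simulateExperiment(smallConfig(seed = 26,
                                        baselineLog2Mean = 7,
                                        baselineLog2SD = 1))
  ex1 <- sim$experiment
  cts2 <- counts(ex1); cts2[, 2] <- cts2[, 2] * 3L
  ex2 <- CytokineExperiment(cts2, sampleSheet(ex1))
  s1 <- deGenes(ex1, "IL4"); s2 <- deGenes(ex2, "IL4")
  jac <- length(intersect(names(s1), names(s2))) /
    length(union(names(s1), names(s2)))
  expect_gt(jac, 0.95)
})

test_that("method-of-moments dispersion is consistent and guarded", {
  m <- matrix(7, 10, 6, dimnames = list(paste0("g", 1:10),
                                        paste0("s", 1:6)))
  phi <- estimateDispersion(m, paste0("s", 1:3), paste0("s", 4:6))
  expect_true(all(phi == 1e-4))  # zero variance -> floor

  set.seed(22)
  big <- matrix(rnbinom(2000 * 100, mu = 100, size = 5), nrow = 2000,
                dimnames = list(paste0("g", 1:2000), paste0("s", 1:100)))
  ph <- estimateDispersion(big, paste0("s", 1:50), paste0("s", 51:100))
  expect_gt(median(ph), 0.15)
  expect_lt(median(ph), 0.25)

  z <- rbind(g1 = c(0, 0, 0, 5, 7, 6))
  colnames(z) <- paste0("s", 1:6)
  phz <- estimateDispersion(z, paste0("s", 1:3), paste0("s", 4:6))
  expect_true(is.finite(phz))
  expect_error(estimateDispersion(m, "s1", paste0("s", 2:6)), "2 samples")
})

test_that("NB Wald test: null identity, exact fold change, moments", {
  m <- matrix(rep(c(4, 6, 5, 4, 6, 5), each = 3), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  res <- nbWaldTest(m, paste0("s", 1:3), paste0("s", 4:6), 0.1)
  expect_equal(res$log2fc, rep(0, 3))
  expect_equal(res$wald, rep(0, 3))
  expect_equal(res$p, rep(1, 3))

  m2 <- rbind(g1 = c(10, 12, 8, 40, 44, 36))
  colnames(m2) <- paste0("s", 1:6)
  res2 <- nbWaldTest(m2, paste0("s", 1:3), paste0("s", 4:6), 0.1,
                     pseudocount = 0)
  expect_identical(res2$log2fc, 2)  # log2(40 / 10), exact with c = 0

  zero <- rbind(g1 = rep(0, 6))
  colnames(zero) <- paste0("s", 1:6)
  res3 <- nbWaldTest(zero, paste0("s", 1:3), paste0("s", 4:6), 0.1)
  expect_equal(res3$log2fc, 0)
  expect_equal(res3$p, 1)
})

test_that("Wald p-values are calibrated and uniform under the null", {
  set.seed(23)
  n <- 20; G <- 2000
  mu <- 2^rnorm(G, 6, 2)
  cts <- matrix(rnbinom(G * 2 * n, mu = rep(mu, 2 * n), size = 10),
                nrow = G, dimnames = list(paste0("g", 1:G),
                                          paste0("s", 1:(2 * n))))
  g1 <- paste0("s", 1:n); g2 <- paste0("s", (n + 1):(2 * n))
  norm <- sweep(cts, 2, computeSizeFactors(cts), "/")
  phi <- estimateDispersion(norm, g1, g2)
  res <- nbWaldTest(norm, g1, g2, phi)
  expect_gt(mean(res$p < 0.05), 0.035)
  expect_lt(mean(res$p < 0.05), 0.065)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(24)
  for (i in 1:20) {
    p <- runif(sample(1:300, 1))
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
  }
  # ties and boundary values
  p <- c(0, 0, 0.5, 0.5, 1, 0.02, 0.02)
  expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(-0.1, 0.2)), "\\[0, 1\\]")
})

test_that("BH is monotone in its inputs", {
  set.seed(25)
  p <- runif(50)
  adj <- bhAdjust(p)
  for (i in sample(50, 5)) {
    p2 <- p
    p2[i] <- min(1, p[i] + runif(1) * (1 - p[i]))
    expect_true(all(bhAdjust(p2) >= adj - 1e-12))
  }
})

test_that("deGenes recovers simulated programs and controls the null", {
  cfg <- simConfig(seed = 31)
  sim <- simulateExperiment(cfg)
  g <- deGenes(sim$experiment, "IFNa")
  truth <- sim$truth@programMembers$STAT1
  recovery <- mean(names(truth) %in% names(g))
  expect_gte(recovery, 0.7)
  common <- intersect(names(truth), names(g))
  expect_gte(mean(truth[common] == g[common]), 0.95)

  # chimera at alpha 0 is distributionally identical to control
  null <- deGenes(sim$experiment, "chimera_a000")
  expect_lte(length(null), 0.05 * nrow(sim$experiment))

  expect_length(deGenes(sim$experiment, "IFNa", alpha = 0), 0)
  expect_error(deGenes(sim$experiment, "nope"), "unknown condition")
  expect_error(deGenes(sim$experiment, "noICD"), "differ")
})

test_that("significance flags are exactly padj < alpha", {
  sim <- simulateExperiment(smallConfig(seed = 33))
  tab <- deTest(sim$experiment, "IL4", alpha = 0.05)
  expect_identical(tab$significant, tab$padj < 0.05)
  expect_true(all(tab$padj >= tab$p - 1e-12))
  expect_true(all(tab$p[tab$wald == 0] == 1))
})
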