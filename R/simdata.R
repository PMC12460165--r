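#' Default condition panel
#'
#' The stimulation design emulated by the simulator: one unstimulated control
#' ("noICD", the receptor-without-signalling-domain baseline), six reference
#' cytokine conditions mapped to their STATs (IFNa -> STAT1; IL-10 and
#' IL-21 -> STAT3; IL-2 and IL-7 -> STAT5; IL-4 -> STAT6), and a grid of
#' chimera (query) conditions activating one STAT at attenuation
#' \code{alpha in chimeraAlphas} — partial agonists of the target cytokine
#' program.
#'
#' @param chimeraStat STAT targeted by the chimera grid.
#' @param chimeraAlphas attenuation factors of the chimera conditions.
#' @return list with elements \code{conditions} (data.frame name/role/
#'   reference_stat) and \code{activation} (condition x STAT matrix).
#' @export
defaultConditions <- function(chimeraStat = "STAT3",
                              chimeraAlphas = c(0, 0.25, 0.5, 0.75, 1)) {
  refs <- data.frame(
    name = c("IFNa", "IL10", "IL21", "IL2", "IL7", "IL4"),
    role = "reference",
    reference_stat = c("STAT1", "STAT3", "STAT3", "STAT5", "STAT5", "STAT6"),
    stringsAsFactors = FALSE)
  chim <- data.frame(
    name = sprintf("chimera_a%03d", round(100 * chimeraAlphas)),
    role = rep("query", length(chimeraAlphas)),
    reference_stat = rep(NA_character_, length(chimeraAlphas)),
    stringsAsFactors = FALSE)
  cond <- rbind(
    data.frame(name = "noICD", role = "control",
               reference_stat = NA_character_, stringsAsFactors = FALSE),
    refs, chim)
  act <- matrix(0, nrow(cond), length(.STATS),
                dimnames = list(cond$name, .STATS))
  for (i in seq_len(nrow(refs))) act[refs$name[i], refs$reference_stat[i]] <- 1
  act[chim$name, chimeraStat] <- chimeraAlphas
  list(conditions = cond, activation = act)
}

#' Build a simulation configuration
#'
#' Defaults describe the emulated study: 2,000 genes, four disjoint STAT
#' programs of 200 genes, 30% of program genes repressed, a 2 log2-fold effect
#' at full activation, NB dispersion 0.1, log2-normal baselines (mean 6,
#' sd 2), depth factors uniform in [0.7, 1.3], 3 replicates per condition, and
#' a 10% private off-target program for each paired reference cytokine
#' (IL-10, IL-21, IL-2, IL-7) so that the STAT3/STAT5 intersections are
#' non-trivial.
#'
#' @param nGenes,programSizes,overlapFraction,fracRepressed,effectLog2FC
#'   see \linkS4class{SimConfig}.
#' @param dispersion,baselineLog2Mean,baselineLog2SD,libSizeRange,nReplicates
#'   see \linkS4class{SimConfig}.
#' @param conditions,activation design; defaults from
#'   \code{\link{defaultConditions}}.
#' @param offtargetFraction,geneLengthRange,seed see \linkS4class{SimConfig}.
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nGenes = 2000,
                      programSizes = c(STAT1 = 200, STAT3 = 200,
                                       STAT5 = 200, STAT6 = 200),
                      overlapFraction = 0,
                      fracRepressed = 0.3,
                      effectLog2FC = 2,
                      dispersion = 0.1,
                      baselineLog2Mean = 6,
                      baselineLog2SD = 2,
                      libSizeRange = c(0.7, 1.3),
                      nReplicates = 3,
                      conditions = NULL,
                      activation = NULL,
                      offtargetFraction = 0.1,
                      geneLengthRange = c(500L, 10000L),
                      seed = 1L) {
  if (is.null(conditions) || is.null(activation)) {
    dflt <- defaultConditions()
    if (is.null(conditions)) conditions <- dflt$conditions
    if (is.null(activation)) activation <- dflt$activation
  }
  activation <- activation[conditions$name, , drop = FALSE]
  new("SimConfig",
      nGenes = as.integer(nGenes), programSizes = programSizes,
      overlapFraction = overlapFraction, fracRepressed = fracRepressed,
      effectLog2FC = effectLog2FC, dispersion = dispersion,
      baselineLog2Mean = baselineLog2Mean, baselineLog2SD = baselineLog2SD,
      libSizeRange = as.numeric(libSizeRange),
      nReplicates = as.integer(nReplicates),
      conditions = conditions, activation = activation,
      offtargetFraction = offtargetFraction,
      geneLengthRange = as.integer(geneLengthRange),
      seed = as.integer(seed))
}

#' Negative-binomial count sampler
#'
#' Draws counts with mean \code{mean} and variance
#' \code{mean + dispersion * mean^2}; \code{dispersion = 0} degenerates to
#' Poisson. Vectorized over \code{mean}.
#'
#' @param n number of draws.
#' @param mean positive mean(s).
#' @param dispersion non-negative dispersion phi.
#' @return integer vector of non-negative counts.
#' @examples
#' mean(nbSample(1e4, 10, 0.1))
#' @export
nbSample <- function(n, mean, dispersion) {
  if (any(!is.finite(mean)) || any(mean <= 0))
    stop("'mean' must be positive", call. = FALSE)
  .assertScalarNum(dispersion, "dispersion", min = 0)
  if (dispersion == 0) stats::rpois(n, lambda = mean)
  else stats::rnbinom(n, mu = mean, size = 1 / dispersion)
}

## Assign program members: contiguous blocks over a shuffled gene pool;
## program i >= 2 takes its first ceil(f * size_i) members from the tail of
## program i-1, giving exactly that many shared genes per consecutive pair.
.assignPrograms <- function(genes, sizes, overlapFraction, fracRepressed) {
  pool <- sample(genes)
  members <- vector("list", length(sizes))
  names(members) <- names(sizes)
  cursor <- 1L
  for (i in seq_along(sizes)) {
    size <- as.integer(sizes[i])
    shared <- character()
    if (i > 1L && overlapFraction > 0) {
      nShare <- min(ceiling(overlapFraction * size),
                    length(members[[i - 1L]]))
      shared <- utils::tail(names(members[[i - 1L]]), nShare)
    }
    nNew <- size - length(shared)
    fresh <- pool[seq.int(cursor, length.out = nNew)]
    cursor <- cursor + nNew
    ids <- c(shared, fresh)
    nRep <- round(fracRepressed * size)
    signs <- rep(1, size)
    if (nRep > 0) signs[sample.int(size, nRep)] <- -1
    members[[i]] <- stats::setNames(signs, ids)
  }
  attr(members, "next_free") <- cursor
  attr(members, "pool") <- pool
  members
}

#' Simulate a cytokine-stimulation experiment
#'
#' Generates counts per the model in \linkS4class{SimConfig}: baseline means,
#' STAT program membership (disjoint unless \code{overlapFraction > 0}),
#' per-condition activations scaling the log2 effect, private off-target
#' programs for paired reference cytokines, per-sample depth factors, and NB
#' noise. Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{CytokineExperiment} with gene lengths attached) and
#'   \code{truth} (\linkS4class{SimTruth}).
#' @examples
#' sim <- simulateExperiment(simConfig(nGenes = 300,
#'   programSizes = c(STAT1 = 30, STAT3 = 30, STAT5 = 30, STAT6 = 30)))
#' sim$experiment
#' @export
simulateExperiment <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    genes <- sprintf("gene_%05d", seq_len(config@nGenes))
    baseline <- stats::setNames(
      2^stats::rnorm(config@nGenes, config@baselineLog2Mean,
                     config@baselineLog2SD), genes)
    lengths <- stats::setNames(
      sample.int(config@geneLengthRange[2] - config@geneLengthRange[1] + 1L,
                 config@nGenes, replace = TRUE) +
        config@geneLengthRange[1] - 1L, genes)
    members <- .assignPrograms(genes, config@programSizes,
                               config@overlapFraction, config@fracRepressed)

    ## private off-target programs for reference cytokines whose STAT is
    ## covered by >= 2 cytokines (the intersection step must prune these)
    cond <- config@conditions
    refStat <- stats::setNames(cond$reference_stat, cond$name)
    refConds <- cond$name[cond$role == "reference"]
    paired <- refConds[refStat[refConds] %in%
      names(which(table(refStat[refConds]) >= 2))]
    pool <- attr(members, "pool")
    cursor <- attr(members, "next_free")
    offtarget <- stats::setNames(vector("list", length(paired)), paired)
    for (cn in paired) {
      nOff <- ceiling(config@offtargetFraction *
                        config@programSizes[[refStat[[cn]]]])
      nOff <- min(nOff, length(pool) - cursor + 1L)
      offtarget[[cn]] <- pool[seq.int(cursor, length.out = nOff)]
      cursor <- cursor + nOff
    }

    ## per-condition log2 fold effect per gene
    stats_ <- colnames(config@activation)
    log2fold <- matrix(0, config@nGenes, nrow(cond),
                       dimnames = list(genes, cond$name))
    for (k in stats_) {
      pk <- members[[k]]
      if (is.null(pk)) next
      for (cn in cond$name) {
        a <- config@activation[cn, k]
        if (a > 0)
          log2fold[names(pk), cn] <- log2fold[names(pk), cn] +
            unname(pk) * a * config@effectLog2FC
      }
    }
    for (cn in names(offtarget)) {
      a <- config@activation[cn, refStat[[cn]]]
      log2fold[offtarget[[cn]], cn] <- log2fold[offtarget[[cn]], cn] +
        a * config@effectLog2FC
    }

    ## samples: <condition>_r<replicate>, depth factors uniform
    sampleCond <- rep(cond$name, each = config@nReplicates)
    sampleIds <- paste0(sampleCond, "_r", seq_len(config@nReplicates))
    depth <- stats::setNames(
      stats::runif(length(sampleIds), config@libSizeRange[1],
                   config@libSizeRange[2]), sampleIds)

    countsMat <- matrix(0L, config@nGenes, length(sampleIds),
                        dimnames = list(genes, sampleIds))
    for (s in seq_along(sampleIds)) {
      mu <- baseline * 2^log2fold[, sampleCond[s]] * depth[s]
      countsMat[, s] <- nbSample(config@nGenes, mu, config@dispersion)
    }

    sheet <- data.frame(
      sample = sampleIds, condition = sampleCond,
      role = cond$role[match(sampleCond, cond$name)],
      reference_stat = cond$reference_stat[match(sampleCond, cond$name)],
      stringsAsFactors = FALSE)
    experiment <- CytokineExperiment(countsMat, sheet, geneLengths = lengths)
    truth <- new("SimTruth",
                 programMembers = members[names(config@programSizes)],
                 conditionActivation = config@activation,
                 baselineMeans = baseline,
                 geneLengths = lengths,
                 offtargetMembers = offtarget,
                 depthFactors = depth)
    list(experiment = experiment, truth = truth)
  })
}
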