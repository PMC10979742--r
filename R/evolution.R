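#' @include AllClasses.R genome.R development.R fitness.R
NULL

## ---------------------------------------------------------------------------
## Internal fast-path GA.  Populations are lists of fast genomes (see
## genome.R); Genome S4 objects appear only at the exported boundaries.
## ---------------------------------------------------------------------------

.reproduceFast <- function(fasts, pairs, params) {
  spec <- params@genomeSpec
  cppReproduce(fasts, pairs, fasts[[1L]]$n, params@mutationRate,
               spec@density, spec@values == "gaussian")
}

## mean and sd helpers tolerant of length-1 input
.sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0

## projections of a developed population onto the phenotype axis
.projPhenotypes <- function(adults, eAnc, eNov, k) {
  d <- eNov[seq_len(k)] - eAnc[seq_len(k)]
  den <- sum(d * d)
  if (den == 0) return(rep(NA_real_, ncol(adults)))
  as.numeric(crossprod(adults[seq_len(k), , drop = FALSE] - eAnc[seq_len(k)], d)) / den
}

## one generation: develop (novel + optionally ancestral), record, select,
## reproduce.  Returns list(offspring, record).
.runGenerationFast <- function(fasts, envNovel, envAncestral, params,
                               measureAncestral = TRUE) {
  N <- length(fasts)
  n <- params@nEnv
  dp <- params@devParams
  fp <- params@fitnessParams
  model <- params@model
  k <- fp@nSelectedTraits

  if (model == "full") {
    cuesNov <- vapply(seq_len(N), function(q) generateCue(envNovel, params@cueNoise),
                      numeric(n))
    devNov <- .developPopulationFast(fasts, cuesNov, model, dp)
    if (measureAncestral) {
      cuesAnc <- vapply(seq_len(N), function(q) generateCue(envAncestral, params@cueNoise),
                        numeric(n))
      devAnc <- .developPopulationFast(fasts, cuesAnc, model, dp)
    } else devAnc <- NULL
  } else {
    ## NoCue development is cue-independent: the novel- and
    ## ancestral-environment outcomes of a genome are identical
    devNov <- .developPopulationFast(fasts, NULL, model, dp)
    devAnc <- if (measureAncestral) devNov else NULL
  }

  record <- NULL
  if (measureAncestral) {
    projNov <- .projPhenotypes(devNov$adults, envAncestral, envNovel, k)
    projAnc <- .projPhenotypes(devAnc$adults, envAncestral, envNovel, k)
    sel <- seq_len(k)
    record <- data.frame(
      projNovelMean = mean(projNov),
      projNovelSd = .sd0(projNov),
      projAncestralMean = mean(projAnc),
      projAncestralSd = .sd0(projAnc),
      mismatchNovel = mean(colSums(abs(devNov$adults[sel, , drop = FALSE] -
                                         envNovel[sel]))),
      mismatchAncestral = mean(colSums(abs(devAnc$adults[sel, , drop = FALSE] -
                                             envAncestral[sel]))),
      fracConverged = mean(devNov$converged),
      meanSteps = mean(devNov$nSteps),
      geneticVariance = .geneticVarianceFast(fasts))
  }

  ## selection and reproduction use only the novel-environment outcomes
  logW <- .logFitnessPopulation(devNov$adults, devNov$nSteps, devNov$converged,
                                envNovel, fp)
  omega <- normalizeFitness(logW)
  pairs <- selectParents(omega, N %/% 2L)
  list(offspring = .reproduceFast(fasts, pairs, params), record = record)
}

## one epoch; genotype projections are filled in after the last generation
## because their axis needs the first- and last-generation mean genomes
.runEpochFast <- function(fasts, envNovel, envAncestral, params,
                          record = TRUE) {
  G <- params@generationsPerEpoch
  records <- vector("list", G)
  snapshots <- if (record) vector("list", G) else NULL
  for (g in seq_len(G)) {
    if (record) snapshots[[g]] <- fasts
    step <- withCallingHandlers(
      .runGenerationFast(fasts, envNovel, envAncestral, params,
                         measureAncestral = record),
      error = function(e) {
        if (inherits(e, "grnevoExtinction"))
          stop(errorCondition(
            sprintf("%s (generation %d)", conditionMessage(e), g),
            class = "grnevoExtinction"))
      })
    if (record) records[[g]] <- cbind(generation = g, step$record)
    fasts <- step$offspring
  }
  traj <- NULL
  if (record) {
    traj <- do.call(rbind, records)
    geno <- .genotypeProjections(snapshots)
    traj$genoMean <- geno$mean
    traj$genoSd <- geno$sd
  }
  list(genomes = fasts, trajectory = traj)
}

.meanGenomeVector <- function(fasts, n) {
  sums <- numeric(6L * n * n)
  for (f in fasts) {
    idx <- .fastLinearIndex(f)
    sums[idx] <- sums[idx] + f$x
  }
  sums / length(fasts)
}

## per-generation mean/sd of genotype projections over epoch snapshots
.genotypeProjections <- function(snapshots) {
  n <- snapshots[[1L]][[1L]]$n
  G <- length(snapshots)
  g1 <- .meanGenomeVector(snapshots[[1L]], n)
  gT <- .meanGenomeVector(snapshots[[G]], n)
  axis <- gT - g1
  den <- sum(axis * axis)
  if (den == 0)
    return(list(mean = rep(NA_real_, G), sd = rep(NA_real_, G)))
  origin <- sum(g1 * axis) / den
  means <- numeric(G)
  sds <- numeric(G)
  for (g in seq_len(G)) {
    proj <- vapply(snapshots[[g]], function(f)
      sum(axis[.fastLinearIndex(f)] * f$x), numeric(1)) / den - origin
    means[g] <- mean(proj)
    sds[g] <- .sd0(proj)
  }
  list(mean = means, sd = sds)
}

## ---------------------------------------------------------------------------
## Exported GA operations
## ---------------------------------------------------------------------------

#' Produce an offspring population from selected parent pairs
#'
#' Each pair yields two offspring by row-block crossover
#' ([crossoverGenomes()]) followed by density-preserving mutation
#' ([mutateGenome()]) of each offspring.
#'
#' @param genomes list of [Genome-class] (the adult population).
#' @param pairs two-column integer matrix of parent indices (one row per
#'   pair), as returned by [selectParents()].
#' @param params an [EvolutionParams-class] (supplies mutation rate and
#'   genome spec).
#' @return list of `2 * nrow(pairs)` offspring [Genome-class] objects.
#' @export
reproduce <- function(genomes, pairs, params) {
  fasts <- lapply(genomes, .genomeToFast)
  lapply(.reproduceFast(fasts, pairs, params), .fastToGenome)
}

#' Run one generation of the evolutionary protocol
#'
#' Every genome develops twice — once with a cue derived from the novel
#' environment and once with a cue from the ancestral environment.  Fitness,
#' selection and reproduction use only the novel-environment outcomes; the
#' ancestral-environment population exists for measurement only and is
#' discarded.  For the NoCue model the two developments coincide by
#' construction and are computed once.
#'
#' @param genomes list of [Genome-class] of length `params@popSize`.
#' @param envNovel,envAncestral the novel (selective) and ancestral
#'   environments.
#' @param params an [EvolutionParams-class].
#' @return list with `genomes` (offspring list) and `record` (one-row
#'   data.frame of generation statistics: mean/sd projected phenotype in each
#'   environment, mean mismatch, convergence fraction, mean developmental
#'   steps, genetic variance).
#' @export
runGeneration <- function(genomes, envNovel, envAncestral, params) {
  if (length(genomes) != params@popSize)
    stop("genome count must equal params popSize")
  fasts <- lapply(genomes, .genomeToFast)
  step <- .runGenerationFast(fasts, envNovel, envAncestral, params)
  list(genomes = lapply(step$offspring, .fastToGenome), record = step$record)
}

#' Run one epoch (constant environment)
#'
#' Iterates [runGeneration()] for `params@generationsPerEpoch` generations
#' under fixed novel and ancestral environments, then adds the genotype
#' projections: their axis joins the population-mean vectorized genomes of
#' the epoch's first and last generation, so projected genotypes of 0 and 1
#' correspond to the average genotype before and after the epoch.
#'
#' @inheritParams runGeneration
#' @param record logical; record per-generation statistics (default TRUE).
#' @return list with `genomes` (population after the epoch) and `trajectory`
#'   (data.frame, one row per generation; NULL when `record = FALSE`).
#' @export
runEpoch <- function(genomes, envNovel, envAncestral, params, record = TRUE) {
  fasts <- lapply(genomes, .genomeToFast)
  res <- .runEpochFast(fasts, envNovel, envAncestral, params, record)
  list(genomes = lapply(res$genomes, .fastToGenome),
       trajectory = res$trajectory)
}

#' Run a full evolutionary experiment
#'
#' Executes the two-phase protocol: (1) `nPrepEpochs` preparatory epochs,
#' each under a freshly drawn, completely uncorrelated random environment, to
#' equilibrate the randomly initialized population; then (2) `nEpochs`
#' production epochs, each preceded by flipping `envChangeFraction` of the
#' current environment.  Within each production epoch the pre-change
#' environment serves as that epoch's ancestral environment.  Per-generation
#' statistics are recorded for the production epochs.
#'
#' @param params an [EvolutionParams-class] (see [evolutionParams()]).
#' @param verbose print one progress line per epoch.
#' @return an [ExperimentResult-class].
#' @examples
#' \donttest{
#' p <- evolutionParams(preset = "desk", nEpochs = 1, seed = 1)
#' res <- runExperiment(p)
#' head(trajectory(res))
#' }
#' @export
runExperiment <- function(params, verbose = FALSE) {
  validObject(params)
  if (!is.na(params@seed)) set.seed(params@seed)
  fasts <- replicate(params@popSize, .randomFast(params@genomeSpec),
                     simplify = FALSE)
  env <- newEnvironment(params@nEnv)
  epochRows <- list()
  trajRows <- list()

  runOne <- function(phase, ep, envNovel, envAncestral, record) {
    withCallingHandlers(
      .runEpochFast(fasts, envNovel, envAncestral, params, record),
      error = function(e) {
        if (inherits(e, "grnevoExtinction"))
          stop(errorCondition(
            sprintf("%s [%s epoch %d]", conditionMessage(e), phase, ep),
            class = "grnevoExtinction"))
      })
  }

  for (ep in seq_len(params@nPrepEpochs)) {
    envAnc <- env
    env <- newEnvironment(params@nEnv)
    res <- runOne("preparatory", ep, env, envAnc, record = FALSE)
    fasts <- res$genomes
    epochRows[[length(epochRows) + 1L]] <-
      data.frame(phase = "prep", epoch = ep,
                 envCorrelation = envCorrelation(envAnc, env))
    if (verbose)
      message(sprintf("prep epoch %d/%d done", ep, params@nPrepEpochs))
  }

  envAnc <- env
  for (ep in seq_len(params@nEpochs)) {
    envAnc <- env
    env <- flipEnvironment(env, params@envChangeFraction)
    res <- runOne("production", ep, env, envAnc, record = TRUE)
    fasts <- res$genomes
    traj <- cbind(epoch = ep, res$trajectory)
    trajRows[[ep]] <- traj
    epochRows[[length(epochRows) + 1L]] <-
      data.frame(phase = "production", epoch = ep,
                 envCorrelation = envCorrelation(envAnc, env))
    if (verbose)
      message(sprintf(
        "production epoch %d/%d: gen-1 mismatch %.2f, final mismatch %.2f",
        ep, params@nEpochs, traj$mismatchNovel[1L],
        traj$mismatchNovel[nrow(traj)]))
  }

  new("ExperimentResult",
      params = params,
      trajectory = if (length(trajRows)) do.call(rbind, trajRows) else data.frame(),
      epochs = if (length(epochRows)) do.call(rbind, epochRows) else data.frame(),
      finalGenomes = lapply(fasts, .fastToGenome),
      finalEnv = env,
      ancestralEnv = envAnc)
}
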