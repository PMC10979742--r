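test_that("rawLogFitness evaluates the printed closed forms", {
  e <- rep(1, 200)
  # perfect match on the selected traits, 10 steps: -(20*0 + 10/20)
  expect_identical(rawLogFitness(e, e, 10, TRUE), -0.5)
  expect_identical(rawLogFitness(e, e, 10, FALSE), -Inf)

  # traits beyond the selected window do not matter
  perturbed <- e
  perturbed[41:200] <- -5
  expect_identical(rawLogFitness(perturbed, e, 10, TRUE), -0.5)

  # mismatch raises the penalty linearly
  off <- e
  off[1] <- 0.5
  expect_equal(rawLogFitness(off, e, 10, TRUE), -(20 * 0.5 + 0.5))
  expect_error(rawLogFitness(numeric(10), e, 1, TRUE), "nSelectedTraits")
})

test_that("normalizeFitness is a shift-invariant max-normalization", {
  expect_identical(normalizeFitness(c(-0.5, -0.5)), c(1, 1))
  expect_equal(normalizeFitness(c(-1, -1 - log(2))), c(1, 0.5))
  lw <- c(-1600, -1630, -Inf, -1590)
  om <- normalizeFitness(lw)
  expect_identical(max(om), 1)
  expect_identical(om[3], 0)
  # invariance under constant shift (no under/overflow pathology)
  expect_equal(normalizeFitness(lw + 12345), om)
  expect_error(normalizeFitness(c(-Inf, -Inf)), class = "grnevoExtinction")
})

test_that("selectParents realizes acceptance-rejection roulette frequencies", {
  set.seed(401)
  # degenerate fitness: only individual 1 is ever selected
  om <- c(1, 0, 0, 0)
  pairs <- selectParents(om, 10)
  expect_identical(dim(pairs), c(10L, 2L))
  expect_true(all(pairs == 1L))

  # omega = (1, 0.5): stationary frequency of individual 1 is 2/3
  counts <- table(selectParents(c(1, 0.5), 3000))
  freq1 <- counts[["1"]] / 6000
  expect_lt(abs(freq1 - 2 / 3), 5 * sqrt((2 / 9) / 6000))

  expect_error(selectParents(c(0, 0), 2), class = "grnevoExtinction")
})

test_that("reproduce returns popSize offspring and respects crossover conservation", {
  set.seed(402)
  params <- evolutionParams(preset = "desk", nEnv = 10, popSize = 6,
                            density = 0.2, nSelectedTraits = 4,
                            mutationRate = 0)
  pop <- replicate(6, randomGenome(genomeSpec(n = 10, density = 0.2)),
                   simplify = FALSE)
  pairs <- cbind(c(1L, 3L, 5L), c(2L, 4L, 6L))
  off <- reproduce(pop, pairs, params)
  expect_length(off, 6)

  # with zero mutation and identical parents the offspring are clones
  offSame <- reproduce(list(pop[[1]], pop[[1]]), cbind(1L, 2L), params)
  for (m in c("E", "F", "G", "H", "J", "P"))
    expect_equal(as.matrix(genomeMatrix(offSame[[1]], m)),
                 as.matrix(genomeMatrix(pop[[1]], m)))

  # pre-mutation offspring rows partition the parental rows
  o <- reproduce(pop[1:2], cbind(1L, 2L), params)
  for (i in 1:10) {
    rA <- as.matrix(genomeMatrix(pop[[1]], "F"))[i, ]
    rB <- as.matrix(genomeMatrix(pop[[2]], "F"))[i, ]
    r1 <- as.matrix(genomeMatrix(o[[1]], "F"))[i, ]
    r2 <- as.matrix(genomeMatrix(o[[2]], "F"))[i, ]
    expect_true((identical(r1, rA) && identical(r2, rB)) ||
                  (identical(r1, rB) && identical(r2, rA)))
  }
})

test_that("runGeneration keeps population size and records finite statistics", {
  set.seed(403)
  params <- evolutionParams(preset = "desk", nEnv = 30, popSize = 10,
                            density = 0.1, nSelectedTraits = 6, seed = 1)
  pop <- replicate(10, randomGenome(genomeSpec(n = 30, density = 0.1)),
                   simplify = FALSE)
  eA <- newEnvironment(30)
  eN <- flipEnvironment(eA, 0.5)
  gen <- runGeneration(pop, eN, eA, params)
  expect_length(gen$genomes, 10)
  rec <- gen$record
  expect_true(all(is.finite(unlist(rec))))
  expect_gte(rec$mismatchNovel, 0)
  expect_error(runGeneration(pop[1:3], eN, eA, params), "popSize")
})

test_that("NoCue novel and ancestral phenotype clouds coincide", {
  set.seed(404)
  params <- evolutionParams(preset = "desk", nEnv = 30, popSize = 8,
                            density = 0.1, nSelectedTraits = 6,
                            model = "nocue")
  pop <- replicate(8, randomGenome(genomeSpec(n = 30, density = 0.1)),
                   simplify = FALSE)
  eA <- newEnvironment(30)
  eN <- flipEnvironment(eA, 0.5)
  rec <- runGeneration(pop, eN, eA, params)$record
  expect_identical(rec$projNovelMean, rec$projAncestralMean)
  expect_identical(rec$projNovelSd, rec$projAncestralSd)
})

test_that("runEpoch is reproducible and produces one record per generation", {
  params <- evolutionParams(preset = "desk", nEnv = 30, popSize = 10,
                            generationsPerEpoch = 3, density = 0.1,
                            nSelectedTraits = 6)
  set.seed(405)
  pop <- replicate(10, randomGenome(genomeSpec(n = 30, density = 0.1)),
                   simplify = FALSE)
  eA <- newEnvironment(30)
  eN <- flipEnvironment(eA, 0.5)

  set.seed(77)
  r1 <- runEpoch(pop, eN, eA, params)
  set.seed(77)
  r2 <- runEpoch(pop, eN, eA, params)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(nrow(r1$trajectory), 3L)
  expect_true(all(c("genoMean", "genoSd") %in% names(r1$trajectory)))

  one <- runEpoch(pop, eN, eA,
                  evolutionParams(preset = "desk", nEnv = 30, popSize = 10,
                                  generationsPerEpoch = 1, density = 0.1,
                                  nSelectedTraits = 6))
  expect_identical(nrow(one$trajectory), 1L)
})

test_that("whole-population non-convergence raises a labeled extinction error", {
  set.seed(406)
  # one developmental step cannot beat the unit initial moving variance
  params <- evolutionParams(preset = "desk", nEnv = 20, popSize = 4,
                            density = 0.1, nSelectedTraits = 4, maxSteps = 1)
  pop <- replicate(4, randomGenome(genomeSpec(n = 20, density = 0.1)),
                   simplify = FALSE)
  eA <- newEnvironment(20)
  expect_error(runGeneration(pop, flipEnvironment(eA, 0.5), eA, params),
               class = "grnevoExtinction")
})

test_that("a minimal experiment schedule runs end to end and is seed-stable", {
  params <- evolutionParams(preset = "desk", nEnv = 20, popSize = 6,
                            generationsPerEpoch = 2, nPrepEpochs = 0,
                            nEpochs = 1, density = 0.1, nSelectedTraits = 4,
                            seed = 9)
  res <- runExperiment(params)
  expect_s4_class(res, "ExperimentResult")
  expect_identical(nrow(trajectory(res)), 2L)
  expect_length(finalPopulation(res), 6)
  expect_identical(res@epochs$phase, "production")

  res2 <- runExperiment(params)
  expect_identical(trajectory(res), trajectory(res2))
  expect_identical(vectorizeGenome(finalPopulation(res)[[1]]),
                   vectorizeGenome(finalPopulation(res2)[[1]]))
})

test_that("a monomorphic population without mutation stays frozen", {
  set.seed(407)
  params <- evolutionParams(preset = "desk", nEnv = 20, popSize = 6,
                            generationsPerEpoch = 3, density = 0.1,
                            nSelectedTraits = 4, mutationRate = 0)
  g <- randomGenome(genomeSpec(n = 20, density = 0.1))
  pop <- replicate(6, g, simplify = FALSE)
  eA <- newEnvironment(20)
  eN <- flipEnvironment(eA, 0.5)
  ep <- runEpoch(pop, eN, eA, params)
  expect_identical(unique(ep$trajectory$geneticVariance), 0)
  # degenerate genotype axis reported as NA rather than NaN arithmetic
  expect_true(all(is.na(ep$trajectory$genoMean)))
  for (m in c("E", "F", "G", "H", "J", "P"))
    expect_equal(as.matrix(genomeMatrix(ep$genomes[[1]], m)),
                 as.matrix(genomeMatrix(g, m)))
})
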