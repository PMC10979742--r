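test_that("mismatch is the selected-trait L1 distance", {
  e <- newEnvironment(200)
  expect_identical(mismatch(e, e), 0)
  expect_identical(mismatch(-e, e), 80)  # 40 traits x |−1−(+1)|
  expect_error(mismatch(numeric(10), e), "nSelected")

  # developed phenotypes live strictly inside (-1, 1): mismatch > 0
  set.seed(501)
  g <- randomGenome(genomeSpec())
  out <- develop(g, generateCue(e, 0.05), "full")
  expect_gt(mismatch(adultPhenotype(out), e), 0)
})

test_that("phenotype projection anchors at 0 and 1 and is linear", {
  set.seed(502)
  eA <- newEnvironment(200)
  eN <- flipEnvironment(eA, 0.5)
  fr <- projectionFrame(eA, eN, 40)
  expect_identical(projectPhenotype(eN, fr), 1)
  expect_identical(projectPhenotype(eA, fr), 0)
  expect_equal(projectPhenotype((eA + eN) / 2, fr), 0.5)
  expect_error(projectPhenotype(eA, projectionFrame(eA, eA, 40)),
               "degenerate")
})

test_that("genotype projection anchors at 0 and 1 and is linear", {
  set.seed(503)
  g1 <- vectorizeGenome(randomGenome(genomeSpec(n = 10, density = 0.1)))
  g2 <- vectorizeGenome(randomGenome(genomeSpec(n = 10, density = 0.1)))
  fr <- projectionFrame(rep(1, 4), rep(-1, 4), 4, genoOrigin = g1, genoEnd = g2)
  expect_equal(projectGenotype(g1, fr), 0)
  expect_equal(projectGenotype(g2, fr), 1)
  expect_equal(projectGenotype((g1 + g2) / 2, fr), 0.5)
  expect_error(projectGenotype(g1, projectionFrame(rep(1, 4), rep(-1, 4), 4,
                                                   genoOrigin = g1, genoEnd = g1)),
               "degenerate")
  expect_error(projectGenotype(g1, projectionFrame(rep(1, 4), rep(-1, 4), 4)),
               "anchors")
})

test_that("crossCovariance matches hand and brute-force computation", {
  # N=2, one trait, one covariate: p=(0,2), x=(0,2) -> C = 1 (divisor N)
  expect_equal(as.numeric(crossCovariance(matrix(c(0, 2)), matrix(c(0, 2)))), 1)

  # constant phenotypes -> zero matrix
  expect_equal(max(abs(crossCovariance(matrix(1, 5, 3),
                                       matrix(rnorm(20), 5, 4)))), 0)

  # random case equals the double-loop definition
  set.seed(504)
  P <- matrix(rnorm(6 * 4), 6, 4)
  X <- matrix(rnorm(6 * 7), 6, 7)
  C <- crossCovariance(P, X)
  brute <- matrix(0, 4, 7)
  for (i in 1:4) for (j in 1:7)
    brute[i, j] <- mean((P[, i] - mean(P[, i])) * (X[, j] - mean(X[, j])))
  expect_equal(C, brute, tolerance = 1e-12)

  # sparse covariate input (the phenotype-genome case) agrees with dense
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  expect_equal(crossCovariance(P, Xs), brute, tolerance = 1e-12)

  expect_error(crossCovariance(P[1, , drop = FALSE], X[1, , drop = FALSE]),
               "N >= 2")
})

test_that("svdCrossCovariance recovers spectra and conserves total covariance", {
  # rank-1 matrix: recovers sigma, u, v up to sign
  u <- c(3, 4) / 5
  v <- c(1, 2, 2) / 3
  C1 <- 2.5 * u %*% t(v)
  s <- svdCrossCovariance(C1)
  expect_equal(singularValues(s)[1], 2.5)
  expect_equal(abs(sum(leftVectors(s)[, 1] * u)), 1)
  expect_equal(abs(sum(rightVectors(s)[, 1] * v)), 1)

  # diagonal case
  expect_equal(singularValues(svdCrossCovariance(diag(c(3, 1)))), c(3, 1))

  # Frobenius conservation and reconstruction on a random 5 x 7 matrix
  set.seed(505)
  C <- matrix(rnorm(35), 5, 7)
  s <- svdCrossCovariance(C, method = "direct")
  expect_equal(s@totalSq, sum(C^2), tolerance = 1e-8)
  rec <- leftVectors(s) %*% diag(singularValues(s)) %*% t(rightVectors(s))
  expect_lt(max(abs(rec - C)), 1e-10)

  # Gram fast path agrees with the direct SVD
  sg <- svdCrossCovariance(C, method = "gram")
  expect_equal(singularValues(sg), singularValues(s), tolerance = 1e-8)
  expect_equal(abs(colSums(leftVectors(sg) * leftVectors(s))), rep(1, 5),
               tolerance = 1e-8)
  rec2 <- leftVectors(sg) %*% diag(singularValues(sg)) %*% t(rightVectors(sg))
  expect_lt(max(abs(rec2 - C)), 1e-8)

  # sign convention: first nonzero component of each left vector >= 0
  expect_true(all(apply(leftVectors(s), 2, function(col) col[col != 0][1]) >= 0))

  expect_error(svdCrossCovariance(matrix(c(1, NA, 0, 1), 2)), "finite")
})

test_that("biasProportion reads the spectrum and is scale invariant", {
  expect_identical(biasProportion(c(5, 0, 0)), 1)
  expect_identical(biasProportion(c(1, 1, 1, 1)), 0.25)
  expect_identical(biasProportion(c(3, 1)), 9 / 10)
  expect_identical(biasProportion(7 * c(3, 1)), 9 / 10)
  s <- svdCrossCovariance(diag(c(3, 1)))
  expect_equal(biasProportion(s), 9 / 10)
  expect_error(biasProportion(c(0, 0)), "undefined")
})

test_that("alignment is the cosine with the environmental change, sign-free", {
  eA <- c(1, 1, 1, 1)
  eN <- c(-1, -1, 1, 1)
  fr <- projectionFrame(eA, eN, 4)
  d <- (eN - eA) / sqrt(sum((eN - eA)^2))
  expect_equal(alignment(d, fr), 1)
  expect_equal(alignment(-d, fr), 1)          # singular-vector sign ambiguity
  orth <- c(0, 0, 1, 0)
  expect_equal(alignment(orth, fr), 0)
  # a unit vector at 60 degrees from the axis
  u60 <- 0.5 * d + sqrt(3) / 2 * orth
  expect_equal(alignment(u60, fr), 0.5)
  expect_error(alignment(d, projectionFrame(eA, eA, 4)), "degenerate")
})

test_that("log-fitness decreases as mismatch grows at fixed step count", {
  e <- rep(1, 200)
  adults <- lapply(c(0.9, 0.5, 0), function(a) rep(a, 200))
  lws <- vapply(adults, rawLogFitness, numeric(1), env = e, nSteps = 50,
                converged = TRUE)
  expect_true(all(diff(lws) < 0))
})

test_that("transitionSweep emits one complete row per magnitude and replicate", {
  set.seed(506)
  params <- evolutionParams(preset = "desk", nEnv = 30, popSize = 12,
                            density = 0.1, nSelectedTraits = 6)
  pop <- replicate(12, randomGenome(genomeSpec(n = 30, density = 0.1)),
                   simplify = FALSE)
  env <- newEnvironment(30)
  sw <- transitionSweep(pop, env, params, magnitudes = c(0.3, 0.5),
                        nReplicates = 2)
  expect_identical(nrow(sw), 4L)
  stats <- c("projMean", "projVar", "s1PhenoCue", "s1PhenoGeno",
             "biasPhenoCue", "biasPhenoGeno", "alignPhenoCue", "alignPhenoGeno")
  expect_true(all(stats %in% names(sw)))
  # frame-dependent columns may be NA only when the random flip set missed
  # the selected-trait window; the spectral columns are always defined
  expect_true(all(is.finite(as.matrix(
    sw[, c("s1PhenoCue", "s1PhenoGeno", "biasPhenoCue", "biasPhenoGeno")]))))
  expect_true(all(sw$biasPhenoCue > 0 & sw$biasPhenoCue <= 1))
  expect_true(all(sw$alignPhenoGeno >= 0 & sw$alignPhenoGeno <= 1))
  expect_error(transitionSweep(list(), env, params), "equilibrated")
})

test_that("detectTransition flags the first magnitude above the jump threshold", {
  tab <- data.frame(
    magnitude = rep(c(0.05, 0.15, 0.25, 0.35), each = 3),
    projMean = c(0.01, 0.012, 0.011,  0.02, 0.018, 0.022,
                 0.2, 0.21, 0.19,     0.5, 0.52, 0.48))
  expect_identical(detectTransition(tab, "projMean", multiple = 3), 0.25)
  expect_identical(detectTransition(tab, "projMean", multiple = 100), NA_real_)
  expect_error(detectTransition(tab, "nope"), "unknown")
})
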