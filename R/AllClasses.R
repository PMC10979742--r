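#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Genome architecture specification
#'
#' Describes the shared architecture of all genomes in a population: the
#' number of genes `n` (so every interaction matrix is `n` by `n`), the target
#' sparsity `density` (fraction of nonzero entries per matrix; default 0.02)
#' and the distribution of nonzero values (`"pm1"`: uniform on \{+1, -1\};
#' `"gaussian"`: standard normal).
#'
#' @slot n integer, matrix dimension (number of genes / traits).
#' @slot density numeric in (0, 1], nonzero fraction per matrix.
#' @slot values character, `"pm1"` or `"gaussian"`.
#' @export
setClass("GenomeSpec",
  representation(n = "integer", density = "numeric", values = "character"),
  prototype(n = 200L, density = 0.02, values = "pm1"))

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
    msg <- c(msg, "n must be a single integer >= 1")
  if (length(object@density) != 1L || is.na(object@density) ||
      object@density <= 0 || object@density > 1)
    msg <- c(msg, "density must be in (0, 1]")
  if (length(object@values) != 1L || !object@values %in% c("pm1", "gaussian"))
    msg <- c(msg, "values must be \"pm1\" or \"gaussian\"")
  if (length(msg)) msg else TRUE
})

#' Constructor for [GenomeSpec-class]
#'
#' @param n matrix dimension (default 200).
#' @param density nonzero fraction per matrix (default 0.02).
#' @param values distribution of nonzero entries, `"pm1"` (default) or
#'   `"gaussian"`.
#' @return a `GenomeSpec` object.
#' @examples
#' genomeSpec(n = 10, density = 0.1)
#' @export
genomeSpec <- function(n = 200L, density = 0.02, values = c("pm1", "gaussian")) {
  values <- match.arg(values)
  new("GenomeSpec", n = as.integer(n), density = as.numeric(density),
      values = values)
}

#' Six-matrix sparse genome of a developmental GRN
#'
#' The heritable unit of the simulation: six sparse `n` by `n` interaction
#' matrices.  `E` couples the environmental signal to epigenetic marks, `G`
#' couples gene expression to epigenetic marks, `F` epigenetic marks to gene
#' expression, `H` gene expression to higher-order complexes, `J` higher-order
#' complexes to themselves, and `P` higher-order complexes to the phenotype.
#'
#' @slot E,F,G,H,J,P sparse (`dgCMatrix`) square matrices of equal dimension.
#' @seealso [randomGenome()], [mutateGenome()], [crossoverGenomes()],
#'   [vectorizeGenome()]
#' @export
setClass("Genome",
  representation(E = "dgCMatrix", F = "dgCMatrix", G = "dgCMatrix",
                 H = "dgCMatrix", J = "dgCMatrix", P = "dgCMatrix"))

setValidity("Genome", function(object) {
  dims <- vapply(GENOME_MATRICES, function(m) dim(slot(object, m)), integer(2))
  if (any(dims != dims[1L]))
    return("all six matrices must be square and of identical dimension")
  TRUE
})

GENOME_MATRICES <- c("E", "F", "G", "H", "J", "P")

#' Developmental dynamics parameters
#'
#' @slot maxSteps integer, maximum number of developmental steps (default 200).
#' @slot convTol numeric, convergence threshold on the total exponential moving
#'   variance of the expressed phenotype (default 1e-5).
#' @slot emaAlpha numeric in (0,1), weight of the current phenotype in the
#'   exponential moving average (default 1/3).
#' @slot gains numeric(4), named `f`, `g`, `h`, `p`: gain of each layer's
#'   activation function (default all 0.5).
#' @export
setClass("DevParams",
  representation(maxSteps = "integer", convTol = "numeric",
                 emaAlpha = "numeric", gains = "numeric"),
  prototype(maxSteps = 200L, convTol = 1e-5, emaAlpha = 1 / 3,
            gains = c(f = 0.5, g = 0.5, h = 0.5, p = 0.5)))

setValidity("DevParams", function(object) {
  msg <- character()
  if (object@maxSteps < 1L) msg <- c(msg, "maxSteps must be >= 1")
  if (object@convTol <= 0) msg <- c(msg, "convTol must be > 0")
  if (object@emaAlpha <= 0 || object@emaAlpha >= 1)
    msg <- c(msg, "emaAlpha must be in (0, 1)")
  if (!identical(names(object@gains), c("f", "g", "h", "p")) ||
      any(object@gains <= 0))
    msg <- c(msg, "gains must be positive and named f, g, h, p")
  if (length(msg)) msg else TRUE
})

#' Constructor for [DevParams-class]
#'
#' @param maxSteps maximum developmental steps (default 200).
#' @param convTol convergence threshold on total phenotypic exponential moving
#'   variance (default `1e-5`).
#' @param emaAlpha exponential-moving-average weight (default 1/3).
#' @param gains named numeric(4) activation gains for layers f, g, h, p.
#' @return a `DevParams` object.
#' @export
devParams <- function(maxSteps = 200L, convTol = 1e-5, emaAlpha = 1 / 3,
                      gains = c(f = 0.5, g = 0.5, h = 0.5, p = 0.5)) {
  new("DevParams", maxSteps = as.integer(maxSteps), convTol = convTol,
      emaAlpha = emaAlpha, gains = gains)
}

#' Outcome of one developmental run
#'
#' @slot adult numeric, the adult phenotype (the exponential moving average of
#'   the expressed phenotype at the stopping step).
#' @slot nSteps integer, number of developmental steps executed.
#' @slot converged logical, whether the total exponential moving variance fell
#'   below the threshold within the step budget.
#' @export
setClass("DevOutcome",
  representation(adult = "numeric", nSteps = "integer", converged = "logical"))

setValidity("DevOutcome", function(object) {
  if (length(object@nSteps) != 1L || length(object@converged) != 1L)
    return("nSteps and converged must be scalars")
  TRUE
})

#' Fitness function parameters
#'
#' Raw log-fitness of a converged individual is
#' `-(alphaSel * L1 + betaStep * nSteps)` where `L1` is the mismatch (L1
#' distance between adult phenotype and environment over the first
#' `nSelectedTraits` traits).  Non-converged individuals have zero fitness
#' (`-Inf` in log space).
#'
#' @slot alphaSel numeric, weight of the mismatch term (default 20).
#' @slot betaStep numeric, weight of the developmental step count
#'   (default 1/20).
#' @slot nSelectedTraits integer, number of leading traits under selection
#'   (default 40).
#' @export
setClass("FitnessParams",
  representation(alphaSel = "numeric", betaStep = "numeric",
                 nSelectedTraits = "integer"),
  prototype(alphaSel = 20, betaStep = 1 / 20, nSelectedTraits = 40L))

setValidity("FitnessParams", function(object) {
  msg <- character()
  if (object@alphaSel <= 0 || object@betaStep <= 0 ||
      object@nSelectedTraits <= 0L)
    msg <- c(msg, "alphaSel, betaStep and nSelectedTraits must be positive")
  if (length(msg)) msg else TRUE
})

#' Constructor for [FitnessParams-class]
#'
#' @param alphaSel mismatch weight (default 20).
#' @param betaStep developmental-step weight (default 1/20).
#' @param nSelectedTraits number of selected traits (default 40).
#' @return a `FitnessParams` object.
#' @export
fitnessParams <- function(alphaSel = 20, betaStep = 1 / 20,
                          nSelectedTraits = 40L) {
  new("FitnessParams", alphaSel = alphaSel, betaStep = betaStep,
      nSelectedTraits = as.integer(nSelectedTraits))
}

#' Full configuration of an evolutionary experiment
#'
#' Bundles every parameter of the genetic-algorithm protocol.  Defaults are
#' the full-scale study conditions: 1000 individuals, 200 generations per
#' epoch, 200-dimensional environments, 5% cue noise, 0.5% mutation rate,
#' 40 preparatory epochs.
#'
#' @slot nEnv integer, environment/phenotype dimension.
#' @slot popSize integer, population size (must be even).
#' @slot generationsPerEpoch integer, generations per epoch.
#' @slot nEpochs integer, number of production epochs.
#' @slot envChangeFraction numeric in \[0,1\], fraction of environment elements
#'   flipped between production epochs.
#' @slot cueNoise numeric in \[0,1\], fraction of elements flipped when deriving
#'   an individual's cue from the macro-environment.
#' @slot mutationRate numeric in \[0,1\], per-element mutation probability.
#' @slot nPrepEpochs integer, preparatory epochs under uncorrelated
#'   environments.
#' @slot model character, `"full"` or `"nocue"`.
#' @slot genomeSpec a [GenomeSpec-class].
#' @slot devParams a [DevParams-class].
#' @slot fitnessParams a [FitnessParams-class].
#' @slot seed integer master seed (NA for none).
#' @export
setClass("EvolutionParams",
  representation(nEnv = "integer", popSize = "integer",
                 generationsPerEpoch = "integer", nEpochs = "integer",
                 envChangeFraction = "numeric", cueNoise = "numeric",
                 mutationRate = "numeric", nPrepEpochs = "integer",
                 model = "character", genomeSpec = "GenomeSpec",
                 devParams = "DevParams", fitnessParams = "FitnessParams",
                 seed = "integer"),
  prototype(nEnv = 200L, popSize = 1000L, generationsPerEpoch = 200L,
            nEpochs = 10L, envChangeFraction = 0.5, cueNoise = 0.05,
            mutationRate = 0.005, nPrepEpochs = 40L, model = "full",
            seed = NA_integer_))

setValidity("EvolutionParams", function(object) {
  msg <- character()
  if (object@popSize < 2L || object@popSize %% 2L != 0L)
    msg <- c(msg, "popSize must be even and >= 2")
  for (f in c("envChangeFraction", "cueNoise", "mutationRate")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, paste(f, "must be in [0, 1]"))
  }
  if (!object@model %in% c("full", "nocue"))
    msg <- c(msg, "model must be \"full\" or \"nocue\"")
  if (object@generationsPerEpoch < 1L) msg <- c(msg, "generationsPerEpoch must be >= 1")
  if (object@nEpochs < 0L) msg <- c(msg, "nEpochs must be >= 0")
  if (object@nPrepEpochs < 0L) msg <- c(msg, "nPrepEpochs must be >= 0")
  if (object@genomeSpec@n != object@nEnv)
    msg <- c(msg, "genomeSpec n must equal nEnv (phenotype and environment share dimension)")
  if (object@fitnessParams@nSelectedTraits > object@nEnv)
    msg <- c(msg, "nSelectedTraits cannot exceed nEnv")
  if (length(msg)) msg else TRUE
})

#' Projection frame for genotype-phenotype plots
#'
#' Holds the anchors of the two projection axes: the selected-trait
#' restrictions of the ancestral and novel environments (phenotype axis), and
#' the population-mean vectorized genomes at the first and last generation of
#' an epoch (genotype axis).  The genotype anchors may be empty when only
#' phenotype projections are needed.
#'
#' @slot eAncSel,eNovSel numeric, first `nSelectedTraits` elements of the
#'   ancestral and novel environments.
#' @slot genoOrigin,genoEnd numeric or NULL, mean vectorized genomes at the
#'   first and last generation of the epoch.
#' @export
setClass("ProjectionFrame",
  representation(eAncSel = "numeric", eNovSel = "numeric",
                 genoOrigin = "numericOrNULL", genoEnd = "numericOrNULL"))

setValidity("ProjectionFrame", function(object) {
  msg <- character()
  if (length(object@eAncSel) != length(object@eNovSel))
    msg <- c(msg, "environment anchors must have equal length")
  if (!is.null(object@genoOrigin) &&
      length(object@genoOrigin) != length(object@genoEnd))
    msg <- c(msg, "genotype anchors must have equal length")
  if (length(msg)) msg else TRUE
})

#' Singular value decomposition of a cross-covariance matrix
#'
#' @slot singularValues numeric, nonincreasing nonnegative singular values.
#' @slot left matrix, left singular vectors (phenotype side), one per column.
#' @slot right matrix, right singular vectors (cue/genome side), possibly
#'   0-column when the economical Gram path skipped them.
#' @slot totalSq numeric, sum of squared singular values (squared Frobenius
#'   norm of the decomposed matrix).
#' @export
setClass("CrossCovSVD",
  representation(singularValues = "numeric", left = "matrix",
                 right = "matrix", totalSq = "numeric"))

setValidity("CrossCovSVD", function(object) {
  sv <- object@singularValues
  if (any(sv < -1e-12)) return("singular values must be nonnegative")
  if (is.unsorted(rev(sv), strictly = FALSE) && any(diff(sv) > 1e-12))
    return("singular values must be nonincreasing")
  TRUE
})

#' Result of an evolutionary experiment
#'
#' @slot params the [EvolutionParams-class] used.
#' @slot trajectory data.frame of per-generation records of the production
#'   epochs (see [runEpoch()] for columns).
#' @slot epochs data.frame with one row per epoch (phase, epoch index,
#'   correlation between novel and ancestral environment).
#' @slot finalGenomes list of [Genome-class], the population after the last
#'   epoch.
#' @slot finalEnv numeric, the last selective environment.
#' @slot ancestralEnv numeric, the environment of the penultimate epoch.
#' @export
setClass("ExperimentResult",
  representation(params = "EvolutionParams", trajectory = "data.frame",
                 epochs = "data.frame", finalGenomes = "list",
                 finalEnv = "numeric", ancestralEnv = "numeric"))
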