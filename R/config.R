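#' @include AllClasses.R development.R
NULL

#' Build an evolution configuration
#'
#' Convenience constructor for [EvolutionParams-class].  The `"paper"` preset
#' (default) is the full-scale protocol: 200-dimensional environments,
#' 1000 individuals, 200 generations per epoch, 40 preparatory epochs,
#' density 0.02, cue noise 5%, mutation rate 0.5%, mismatch weight 20, step
#' weight 1/20, 40 selected traits, convergence threshold 1e-5 within 200
#' steps.  The `"desk"` preset shrinks the protocol to workstation scale
#' (200 individuals, 50 generations per epoch, 3 preparatory and 3
#' production epochs) while leaving every model parameter untouched.
#'
#' @param preset `"paper"` (default) or `"desk"`.
#' @param nEnv environment/trait dimension.
#' @param popSize population size (even).
#' @param generationsPerEpoch generations per epoch.
#' @param nEpochs production epochs.
#' @param envChangeFraction fraction of the environment flipped between
#'   production epochs.
#' @param cueNoise cue noise fraction.
#' @param mutationRate per-element mutation probability.
#' @param nPrepEpochs preparatory epochs.
#' @param model `"full"` or `"nocue"`.
#' @param density genome matrix density.
#' @param values nonzero value distribution, `"pm1"` or `"gaussian"`.
#' @param maxSteps,convTol,emaAlpha,gains developmental parameters, see
#'   [devParams()].
#' @param alphaSel,betaStep,nSelectedTraits fitness parameters, see
#'   [fitnessParams()].
#' @param seed master seed (NA for none).
#' @return an [EvolutionParams-class].
#' @examples
#' evolutionParams(preset = "desk", envChangeFraction = 0.5, seed = 1)
#' @export
evolutionParams <- function(preset = c("paper", "desk"),
                            nEnv = 200L,
                            popSize = NULL,
                            generationsPerEpoch = NULL,
                            nEpochs = NULL,
                            envChangeFraction = 0.5,
                            cueNoise = 0.05,
                            mutationRate = 0.005,
                            nPrepEpochs = NULL,
                            model = c("full", "nocue"),
                            density = 0.02,
                            values = "pm1",
                            maxSteps = 200L,
                            convTol = 1e-5,
                            emaAlpha = 1 / 3,
                            gains = c(f = 0.5, g = 0.5, h = 0.5, p = 0.5),
                            alphaSel = 20,
                            betaStep = 1 / 20,
                            nSelectedTraits = 40L,
                            seed = NA_integer_) {
  preset <- match.arg(preset)
  model <- match.arg(model)
  scale <- switch(preset,
    paper = list(popSize = 1000L, generationsPerEpoch = 200L,
                 nPrepEpochs = 40L, nEpochs = 10L),
    desk = list(popSize = 200L, generationsPerEpoch = 50L,
                nPrepEpochs = 3L, nEpochs = 3L))
  popSize <- if (is.null(popSize)) scale$popSize else as.integer(popSize)
  generationsPerEpoch <- if (is.null(generationsPerEpoch))
    scale$generationsPerEpoch else as.integer(generationsPerEpoch)
  nPrepEpochs <- if (is.null(nPrepEpochs)) scale$nPrepEpochs else as.integer(nPrepEpochs)
  nEpochs <- if (is.null(nEpochs)) scale$nEpochs else as.integer(nEpochs)
  new("EvolutionParams",
      nEnv = as.integer(nEnv), popSize = popSize,
      generationsPerEpoch = generationsPerEpoch, nEpochs = nEpochs,
      envChangeFraction = envChangeFraction, cueNoise = cueNoise,
      mutationRate = mutationRate, nPrepEpochs = nPrepEpochs, model = model,
      genomeSpec = genomeSpec(n = nEnv, density = density, values = values),
      devParams = devParams(maxSteps = maxSteps, convTol = convTol,
                            emaAlpha = emaAlpha, gains = gains),
      fitnessParams = fitnessParams(alphaSel = alphaSel, betaStep = betaStep,
                                    nSelectedTraits = nSelectedTraits),
      seed = as.integer(seed))
}

.CONFIG_KEYS <- c("preset", "nEnv", "popSize", "generationsPerEpoch",
                  "nEpochs", "envChangeFraction", "cueNoise", "mutationRate",
                  "nPrepEpochs", "model", "density", "values", "maxSteps",
                  "convTol", "emaAlpha", "gains", "alphaSel", "betaStep",
                  "nSelectedTraits", "seed")

#' Load an evolution configuration from a YAML file
#'
#' Keys mirror the arguments of [evolutionParams()]; an empty file yields the
#' full-scale defaults.  Unknown keys and out-of-range values are rejected
#' with an error listing the offending fields.
#'
#' @param path path to a YAML config file.
#' @return an [EvolutionParams-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$gains)) cfg$gains <- unlist(cfg$gains)
  tryCatch(do.call(evolutionParams, cfg),
           error = function(e) stop("invalid config ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

## flatten params for manifests and config echo
.paramsToList <- function(params) {
  list(nEnv = params@nEnv, popSize = params@popSize,
       generationsPerEpoch = params@generationsPerEpoch,
       nEpochs = params@nEpochs,
       envChangeFraction = params@envChangeFraction,
       cueNoise = params@cueNoise, mutationRate = params@mutationRate,
       nPrepEpochs = params@nPrepEpochs, model = params@model,
       density = params@genomeSpec@density, values = params@genomeSpec@values,
       maxSteps = params@devParams@maxSteps,
       convTol = params@devParams@convTol,
       emaAlpha = params@devParams@emaAlpha,
       gains = as.list(params@devParams@gains),
       alphaSel = params@fitnessParams@alphaSel,
       betaStep = params@fitnessParams@betaStep,
       nSelectedTraits = params@fitnessParams@nSelectedTraits,
       seed = params@seed)
}

#' Write a run manifest
#'
#' Records everything needed to re-run an experiment bit-identically: the
#' full config echo, the master seed, the package version, and an inventory
#' of output files with optional environment fingerprints.
#'
#' @param params the [EvolutionParams-class] of the run.
#' @param path output JSON path.
#' @param files character vector of output files produced by the run.
#' @param extra named list of additional entries (e.g. environment hashes).
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(params, path, files = character(), extra = list()) {
  manifest <- c(list(
    package = "grnevo",
    version = as.character(utils::packageVersion("grnevo")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = .paramsToList(params),
    files = as.list(files)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Generate small deterministic fixtures
#'
#' Writes the tiny inputs used by the test suite and the documentation: a
#' toy environment (one-row CSV), toy genomes at n = 3 and n = 10 (sparse
#' triplet TSV), and a worked development trace (per-step state of the
#' reference recursion on the n = 3 genome, CSV).  Deterministic given
#' `seed`.
#'
#' @param dir output directory (created if needed).
#' @param kind which fixtures to write (default all).
#' @param seed RNG seed (default 42).
#' @return character vector of written paths, invisibly.
#' @export
makeFixtures <- function(dir,
                         kind = c("toy-environment", "toy-genome",
                                  "worked-development"),
                         seed = 42L) {
  kind <- match.arg(kind, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- character(0)
  env4 <- newEnvironment(4L)
  env3 <- newEnvironment(3L)
  g3 <- randomGenome(genomeSpec(n = 3L, density = 0.5))
  g10 <- randomGenome(genomeSpec(n = 10L, density = 0.1))
  if ("toy-environment" %in% kind) {
    p <- file.path(dir, "toy-environment-n4.csv")
    writeEnvironmentCsv(env4, p)
    paths <- c(paths, p)
  }
  if ("toy-genome" %in% kind) {
    p3 <- file.path(dir, "toy-genome-n3.tsv")
    p10 <- file.path(dir, "toy-genome-n10.tsv")
    writeGenomeTsv(g3, p3)
    writeGenomeTsv(g10, p10)
    paths <- c(paths, p3, p10)
  }
  if ("worked-development" %in% kind) {
    p <- file.path(dir, "worked-development-n3.csv")
    state <- devInitialState(3L)
    rows <- list()
    for (s in 1:5) {
      state <- devStep(state, g3, cue = env3, model = "full")
      rows[[s]] <- data.frame(step = s,
                              trait = 1:3, f = state$f, g = state$g,
                              h = state$h, p = state$p, pEma = state$pEma,
                              v = state$v)
    }
    utils::write.csv(do.call(rbind, rows), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
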