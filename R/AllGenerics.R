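#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 classes.
#'
#' @param x an object.
#' @param ... ignored.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("adultPhenotype", function(x, ...) standardGeneric("adultPhenotype"))

#' @rdname accessors
#' @export
setGeneric("devSteps", function(x, ...) standardGeneric("devSteps"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x, ...) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("genomeSize", function(x, ...) standardGeneric("genomeSize"))

#' @rdname accessors
#' @param which matrix label, one of `"E"`, `"F"`, `"G"`, `"H"`, `"J"`, `"P"`.
#' @export
setGeneric("genomeMatrix", function(x, which, ...) standardGeneric("genomeMatrix"))

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x, ...) standardGeneric("singularValues"))

#' @rdname accessors
#' @export
setGeneric("leftVectors", function(x, ...) standardGeneric("leftVectors"))

#' @rdname accessors
#' @export
setGeneric("rightVectors", function(x, ...) standardGeneric("rightVectors"))

#' @rdname accessors
#' @export
setGeneric("trajectory", function(x, ...) standardGeneric("trajectory"))

#' @rdname accessors
#' @export
setGeneric("finalPopulation", function(x, ...) standardGeneric("finalPopulation"))

#' @rdname accessors
#' @export
setMethod("adultPhenotype", "DevOutcome", function(x, ...) x@adult)

#' @rdname accessors
#' @export
setMethod("devSteps", "DevOutcome", function(x, ...) x@nSteps)

#' @rdname accessors
#' @export
setMethod("isConverged", "DevOutcome", function(x, ...) x@converged)

#' @rdname accessors
#' @export
setMethod("genomeSize", "Genome", function(x, ...) nrow(x@E))

#' @rdname accessors
#' @export
setMethod("genomeMatrix", "Genome", function(x, which, ...) {
  which <- match.arg(which, GENOME_MATRICES)
  slot(x, which)
})

#' @rdname accessors
#' @export
setMethod("singularValues", "CrossCovSVD", function(x, ...) x@singularValues)

#' @rdname accessors
#' @export
setMethod("leftVectors", "CrossCovSVD", function(x, ...) x@left)

#' @rdname accessors
#' @export
setMethod("rightVectors", "CrossCovSVD", function(x, ...) x@right)

#' @rdname accessors
#' @export
setMethod("trajectory", "ExperimentResult", function(x, ...) x@trajectory)

#' @rdname accessors
#' @export
setMethod("finalPopulation", "ExperimentResult", function(x, ...) x@finalGenomes)

setMethod("show", "GenomeSpec", function(object) {
  cat(sprintf("GenomeSpec: %d x %d matrices, density %.4g, values %s\n",
              object@n, object@n, object@density, object@values))
})

setMethod("show", "Genome", function(object) {
  n <- genomeSize(object)
  nnz <- vapply(GENOME_MATRICES,
                function(m) length(slot(object, m)@x), numeric(1))
  cat(sprintf("Genome: six %d x %d sparse matrices (E,F,G,H,J,P)\n", n, n))
  cat(sprintf("  nonzeros: %s\n",
              paste(sprintf("%s=%d", GENOME_MATRICES, nnz), collapse = " ")))
})

setMethod("show", "DevOutcome", function(object) {
  cat(sprintf("DevOutcome: %d traits, %d steps, %s\n",
              length(object@adult), object@nSteps,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "EvolutionParams", function(object) {
  cat(sprintf("EvolutionParams (%s model)\n", object@model))
  cat(sprintf("  nEnv=%d popSize=%d generations/epoch=%d epochs=%d prep=%d\n",
              object@nEnv, object@popSize, object@generationsPerEpoch,
              object@nEpochs, object@nPrepEpochs))
  cat(sprintf("  envChange=%.3g cueNoise=%.3g mutationRate=%.3g seed=%s\n",
              object@envChangeFraction, object@cueNoise, object@mutationRate,
              ifelse(is.na(object@seed), "NA", object@seed)))
})

setMethod("show", "CrossCovSVD", function(object) {
  sv <- object@singularValues
  cat(sprintf("CrossCovSVD: %d singular values, sigma1=%.4g, bias=%.4g\n",
              length(sv), sv[1L], sv[1L]^2 / object@totalSq))
})

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf("ExperimentResult: %s model, %d production epochs, %d recorded generations\n",
              object@params@model, object@params@nEpochs,
              nrow(object@trajectory)))
})
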