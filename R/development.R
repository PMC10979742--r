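#' @include AllClasses.R genome.R
NULL

#' Layer activation functions
#'
#' The epigenetic (`f`), expression (`g`) and complex (`h`) layers use the
#' scaled inverse tangent `(2/pi) * atan(gain * x)`; the phenotype layer (`p`)
#' uses `tanh(gain * x)`.  All are odd, strictly monotone and map into
#' (-1, 1).
#'
#' @param layer one of `"f"`, `"g"`, `"h"`, `"p"`.
#' @param x numeric input (vectorized).
#' @param gain positive gain (default 1).
#' @return numeric of the same length as `x`, in (-1, 1).
#' @examples
#' activation("f", 1)          # (2/pi) * atan(1) == 0.5
#' activation("p", 1e3)        # ~ 1
#' @export
activation <- function(layer = c("f", "g", "h", "p"), x, gain = 1) {
  layer <- match.arg(layer)
  if (layer == "p") tanh(gain * x) else (2 / pi) * atan(gain * x)
}

#' Initial developmental state
#'
#' Development starts from `f = 0`, `g = 1`, `h = 0`, `p = 0`, a zero
#' phenotype moving average and unit moving variance per trait.  Unit initial
#' variance enforces a burn-in: the total moving variance cannot fall below
#' the convergence threshold after just one step.
#'
#' @param n number of traits.
#' @return a named list with elements `f`, `g`, `h`, `p`, `pEma`, `v`, `step`.
#' @export
devInitialState <- function(n) {
  list(f = numeric(n), g = rep(1, n), h = numeric(n), p = numeric(n),
       pEma = numeric(n), v = rep(1, n), step = 0L)
}

#' One step of the developmental recursion (reference implementation)
#'
#' Advances the mutually recursive developmental dynamics by one step, in the
#' order dictated by the recursion: epigenetic marks `f` from the previous
#' expression state (plus, in the Full model, the difference between the cue
#' and the running phenotype average), then expression `g`, complexes `h`,
#' expressed phenotype `p`, and finally the phenotype moving average and
#' moving variance.  This pure-R single-step function is the readable
#' reference path; [develop()] runs the same recursion in compiled code.
#'
#' @param state a state list as returned by [devInitialState()] or a previous
#'   `devStep()` call.
#' @param genome a [Genome-class].
#' @param cue a +1/-1 cue vector (required for `model = "full"`, forbidden
#'   for `"nocue"`).
#' @param model `"full"` or `"nocue"`.
#' @param params a [DevParams-class].
#' @return the updated state list.
#' @export
devStep <- function(state, genome, cue = NULL, model = c("full", "nocue"),
                    params = devParams()) {
  model <- match.arg(model)
  n <- genomeSize(genome)
  if (model == "full" && is.null(cue))
    stop("the full model requires an environmental cue")
  if (model == "nocue" && !is.null(cue))
    stop("the nocue model takes no environmental cue")
  if (!is.null(cue) && length(cue) != n)
    stop("cue length must equal the genome dimension")
  a <- params@emaAlpha
  gains <- params@gains
  cvec <- (if (model == "full") cue else 0) - state$pEma
  f <- activation("f", as.numeric(genome@G %*% state$g + genome@E %*% cvec),
                  gains[["f"]])
  g <- activation("g", as.numeric(genome@F %*% f), gains[["g"]])
  h <- activation("h", as.numeric(genome@H %*% g + genome@J %*% state$h),
                  gains[["h"]])
  p <- activation("p", as.numeric(genome@P %*% h), gains[["p"]])
  v <- (1 - a) * (state$v + a * (state$pEma - p)^2)
  pEma <- a * p + (1 - a) * state$pEma
  list(f = f, g = g, h = h, p = p, pEma = pEma, v = v,
       step = state$step + 1L)
}

#' Develop a genome to its adult phenotype
#'
#' Iterates the developmental recursion from the standard initial state until
#' the total phenotypic exponential moving variance `sum(v)` drops below
#' `convTol`, or `maxSteps` is reached.  The adult phenotype is the phenotype
#' moving average at the stopping step.  Development is fully deterministic
#' given genome, cue and parameters; non-convergence is a reported outcome,
#' not an error.
#'
#' @inheritParams devStep
#' @param engine `"cpp"` (compiled, default) or `"r"` (iterated [devStep()]).
#' @return a [DevOutcome-class].
#' @examples
#' set.seed(1)
#' spec <- genomeSpec(n = 20, density = 0.1)
#' g <- randomGenome(spec)
#' e <- newEnvironment(20)
#' develop(g, generateCue(e), model = "full")
#' @export
develop <- function(genome, cue = NULL, model = c("full", "nocue"),
                    params = devParams(), engine = c("cpp", "r")) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  n <- genomeSize(genome)
  if (model == "full" && is.null(cue))
    stop("the full model requires an environmental cue")
  if (model == "nocue" && !is.null(cue))
    stop("the nocue model takes no environmental cue")
  if (!is.null(cue) && length(cue) != n)
    stop("cue length must equal the genome dimension")
  if (engine == "cpp") {
    fast <- .genomeToFast(genome)
    .outcomeFromCpp(cppDevelop(fast$m, fast$i, fast$j, fast$x, n,
                               if (is.null(cue)) numeric(0) else as.numeric(cue),
                               model == "full", params@maxSteps, params@convTol,
                               params@emaAlpha, as.numeric(params@gains)))
  } else {
    state <- devInitialState(n)
    converged <- FALSE
    for (s in seq_len(params@maxSteps)) {
      state <- devStep(state, genome, cue, model, params)
      if (sum(state$v) < params@convTol) {
        converged <- TRUE
        break
      }
    }
    new("DevOutcome", adult = state$pEma, nSteps = state$step,
        converged = converged)
  }
}

.outcomeFromCpp <- function(res) {
  new("DevOutcome", adult = res$adult, nSteps = as.integer(res$nSteps),
      converged = res$converged)
}

## batch development on fast genomes; cues is an n x N matrix or NULL
.developPopulationFast <- function(fasts, cues, model, params) {
  n <- fasts[[1L]]$n
  useCue <- model == "full"
  if (useCue && (is.null(cues) || ncol(cues) != length(fasts)))
    stop("full model needs one cue per genome")
  if (!useCue) cues <- matrix(numeric(0), nrow = n, ncol = 0)
  cppDevelopPopulation(fasts, n, cues, useCue,
                       params@maxSteps, params@convTol, params@emaAlpha,
                       as.numeric(params@gains))
}
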