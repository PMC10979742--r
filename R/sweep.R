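#' @include AllClasses.R analysis.R evolution.R
NULL

#' Sweep the magnitude of environmental change
#'
#' Emulates the "first generation after an environmental change" measurement
#' across a grid of change magnitudes.  For each magnitude and each
#' replicate, the adapted environment of an equilibrated population is
#' flipped by that magnitude (a fresh random flip set per replicate), every
#' individual develops once in the changed environment, and the following
#' statistics of the developed-but-unselected population are recorded:
#' mean and variance of the projected phenotype, first singular value, bias
#' proportion and alignment of both the phenotype-cue and phenotype-genome
#' cross-covariance matrices.
#'
#' The phenotype side of both cross-covariance matrices is restricted to the
#' selected traits; the cue side uses all cue elements and the genome side
#' the full vectorized genome.
#'
#' @param population list of [Genome-class] (an equilibrated population), or
#'   an [ExperimentResult-class] whose final population and final environment
#'   are used.
#' @param env the environment the population is adapted to (ignored when
#'   `population` is an [ExperimentResult-class]).
#' @param params an [EvolutionParams-class].
#' @param magnitudes numeric vector of flip fractions to test.
#' @param nReplicates replicates per magnitude (default 10).
#' @return data.frame, one row per magnitude x replicate, with columns
#'   `magnitude`, `replicate`, `projMean`, `projVar`, `s1PhenoCue`,
#'   `s1PhenoGeno`, `biasPhenoCue`, `biasPhenoGeno`, `alignPhenoCue`,
#'   `alignPhenoGeno`.  When a small random flip set misses the selected-trait
#'   window entirely, the change axis is zero and the projection and alignment
#'   columns of that replicate are `NA`.
#' @seealso [detectTransition()]
#' @export
transitionSweep <- function(population, env = NULL, params,
                            magnitudes = seq(0.05, 0.5, by = 0.05),
                            nReplicates = 10L) {
  if (is(population, "ExperimentResult")) {
    env <- population@finalEnv
    population <- population@finalGenomes
  }
  if (!is.list(population) || !length(population))
    stop("an equilibrated population (nonempty list of Genome) is required")
  if (is.null(env)) stop("the adapted environment is required")
  fasts <- lapply(population, function(g)
    if (is(g, "Genome")) .genomeToFast(g) else g)
  N <- length(fasts)
  n <- params@nEnv
  k <- params@fitnessParams@nSelectedTraits
  dp <- params@devParams
  model <- params@model
  X <- .popMatrix(fasts)   # N x 6n^2, fixed across replicates

  rows <- list()
  for (mag in magnitudes) {
    for (rep in seq_len(nReplicates)) {
      eNov <- flipEnvironment(env, mag)
      ## a small flip set can miss the selected-trait window entirely; the
      ## change axis is then zero and frame-dependent statistics undefined
      degenerate <- all(eNov[seq_len(k)] == env[seq_len(k)])
      cues <- vapply(seq_len(N), function(q) generateCue(eNov, params@cueNoise),
                     numeric(n))
      dev <- .developPopulationFast(fasts,
                                    if (model == "full") cues else NULL,
                                    model, dp)
      adultsSel <- t(dev$adults[seq_len(k), , drop = FALSE])  # N x k
      proj <- .projPhenotypes(dev$adults, env, eNov, k)

      svdCue <- svdCrossCovariance(crossCovariance(adultsSel, t(cues)),
                                   method = "direct")
      svdGeno <- svdCrossCovariance(crossCovariance(adultsSel, X),
                                    method = "gram", right = FALSE)
      if (!degenerate) frame <- projectionFrame(env, eNov, k)
      rows[[length(rows) + 1L]] <- data.frame(
        magnitude = mag, replicate = rep,
        projMean = mean(proj),
        projVar = stats::var(proj),
        s1PhenoCue = svdCue@singularValues[1L],
        s1PhenoGeno = svdGeno@singularValues[1L],
        biasPhenoCue = biasProportion(svdCue),
        biasPhenoGeno = biasProportion(svdGeno),
        alignPhenoCue = if (degenerate) NA_real_ else alignment(svdCue, frame),
        alignPhenoGeno = if (degenerate) NA_real_ else alignment(svdGeno, frame))
    }
  }
  do.call(rbind, rows)
}

#' Locate the onset magnitude of a sweep statistic
#'
#' Flags the smallest magnitude whose per-magnitude median of `stat` exceeds
#' a configurable multiple of the baseline median (the median at the smallest
#' magnitude in the table).  This turns the visual "the statistic jumps
#' around here" reading of a sweep into a reproducible number.
#'
#' @param sweep a sweep table from [transitionSweep()].
#' @param stat column name of the statistic (e.g. `"projMean"`,
#'   `"s1PhenoCue"`).
#' @param multiple jump threshold as a multiple of the baseline median
#'   (default 3).
#' @return the detected magnitude, or `NA` if no magnitude exceeds the
#'   threshold.
#' @export
detectTransition <- function(sweep, stat, multiple = 3) {
  if (!stat %in% names(sweep)) stop("unknown statistic: ", stat)
  med <- vapply(split(sweep[[stat]], sweep$magnitude), stats::median,
                numeric(1), na.rm = TRUE)
  mags <- as.numeric(names(med))
  o <- order(mags)
  mags <- mags[o]; med <- med[o]
  thr <- multiple * abs(med[1L])
  hit <- which(med > thr)
  if (!length(hit)) NA_real_ else mags[hit[1L]]
}
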