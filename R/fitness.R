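#' @include AllClasses.R
NULL

#' Raw log-fitness of an individual
#'
#' The raw fitness of a converged individual is
#' `exp(-(alphaSel * L1 + betaStep * nSteps))`, where `L1` is the mismatch of
#' the adult phenotype to the environment over the first `nSelectedTraits`
#' traits (the remaining traits evolve freely) and `nSteps` is the number of
#' developmental steps, so faster development is favored.  Because
#' `alphaSel * L1` can reach the thousands, fitness is computed and stored in
#' log space, never exponentiated raw.  Individuals whose development did not
#' converge get zero fitness, i.e. `-Inf`.
#'
#' @param adult adult phenotype vector.
#' @param env the selective environment (+1/-1 vector).
#' @param nSteps number of developmental steps.
#' @param converged logical convergence flag.
#' @param params a [FitnessParams-class].
#' @return a finite log-fitness or `-Inf`.
#' @examples
#' e <- rep(1, 200)
#' rawLogFitness(e, e, nSteps = 10, converged = TRUE)  # -0.5
#' @export
rawLogFitness <- function(adult, env, nSteps, converged,
                          params = fitnessParams()) {
  k <- params@nSelectedTraits
  if (length(adult) < k || length(env) < k)
    stop("adult and env must have at least nSelectedTraits elements")
  if (!converged) return(-Inf)
  L1 <- sum(abs(adult[seq_len(k)] - env[seq_len(k)]))
  -(params@alphaSel * L1 + params@betaStep * nSteps)
}

## vectorized version over a developed population (adults: n x N)
.logFitnessPopulation <- function(adults, nSteps, converged, env, params) {
  k <- params@nSelectedTraits
  L1 <- colSums(abs(adults[seq_len(k), , drop = FALSE] - env[seq_len(k)]))
  lw <- -(params@alphaSel * L1 + params@betaStep * nSteps)
  lw[!converged] <- -Inf
  lw
}

#' Normalize log-fitness values to selection probabilities
#'
#' Divides every raw fitness by the population maximum, in log space via
#' max-subtraction: `Omega_i = exp(lw_i - max_j lw_j)`.  The fittest
#' individual gets exactly 1 and `-Inf` maps to 0, so the result is invariant
#' under any constant shift of the log-fitness values and never overflows.
#'
#' @param logW numeric vector of log-fitness values (`-Inf` allowed).
#' @return numeric vector in \[0, 1\] with maximum exactly 1.
#' @export
normalizeFitness <- function(logW) {
  if (!length(logW)) stop("empty fitness vector")
  mx <- max(logW)
  if (!is.finite(mx))
    stop(errorCondition(
      "population extinction: no individual completed development",
      class = "grnevoExtinction"))
  exp(logW - mx)
}

#' Sample parent pairs by roulette-wheel selection
#'
#' Acceptance-rejection sampling with replacement: a uniformly chosen
#' individual is accepted with probability equal to its normalized fitness,
#' until `2 * nPairs` acceptances have been made; consecutive acceptances form
#' pairs.  An individual may be sampled repeatedly (and may pair with
#' itself).
#'
#' @param omega normalized fitness values in \[0, 1\] (see
#'   [normalizeFitness()]).
#' @param nPairs number of parent pairs to draw.
#' @return integer matrix with `nPairs` rows and two columns of parent
#'   indices.
#' @export
selectParents <- function(omega, nPairs) {
  if (nPairs < 1L) stop("nPairs must be >= 1")
  if (all(omega <= 0))
    stop(errorCondition("population extinction: all selection probabilities are zero",
                        class = "grnevoExtinction"))
  N <- length(omega)
  need <- 2L * nPairs
  acc <- integer(0)
  batch <- max(256L, 2L * need)
  while (length(acc) < need) {
    idx <- sample.int(N, batch, replace = TRUE)
    ok <- stats::runif(batch) < omega[idx]
    acc <- c(acc, idx[ok])
  }
  matrix(acc[seq_len(need)], ncol = 2L, byrow = TRUE)
}
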