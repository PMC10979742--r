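#' Random macro-environment vector
#'
#' The selective environment is a vector of +1/-1 values of length `nEnv`.
#' It doubles as the optimal phenotype (environment-as-selector) and as the
#' source of each individual's developmental cue (environment-as-inducer).
#' Each element is drawn independently with equal probability of +1 and -1.
#'
#' @param nEnv positive integer, environment dimension (default 200).
#' @return integer-valued numeric vector of +1/-1 of length `nEnv`.
#' @examples
#' set.seed(1)
#' e <- newEnvironment(200)
#' table(e)
#' @export
newEnvironment <- function(nEnv = 200L) {
  if (length(nEnv) != 1L || is.na(nEnv) || nEnv < 1)
    stop("nEnv must be a positive integer")
  sample(c(-1, 1), as.integer(nEnv), replace = TRUE)
}

.checkEnv <- function(env, arg = "env") {
  if (!is.numeric(env) || length(env) < 1L || !all(abs(env) == 1))
    stop(sprintf("%s must be a vector of +1/-1 values", arg))
  invisible(env)
}

#' Flip a fixed fraction of an environment vector
#'
#' Inverts the sign of exactly `round(fraction * length(env))` distinct
#' elements, chosen uniformly without replacement (ties in the rounding go
#' half away from zero).  The exact flip count makes the correlation between
#' the old and new environments a deterministic function of the fraction:
#' `envCorrelation(e, flipEnvironment(e, f)) == 1 - 2 * k / n` with
#' `k = round(f * n)`.  Flipping 50% of the elements therefore yields
#' correlation 0, and flipping 90% yields -0.8.
#'
#' @param env a +1/-1 environment vector.
#' @param fraction fraction of elements to flip, in \[0, 1\].
#' @return a new environment vector; the input is not modified.
#' @examples
#' set.seed(1)
#' e <- newEnvironment(200)
#' envCorrelation(e, flipEnvironment(e, 0.5)) # exactly 0
#' @export
flipEnvironment <- function(env, fraction) {
  .checkEnv(env)
  if (length(fraction) != 1L || is.na(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]")
  n <- length(env)
  k <- .roundHalfAway(fraction * n)
  if (k > 0L) {
    idx <- sample.int(n, k)
    env[idx] <- -env[idx]
  }
  env
}

## round half away from zero (documented tie-break; base round() is banker's)
.roundHalfAway <- function(x) as.integer(floor(x + 0.5))

#' Derive a noisy environmental cue
#'
#' An individual's cue is the macro-environment with exactly
#' `round(noiseFraction * length(env))` randomly chosen elements flipped,
#' modeling micro-environmental noise experienced during development.  A fresh
#' flip set is drawn at every call, so every individual (and every generation)
#' receives an independent cue.
#'
#' @param env a +1/-1 environment vector.
#' @param noiseFraction fraction of elements flipped (default 0.05).
#' @return a +1/-1 cue vector of the same length.
#' @export
generateCue <- function(env, noiseFraction = 0.05) {
  flipEnvironment(env, noiseFraction)
}

#' Correlation between two environment vectors
#'
#' The normalized inner product `sum(e1 * e2) / length(e1)`.  For +1/-1
#' vectors with element means near zero this equals the Pearson correlation;
#' for a pair differing in exactly `k` positions it equals `1 - 2 * k / n`
#' exactly.
#'
#' @param e1,e2 +1/-1 environment vectors of equal length.
#' @return a number in \[-1, 1\].
#' @export
envCorrelation <- function(e1, e2) {
  .checkEnv(e1, "e1"); .checkEnv(e2, "e2")
  if (length(e1) != length(e2))
    stop("environment vectors must have equal length")
  sum(e1 * e2) / length(e1)
}

#' Write / read an environment vector as one-row CSV
#'
#' @param env a +1/-1 environment vector.
#' @param path file path.
#' @return `writeEnvironmentCsv` returns `path` invisibly;
#'   `readEnvironmentCsv` returns the environment vector.
#' @export
writeEnvironmentCsv <- function(env, path) {
  .checkEnv(env)
  writeLines(paste(as.integer(env), collapse = ","), path)
  invisible(path)
}

#' @rdname writeEnvironmentCsv
#' @export
readEnvironmentCsv <- function(path) {
  as.numeric(strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]])
}
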