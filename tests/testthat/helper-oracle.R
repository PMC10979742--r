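# Independent plain-loop oracle for the developmental recursion.
# Written directly from the model equations with dense matrices and explicit
# loops; shares no code with the package's compiled or Matrix-based paths.

denseGenome <- function(genome) {
  lapply(c(E = "E", F = "F", G = "G", H = "H", J = "J", P = "P"),
         function(m) as.matrix(methods::slot(genome, m)))
}

oracleMatVec <- function(M, v) {
  n <- nrow(M)
  out <- numeric(n)
  for (ii in seq_len(n)) {
    s <- 0
    for (jj in seq_len(ncol(M))) s <- s + M[ii, jj] * v[jj]
    out[ii] <- s
  }
  out
}

oracleSigma <- function(x, gain) (2 / pi) * atan(gain * x)

# Runs the recursion for exactly `steps` steps (no early stop) and returns
# the full state trajectory; or stops at convergence when tol is given.
oracleDevelop <- function(genome, cue = NULL, steps = 50,
                          alpha = 1 / 3, gains = c(0.5, 0.5, 0.5, 0.5),
                          tol = NULL) {
  M <- denseGenome(genome)
  n <- nrow(M$E)
  f <- numeric(n); g <- rep(1, n); h <- numeric(n); p <- numeric(n)
  pt <- numeric(n); v <- rep(1, n)
  nocue <- is.null(cue)
  converged <- FALSE
  sdone <- steps
  for (s in seq_len(steps)) {
    cin <- if (nocue) -pt else cue - pt
    f <- oracleSigma(oracleMatVec(M$G, g) + oracleMatVec(M$E, cin), gains[1])
    g <- oracleSigma(oracleMatVec(M$F, f), gains[2])
    h <- oracleSigma(oracleMatVec(M$H, g) + oracleMatVec(M$J, h), gains[3])
    p <- tanh(gains[4] * oracleMatVec(M$P, h))
    v <- (1 - alpha) * (v + alpha * (pt - p)^2)
    pt <- alpha * p + (1 - alpha) * pt
    if (!is.null(tol) && sum(v) < tol) {
      converged <- TRUE
      sdone <- s
      break
    }
  }
  list(f = f, g = g, h = h, p = p, pEma = pt, v = v, nSteps = sdone,
       converged = converged)
}
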