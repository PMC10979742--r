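#' @include AllClasses.R genome.R
NULL

#' Mismatch between an adult phenotype and the environment
#'
#' The L1 distance between the adult phenotype and the selective environment
#' over the first `nSelected` traits (the traits under selection).  Because
#' expressed phenotypes lie strictly inside (-1, 1) while environments are
#' +1/-1, the mismatch is always strictly positive for developed phenotypes.
#'
#' @param adult adult phenotype vector.
#' @param env +1/-1 environment vector.
#' @param nSelected number of leading traits compared (default 40).
#' @return a nonnegative number.
#' @export
mismatch <- function(adult, env, nSelected = 40L) {
  if (length(adult) < nSelected || length(env) < nSelected)
    stop("adult and env must have at least nSelected elements")
  sel <- seq_len(nSelected)
  sum(abs(adult[sel] - env[sel]))
}

#' Build a projection frame
#'
#' The phenotype axis joins the selected-trait restrictions of the ancestral
#' and novel environments, so projected phenotypes of 0 and 1 correspond to
#' perfect adaptation to the ancestral and novel environment respectively.
#' The genotype axis joins the population-mean vectorized genomes at the
#' first and last generation of an epoch.
#'
#' @param envAncestral,envNovel +1/-1 environment vectors.
#' @param nSelected number of selected traits (default 40).
#' @param genoOrigin,genoEnd optional mean vectorized genomes at the first
#'   and last generation of the epoch (needed for [projectGenotype()]).
#' @return a [ProjectionFrame-class].
#' @export
projectionFrame <- function(envAncestral, envNovel, nSelected = 40L,
                            genoOrigin = NULL, genoEnd = NULL) {
  sel <- seq_len(nSelected)
  new("ProjectionFrame",
      eAncSel = as.numeric(envAncestral[sel]),
      eNovSel = as.numeric(envNovel[sel]),
      genoOrigin = genoOrigin, genoEnd = genoEnd)
}

#' Project a phenotype onto the environmental-change axis
#'
#' Computes `(adult_sel - eAnc) . (eNov - eAnc) / ||eNov - eAnc||^2` over the
#' selected traits.  Values of 0 and 1 correspond to phenotypes perfectly
#' adapted to the ancestral and novel environments.
#'
#' @param adult adult phenotype vector (full length; only the selected traits
#'   are used).
#' @param frame a [ProjectionFrame-class].
#' @return a real number.
#' @export
projectPhenotype <- function(adult, frame) {
  d <- frame@eNovSel - frame@eAncSel
  den <- sum(d * d)
  if (den == 0)
    stop("degenerate frame: novel and ancestral environments coincide on the selected traits")
  k <- length(d)
  sum((adult[seq_len(k)] - frame@eAncSel) * d) / den
}

#' Project a vectorized genome onto the evolution axis
#'
#' Computes `(g - gOrigin) . (gEnd - gOrigin) / ||gEnd - gOrigin||^2`.
#' Values of 0 and 1 correspond to the population-average genotypes before
#' and after one epoch of evolution in the novel environment.
#'
#' @param genomeVec vectorized genome (see [vectorizeGenome()]).
#' @param frame a [ProjectionFrame-class] with genotype anchors.
#' @return a real number.
#' @export
projectGenotype <- function(genomeVec, frame) {
  if (is.null(frame@genoOrigin))
    stop("frame has no genotype anchors")
  axis <- frame@genoEnd - frame@genoOrigin
  den <- sum(axis * axis)
  if (den == 0)
    stop("degenerate frame: genotype anchors coincide (no evolution this epoch)")
  sum((genomeVec - frame@genoOrigin) * axis) / den
}

#' Cross-covariance between phenotypes and a covariate block
#'
#' The phenotype-cue or phenotype-genome cross-covariance matrix
#' `C[i, j] = (1/N) * sum_k (p[k, i] - pbar[i]) * (x[k, j] - xbar[j])`,
#' centered on both sides, divisor `N`.  Rows of both inputs are
#' individuals.
#'
#' @param phenos `N x T` numeric matrix of (selected-trait) adult phenotypes.
#' @param covars `N x M` matrix of covariates: cue elements or vectorized
#'   genomes; may be sparse (`Matrix`).
#' @return a dense `T x M` matrix.
#' @export
crossCovariance <- function(phenos, covars) {
  N <- nrow(phenos)
  if (is.null(N) || N < 2L || nrow(covars) != N)
    stop("phenos and covars need the same N >= 2 rows")
  pc <- sweep(phenos, 2L, colMeans(phenos))
  xbar <- as.numeric(Matrix::colMeans(covars))
  ## (1/N) t(Pc) X - 0 * xbar: Pc is centered, so t(Pc) %*% 1 xbar' vanishes
  C <- as.matrix(Matrix::crossprod(pc, covars)) / N
  C - outer(colMeans(pc), xbar)
}

#' Singular value decomposition of a cross-covariance matrix
#'
#' Full SVD with singular values in nonincreasing order.  For wide matrices
#' (the phenotype-genome case, where the covariate side has `6 n^2` columns)
#' the decomposition is computed economically from the Gram matrix
#' `C C^T` on the small phenotype side, which yields identical singular
#' values and left vectors; right singular vectors are then recovered only on
#' request.  Left singular vectors are sign-fixed so that their first nonzero
#' component is nonnegative.
#'
#' @param C numeric matrix (finite).
#' @param method `"auto"` (Gram path when `ncol > 4 * nrow`), `"direct"`, or
#'   `"gram"`.
#' @param right logical, return right singular vectors (default TRUE for the
#'   direct path; set FALSE to skip the expensive back-computation on the
#'   Gram path).
#' @return a [CrossCovSVD-class].
#' @export
svdCrossCovariance <- function(C, method = c("auto", "direct", "gram"),
                               right = TRUE) {
  method <- match.arg(method)
  if (!all(is.finite(C))) stop("C must be finite")
  C <- as.matrix(C)
  if (method == "auto")
    method <- if (ncol(C) > 4L * nrow(C)) "gram" else "direct"
  if (method == "direct") {
    s <- svd(C)
    d <- s$d
    u <- s$u
    v <- s$v
  } else {
    gram <- tcrossprod(C)
    eg <- eigen(gram, symmetric = TRUE)
    d <- sqrt(pmax(eg$values, 0))
    u <- eg$vectors
    v <- NULL
    if (right) {
      pos <- d > max(d[1L], .Machine$double.eps) * 1e-12
      v <- crossprod(C, u[, pos, drop = FALSE])
      v <- sweep(v, 2L, d[pos], "/")
    }
  }
  ## sign convention: first nonzero component of each left vector nonnegative
  for (q in seq_along(d)) {
    col <- u[, q]
    nz <- which(col != 0)
    if (length(nz) && col[nz[1L]] < 0) {
      u[, q] <- -col
      if (!is.null(v) && q <= ncol(v)) v[, q] <- -v[, q]
    }
  }
  new("CrossCovSVD", singularValues = d, left = u,
      right = if (is.null(v)) matrix(numeric(0), nrow = ncol(C), ncol = 0) else v,
      totalSq = sum(d^2))
}

#' Developmental-bias proportion
#'
#' The proportion of the squared first singular value in the total squared
#' cross-covariance, `sigma1^2 / sum(sigma^2)`.  A value of 1 means the
#' entire cross-covariance is carried by a single phenotype direction
#' (maximal bias); `1/k` for `k` equal singular values means no bias.
#'
#' @param sv a [CrossCovSVD-class] or a numeric vector of singular values.
#' @return a number in (0, 1\].
#' @export
biasProportion <- function(sv) {
  d <- if (is(sv, "CrossCovSVD")) sv@singularValues else sv
  tot <- sum(d^2)
  if (tot == 0) stop("bias proportion undefined: all singular values are zero")
  d[1L]^2 / tot
}

#' Alignment of the leading phenotype axis with the environmental change
#'
#' The magnitude of the normalized dot product between the first left
#' singular vector of a cross-covariance matrix and the environmental-change
#' vector `eNov - eAnc` over the selected traits:
#' `|u1 . (eNov - eAnc)| / ||eNov - eAnc||`.  1 means the leading axis of
#' phenotypic variation points along the environmental change; 0 means it is
#' orthogonal.  The singular-vector sign ambiguity is irrelevant by the
#' absolute value.
#'
#' @param u1 unit-norm first left singular vector (or a [CrossCovSVD-class],
#'   from which it is taken).
#' @param frame a [ProjectionFrame-class].
#' @return a number in \[0, 1\].
#' @export
alignment <- function(u1, frame) {
  if (is(u1, "CrossCovSVD")) u1 <- u1@left[, 1L]
  d <- frame@eNovSel - frame@eAncSel
  nrm <- sqrt(sum(d * d))
  if (nrm == 0) stop("degenerate frame: zero environmental change")
  if (length(u1) != length(d))
    stop("u1 must have the selected-trait length")
  abs(sum(u1 * d)) / nrm
}
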