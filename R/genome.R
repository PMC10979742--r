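#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Internal fast genome representation
##
## The GA's inner loop (crossover, mutation, development) works on a compact
## triplet form: one set of parallel vectors over all six matrices with
##   m : matrix id (1=E, 2=F, 3=G, 4=H, 5=J, 6=P)
##   i : row (1..n),  j : column (1..n),  x : value,  n : dimension.
## Genome S4 objects are built only at API boundaries.
## ---------------------------------------------------------------------------

.fastGenome <- function(m, i, j, x, n) {
  list(m = as.integer(m), i = as.integer(i), j = as.integer(j),
       x = as.numeric(x), n = as.integer(n))
}

.genomeToFast <- function(genome) {
  n <- genomeSize(genome)
  parts <- lapply(seq_along(GENOME_MATRICES), function(k) {
    M <- slot(genome, GENOME_MATRICES[k])
    list(m = rep.int(k, length(M@x)), i = M@i + 1L,
         j = rep(seq_len(n), diff(M@p)), x = M@x)
  })
  .fastGenome(unlist(lapply(parts, `[[`, "m")),
              unlist(lapply(parts, `[[`, "i")),
              unlist(lapply(parts, `[[`, "j")),
              unlist(lapply(parts, `[[`, "x")), n)
}

.fastToGenome <- function(fast) {
  n <- fast$n
  mats <- lapply(seq_along(GENOME_MATRICES), function(k) {
    sel <- fast$m == k
    Matrix::sparseMatrix(i = fast$i[sel], j = fast$j[sel], x = fast$x[sel],
                         dims = c(n, n))
  })
  names(mats) <- GENOME_MATRICES
  new("Genome", E = mats$E, F = mats$F, G = mats$G,
      H = mats$H, J = mats$J, P = mats$P)
}

## linear index of an entry within the concatenated row-major genome vector
.fastLinearIndex <- function(fast) {
  n <- fast$n
  (fast$m - 1L) * n * n + (fast$i - 1L) * n + fast$j
}

.sampleValues <- function(k, spec) {
  if (k == 0L) return(numeric(0))
  switch(spec@values,
         pm1 = sample(c(-1, 1), k, replace = TRUE),
         gaussian = stats::rnorm(k))
}

## ---------------------------------------------------------------------------
## Public genome operations
## ---------------------------------------------------------------------------

#' Random sparse genome
#'
#' Creates a genome whose six matrices each contain exactly
#' `round(density * n^2)` nonzero entries at uniformly chosen positions, with
#' values drawn from the spec's value distribution (+1/-1 with equal
#' probability by default).
#'
#' @param spec a [GenomeSpec-class].
#' @return a [Genome-class].
#' @examples
#' set.seed(1)
#' g <- randomGenome(genomeSpec(n = 10, density = 0.1))
#' g
#' @export
randomGenome <- function(spec = genomeSpec()) {
  stopifnot(is(spec, "GenomeSpec"))
  validObject(spec)
  .fastToGenome(.randomFast(spec))
}

.randomFast <- function(spec) {
  n <- spec@n
  nnz <- .roundHalfAway(spec@density * n * n)
  if (nnz < 1L) stop("density too small: no nonzero entries at this n")
  parts <- lapply(1:6, function(k) {
    pos <- sample.int(n * n, nnz)
    list(m = rep.int(k, nnz),
         i = ((pos - 1L) %/% n) + 1L,
         j = ((pos - 1L) %% n) + 1L,
         x = .sampleValues(nnz, spec))
  })
  .fastGenome(unlist(lapply(parts, `[[`, "m")),
              unlist(lapply(parts, `[[`, "i")),
              unlist(lapply(parts, `[[`, "j")),
              unlist(lapply(parts, `[[`, "x")), n)
}

## mutation on the fast representation; used directly by the GA loop
.mutateFast <- function(fast, rate, spec) {
  if (rate == 0) return(fast)
  n <- fast$n
  nsq <- n * n
  ## independent per-element selection over all 6 n^2 positions in one draw
  nSel <- stats::rbinom(1L, 6L * nsq, rate)
  if (nSel == 0L) return(fast)
  pos <- sample.int(6L * nsq, nSel)
  key <- (fast$m - 1L) * nsq + (fast$i - 1L) * n + fast$j
  keep <- !(key %in% pos)
  ## resample each selected element from the marginal element distribution:
  ## zero with probability 1 - density, otherwise a fresh nonzero value
  pnz <- pos[stats::runif(nSel) < spec@density]
  pos0 <- pnz - 1L
  r <- pos0 %% nsq
  list(m = c(fast$m[keep], pos0 %/% nsq + 1L),
       i = c(fast$i[keep], r %/% n + 1L),
       j = c(fast$j[keep], r %% n + 1L),
       x = c(fast$x[keep], .sampleValues(length(pnz), spec)),
       n = n)
}

#' Mutate a genome
#'
#' Every element of every matrix (zeros included) is independently selected
#' with probability `rate`; a selected element is resampled from the marginal
#' element distribution of the spec — zero with probability `1 - density`,
#' otherwise a fresh value from the value distribution.  This is the unique
#' per-element resampling scheme whose stationary distribution preserves the
#' matrix density in expectation.
#'
#' @param genome a [Genome-class].
#' @param rate per-element mutation probability in \[0, 1\] (default 0.005).
#' @param spec the population's [GenomeSpec-class].
#' @return a new mutated [Genome-class].
#' @export
mutateGenome <- function(genome, rate = 0.005, spec = genomeSpec(n = genomeSize(genome))) {
  stopifnot(is(genome, "Genome"))
  if (length(rate) != 1L || is.na(rate) || rate < 0 || rate > 1)
    stop("rate must be in [0, 1]")
  if (rate == 0) return(genome)
  .fastToGenome(.mutateFast(.genomeToFast(genome), rate, spec))
}

## crossover on the fast representation
.crossoverFast <- function(fa, fb) {
  n <- fa$n
  swap <- stats::runif(n) < 0.5
  selA <- swap[fa$i]   # entries of parent a whose row moves to offspring 2
  selB <- swap[fb$i]
  off1 <- .fastGenome(c(fa$m[!selA], fb$m[selB]), c(fa$i[!selA], fb$i[selB]),
                      c(fa$j[!selA], fb$j[selB]), c(fa$x[!selA], fb$x[selB]), n)
  off2 <- .fastGenome(c(fb$m[!selB], fa$m[selA]), c(fb$i[!selB], fa$i[selA]),
                      c(fb$j[!selB], fa$j[selA]), c(fb$x[!selB], fa$x[selA]), n)
  list(off1, off2)
}

#' Recombine two genomes by row-block exchange
#'
#' For each row index `i`, with probability 1/2 the `i`-th rows of all six
#' matrices are exchanged between the two offspring.  A row thus travels as
#' one linkage block (a gene's entire incoming regulation), and the union of
#' the offspring's rows equals the union of the parents' rows exactly.
#'
#' @param parentA,parentB two [Genome-class] objects of identical dimension.
#' @return list of two offspring [Genome-class] objects.
#' @export
crossoverGenomes <- function(parentA, parentB) {
  stopifnot(is(parentA, "Genome"), is(parentB, "Genome"))
  if (genomeSize(parentA) != genomeSize(parentB))
    stop("parents must have identical genome dimensions")
  off <- .crossoverFast(.genomeToFast(parentA), .genomeToFast(parentB))
  list(.fastToGenome(off[[1L]]), .fastToGenome(off[[2L]]))
}

#' Flatten a genome to a vector
#'
#' Concatenates the six matrices in the fixed order E, F, G, H, J, P, each
#' flattened row-major, giving a dense vector of length `6 * n^2`.  The
#' mapping is invertible via [devectorizeGenome()].
#'
#' @param genome a [Genome-class].
#' @return numeric vector of length `6 * genomeSize(genome)^2`.
#' @export
vectorizeGenome <- function(genome) {
  stopifnot(is(genome, "Genome"))
  fast <- .genomeToFast(genome)
  n <- fast$n
  v <- numeric(6L * n * n)
  v[.fastLinearIndex(fast)] <- fast$x
  v
}

#' @rdname vectorizeGenome
#' @param v numeric vector of length `6 * n^2`.
#' @param n genome dimension.
#' @export
devectorizeGenome <- function(v, n) {
  n <- as.integer(n)
  if (length(v) != 6L * n * n)
    stop("v must have length 6 * n^2")
  idx <- which(v != 0)
  idx0 <- idx - 1L
  m <- idx0 %/% (n * n)
  r <- idx0 %% (n * n)
  .fastToGenome(.fastGenome(m + 1L, (r %/% n) + 1L, (r %% n) + 1L, v[idx], n))
}

#' Population genetic variance
#'
#' The sum, over all `6 * n^2` genome-element positions, of the
#' across-population variance of that element (population variance,
#' divisor `N`).  Equivalent to the summed elementwise variance of the
#' vectorized genomes.
#'
#' @param genomes nonempty list of [Genome-class] objects of equal dimension.
#' @return a nonnegative number.
#' @export
populationGeneticVariance <- function(genomes) {
  if (!is.list(genomes) || length(genomes) == 0L)
    stop("genomes must be a nonempty list")
  fasts <- lapply(genomes, function(g) {
    if (is(g, "Genome")) .genomeToFast(g) else g
  })
  .geneticVarianceFast(fasts)
}

.geneticVarianceFast <- function(fasts) {
  n <- fasts[[1L]]$n
  if (!all(vapply(fasts, `[[`, integer(1), "n") == n))
    stop("all genomes must share the same dimension")
  N <- length(fasts)
  sums <- numeric(6L * n * n)
  sumsq <- 0
  for (f in fasts) {
    idx <- .fastLinearIndex(f)
    sums[idx] <- sums[idx] + f$x
    sumsq <- sumsq + sum(f$x^2)
  }
  sumsq / N - sum((sums / N)^2)
}

## sparse population-by-genome-element matrix (rows: individuals)
.popMatrix <- function(fasts) {
  n <- fasts[[1L]]$n
  N <- length(fasts)
  nnz <- vapply(fasts, function(f) length(f$x), integer(1))
  Matrix::sparseMatrix(
    i = rep.int(seq_len(N), nnz),
    j = unlist(lapply(fasts, .fastLinearIndex)),
    x = unlist(lapply(fasts, `[[`, "x")),
    dims = c(N, 6L * n * n))
}

## ---------------------------------------------------------------------------
## Genome serialization: sparse triplet text format
## ---------------------------------------------------------------------------

#' Write / read a genome in sparse triplet text form
#'
#' One TSV row per nonzero entry with columns `matrix` (E/F/G/H/J/P), `row`,
#' `col`, `value`; a header comment line carries the dimension.
#'
#' @param genome a [Genome-class].
#' @param path file path.
#' @return `writeGenomeTsv` returns `path` invisibly; `readGenomeTsv` returns
#'   the [Genome-class].
#' @export
writeGenomeTsv <- function(genome, path) {
  stopifnot(is(genome, "Genome"))
  fast <- .genomeToFast(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grnevo genome n=%d", fast$n), con)
  writeLines("matrix\trow\tcol\tvalue", con)
  writeLines(sprintf("%s\t%d\t%d\t%.17g",
                     GENOME_MATRICES[fast$m], fast$i, fast$j, fast$x), con)
  invisible(path)
}

#' @rdname writeGenomeTsv
#' @export
readGenomeTsv <- function(path) {
  header <- readLines(path, n = 1L)
  n <- as.integer(sub("^# grnevo genome n=", "", header))
  if (is.na(n)) stop("not a grnevo genome triplet file: ", path)
  df <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  m <- match(df$matrix, GENOME_MATRICES)
  if (anyNA(m)) stop("unknown matrix label in ", path)
  .fastToGenome(.fastGenome(m, df$row, df$col, df$value, n))
}
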