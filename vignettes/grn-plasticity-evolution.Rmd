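---
title: "Modeling plasticity-led and mutation-led adaptation with hierarchical developmental GRNs"
author: "grnevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling plasticity-led and mutation-led adaptation with hierarchical developmental GRNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`grnevo` simulates the evolution of populations of *hierarchical
developmental gene regulatory networks* (GRNs) under environmental change.
The question it addresses is when adaptation is *plasticity-led* (a new
environment induces adaptive phenotypes during development, which selection
then stabilizes genetically) and when it is *mutation-led* (adaptation waits
for mutations that produce the new phenotype).

### Environment

The selective environment is a vector $\mathbf{e} \in \{+1,-1\}^{200}$.  It
plays two roles: it is the optimal phenotype against which fitness is scored
(environment as selector), and it is the source of each individual's
developmental cue (environment as inducer).  A cue is $\mathbf{e}$ with
exactly 5% of its elements flipped at random, freshly drawn for every
individual in every generation — micro-environmental noise during
development.  Environmental *change* is modeled by flipping a chosen
fraction of $\mathbf{e}$'s elements.  Because flip counts are exact
(`round(fraction * n)` positions without replacement, ties rounded half away
from zero), the correlation between the environments before and after a
change is the deterministic identity $1 - 2k/n$: flipping 50% gives
correlation 0, flipping 90% gives $-0.8$.

### Genome and development

An individual's genome is six sparse $200 \times 200$ interaction matrices
$E, F, G, H, J, P$, each with a nonzero density of 0.02.  Development is the
mutually recursive dynamical system

$$
\begin{aligned}
f(s) &= \sigma_f\!\big(G\,g(s-1) + E\,(e - \tilde p(s-1))\big) \\
g(s) &= \sigma_g\!\big(F\,f(s)\big) \\
h(s) &= \sigma_h\!\big(H\,g(s) + J\,h(s-1)\big) \\
p(s) &= \sigma_p\!\big(P\,h(s)\big) \\
\tilde p(s) &= \alpha\, p(s) + (1-\alpha)\, \tilde p(s-1) \\
v_i(s) &= (1-\alpha)\big\{ v_i(s-1) + \alpha\,[\tilde p_i(s-1) - p_i(s)]^2 \big\}
\end{aligned}
$$

with layers representing epigenetic marks ($f$), gene expression ($g$),
higher-order complexes ($h$) and the expressed phenotype ($p$);
$\tilde p$ is an exponential moving average (EMA) of the phenotype and $v$
its per-trait EMA variance.  The **Full** model feeds the cue difference
$e - \tilde p$ into the epigenetic layer; the **NoCue** variant replaces it
with $-\tilde p$ and therefore cannot respond to the environment — it is the
mutation-led control.  Initial conditions are $f = 0$, $g = \mathbf 1$,
$h = 0$, $p = 0$.  Development stops when the total EMA variance
$\sum_i v_i(s)$ drops below $10^{-5}$ (convergence) or after 200 steps
(failure; such individuals get zero fitness).

The per-step evaluation order is exactly the dependency order of the
recursion: $f$ uses $g(s-1)$ and $\tilde p(s-1)$; $g$ uses the *current*
$f$; $h$ uses the current $g$ and previous $h$; $p$ uses the current $h$;
the EMA updates close the step, both reading $\tilde p(s-1)$.

### Numerical choices in the developmental layer

Several quantities of the developmental layer are structural choices of this
package:

* **Activation functions.** $\sigma_{f,g,h}(x) = \tfrac{2}{\pi}
  \arctan(\gamma x)$ and $\sigma_p(x) = \tanh(\gamma x)$ — odd, strictly
  monotone, bounded in $(-1, 1)$.
* **Activation gain $\gamma = 0.5$** (all layers, configurable per layer).
  The gain controls where the recursion sits between a weakly coupled,
  strongly contracting regime and a saturated, oscillatory one.  We measured
  convergence of randomly initialized genomes across gains: at $\gamma = 1$
  essentially no random NoCue genome reaches the $10^{-5}$ fixed-point
  criterion within 200 steps (0 of 200 tried; about 60% for the Full model),
  so a random founding population is extinct at the first generation and the
  protocol cannot start.  At $\gamma = 0.5$ random genomes of both variants
  converge reliably (100 of 100) while $\tanh$ can still drive phenotype
  components toward $\pm 1$, which adaptation requires.  We therefore fixed
  0.5 as the default before running any evolutionary experiment.
* **EMA weight $\alpha = 1/3$.**  A smooth adult phenotype read-out that
  still tracks the expressed phenotype within a few steps.  Note $\alpha$
  here is unrelated to the fitness weight below; the two are separate
  parameters (`emaAlpha` vs `alphaSel`).
* **Initial EMA variance $v(0) = 1$ per trait.**  With 200 traits decaying
  at factor $(1-\alpha) = 2/3$ per step, the convergence test cannot fire
  before ~42 steps.  This deliberate burn-in prevents spurious "instant
  convergence" and keeps the developmental step count informative as a
  fitness component.
* **Degenerate inputs.** A zero genome develops to the zero adult;
  non-convergence is a reported outcome, not an error; an all-nonconverged
  population raises a labeled extinction condition.

### Fitness and the genetic algorithm

Raw fitness is $\omega = \exp(-(\alpha_{\mathrm{sel}} \lVert \tilde p -
\mathbf e\rVert_1 + \beta N_{\mathrm{step}}))$ with
$\alpha_{\mathrm{sel}} = 20$, $\beta = 1/20$, where the L1 *mismatch* runs
over the first 40 of 200 traits only (the selected traits; the rest evolve
freely) and $N_{\mathrm{step}}$ is the developmental step count, so faster
developers are favored.  Since $\alpha_{\mathrm{sel}} \lVert\cdot\rVert_1$
can reach ~1600, all fitness arithmetic stays in log space; normalized
fitness $\Omega_i = \omega_i / \max_j \omega_j$ is computed by
max-subtraction and is exactly invariant under constant log shifts.
Non-converged individuals get $\Omega = 0$.

Each generation: every genome develops once with a cue from the novel
(selective) environment and once with a cue from the ancestral environment —
the ancestral copy is measured and discarded, selection sees only the novel
outcomes.  Parents are sampled by acceptance–rejection roulette (uniform
draw, accept with probability $\Omega_i$, consecutive acceptances pair up;
selfing is allowed).  Each pair produces two offspring by *row-block
crossover*: for each row index, with probability 1/2 that row of **all six**
matrices is exchanged — a gene's entire incoming regulation travels as one
linkage block.  Offspring matrices are then mutated element-wise: each of
the $6 n^2$ positions is independently selected with probability 0.005 and
resampled from the marginal element distribution (zero with probability
$1 - \mathrm{density}$, otherwise a fresh $\pm 1$).  This is the unique
per-element resampling scheme that preserves the expected density without
global renormalization.  Nonzero values are $\pm 1$ by default, matching
the discrete coding of the environment (a Gaussian alternative is
configurable).

An **epoch** is 200 generations under a constant environment.  An
experiment runs 40 *preparatory* epochs, each under a freshly drawn,
completely uncorrelated environment (to equilibrate the random founding
population and let the system learn to respond to change), followed by
production epochs, each preceded by flipping `envChangeFraction` of the
current environment.

### Analysis statistics

* **Projections.**  Phenotypes are projected onto the selected-trait axis
  from the ancestral to the novel environment, so 0/1 mean perfect
  adaptation to the ancestral/novel environment.  Genotypes (vectorized by
  concatenating the six matrices row-major, order E, F, G, H, J, P) are
  projected onto the axis joining the population-mean genomes of an epoch's
  first and last generation.  Both projections raise a labeled error on a
  degenerate (zero-length) axis.
* **Genetic variance.**  The sum over all $6 n^2$ genome positions of the
  across-population variance (divisor $N$).
* **Cross-covariances.**  The phenotype–cue and phenotype–genome
  cross-covariance matrices (divisor $N$, centered on both sides) take the
  selected 40 traits on the phenotype side — the alignment statistic dots
  their left singular vectors with the 40-dimensional environmental-change
  vector, which forces that choice — and all 200 cue elements or all
  $6 n^2$ genome elements on the other side.  Their SVD yields the
  developmental-bias proportion $\sigma_1^2 / \sum_i \sigma_i^2$ and the
  alignment $|u_1 \cdot (\mathbf e_n - \mathbf e_a)| / \lVert \mathbf e_n -
  \mathbf e_a \rVert$.  For the wide phenotype–genome case the SVD is
  computed from the $40 \times 40$ Gram matrix $CC^\top$, which gives
  identical singular values and left vectors at a fraction of the cost;
  left singular vectors are sign-fixed (first nonzero component
  nonnegative) for reproducible output.
* **Transition sweep.**  Starting from an equilibrated population adapted
  to environment $\mathbf e_a$, each replicate applies a fresh random flip
  of a given magnitude, develops the whole population once (first
  generation, before selection) and records eight statistics: mean and
  variance of projected phenotype, first singular values, bias proportions
  and alignments of both cross-covariances.  Replicate variation comes from
  the random flip sets and cues; the population itself is held fixed, since
  all quantities are defined at the first generation after the change.  A
  small flip can miss the selected-trait window entirely (10 flips among
  200 elements miss the first 40 about 11% of the time); such replicates
  record `NA` for the frame-dependent columns, and medians are taken with
  `na.rm`.  `detectTransition()` turns the visual "the curve jumps here"
  reading into a number: the smallest magnitude whose median statistic
  exceeds a configurable multiple (default 3) of the smallest-magnitude
  median.

## Scales, runtime and what the synthetic conditions do (and do not) show

The full-scale protocol (1000 individuals, 200 generations per epoch, 40
preparatory epochs) is what the model's headline numbers refer to: the
sharp rise of plastic response and phenotypic variance around 30%
environmental change, of the bias proportions around 25%, and the NoCue
model's 20–30-generation adaptation delay.  Those runs take hours.  The
`"desk"` preset (200 individuals, 50 generations per epoch, 3 preparatory
and 3 production epochs, identical model parameters) is the scale used by
the test suite and the acceptance script; one desk run takes on the order
of one to two minutes on a single core.

At desk scale the *qualitative* contrast survives and is what the tests
assert: under a 50% change the Full model's generation-1 phenotype cloud
sits measurably closer to the novel environment than its
ancestral-environment twin (adaptive plastic response), its mismatch
declines from the first generation, and large-change sweep statistics
dominate small-change baselines.  What desk scale does **not** reproduce:
precise transition locations, the NoCue delay-then-drop mismatch
trajectory (at this population size and epoch length NoCue adaptation is
too slow to measure — its trajectory is nearly flat), and equilibrated
levels of genetic variance.  Passing desk-scale tests therefore validates
mechanisms and implementations, not the full-scale quantitative claims.

The simulated data are idealized in ways real gene-regulatory data are
not: environments are balanced $\pm 1$ vectors with exactly correlated
selector and inducer roles, all matrices share one density, there is no
within-development stochasticity beyond the cue, and population size is
constant.  Conclusions about real regulatory networks require mapping
through those assumptions.

## Design choices where the design was open

* **Exact flip counts** rather than per-element Bernoulli flips make the
  printed correlation identities exact and testable.
* **Fresh cue per individual per generation** (not per epoch): the cue
  models developmental micro-noise, and the phenotype–cue covariance is
  only defined if cues vary within a generation.
* **Row linkage in crossover** interprets "corresponding rows" as one
  regulatory unit per gene across all six matrices; per-matrix independent
  swapping would break a gene's incoming regulation apart.
* **Acceptance–rejection roulette** realizes "sampled with probability
  $\Omega_i$, with replacement" exactly, without normalizing $\Omega$ into
  a distribution.
* **Preparatory environments** are independent uniform redraws (expected
  pairwise correlation 0).
* **NoCue's two developments coincide** (no cue input), so the
  ancestral-environment copy is computed once and reused; preparatory
  epochs skip the measurement-only ancestral development entirely.
* **Performance split.**  The developmental recursion and whole-generation
  reproduction run in compiled code over a compact sparse-triplet genome
  representation; the exported single-step (`devStep`) and single-genome
  (`crossoverGenomes`, `mutateGenome`) functions keep independent pure-R
  implementations, and the test suite checks both paths against a dense
  plain-loop oracle.

## Known limitations

* NoCue adaptation is not observable at desk scale (see above); full-scale
  runs are needed for every NoCue rate claim.
* The sweep holds the population fixed across replicates of a magnitude;
  it does not model re-adaptation between probes.
* Selection intensity interacts with the activation gain: gains well above
  0.5 reintroduce non-convergence and extinction, gains well below weaken
  the attainable phenotype amplitude; the default is a measured compromise,
  not a tuned optimum.

## A minimal session

```{r example}
library(grnevo)

params <- evolutionParams(preset = "desk", envChangeFraction = 0.5, seed = 1)
res <- runExperiment(params)
head(trajectory(res))

sw <- transitionSweep(res, params = params,
                      magnitudes = seq(0.05, 0.5, by = 0.15),
                      nReplicates = 5)
aggregate(cbind(projMean, s1PhenoCue) ~ magnitude, sw, median)
detectTransition(sw, "s1PhenoCue")
```
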