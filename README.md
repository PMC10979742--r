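# grnevo

Evolutionary simulation of hierarchical developmental gene regulatory
networks (GRNs), for studying when adaptation to environmental change is
**plasticity-led** (the new environment induces adaptive phenotypes during
development, which selection then stabilizes genetically) versus
**mutation-led** (adaptation waits for the right mutations).  The package is
aimed at evo-devo and theoretical-biology researchers who want a
reproducible, tested implementation of this model family to probe the
robust-to-plastic developmental transition.

## The model in brief

An individual's genome is six sparse `n × n` interaction matrices
`E, F, G, H, J, P` (`n = 200`, density 0.02, entries ±1).  Development is
the recursion

    f(s) = σ_f( G g(s−1) + E (e − p̃(s−1)) )      (epigenetic marks)
    g(s) = σ_g( F f(s) )                          (gene expression)
    h(s) = σ_h( H g(s) + J h(s−1) )               (higher-order complexes)
    p(s) = σ_p( P h(s) )                          (expressed phenotype)
    p̃(s) = α p(s) + (1−α) p̃(s−1)                 (adult read-out, EMA)
    v(s) = (1−α){ v(s−1) + α [p̃(s−1) − p(s)]² }   (EMA variance)

run until `Σ v_i < 1e-5` (convergence) or 200 steps.  `e` is the
individual's environmental cue — the ±1 selective environment with 5% of
elements flipped.  The **Full** model uses the cue; the **NoCue** variant
replaces `e − p̃` with `−p̃` and is the mutation-led control.  Fitness of a
converged individual is `exp(−(20·‖p̃ − e‖₁ + N_step/20))`, with the L1
mismatch over the first 40 (selected) traits.  A genetic algorithm
(roulette selection, row-block crossover, density-preserving mutation at
rate 0.005, population 1000) evolves the population in epochs of 200
generations per environment, after 40 preparatory epochs under uncorrelated
random environments.

Analysis tools: genotype/phenotype projections for genotype–phenotype
plots, population genetic variance, phenotype–cue and phenotype–genome
cross-covariance matrices with their SVD, developmental-bias proportion
`σ₁²/Σσᵢ²`, alignment of the leading phenotype axis with the environmental
change, and a magnitude sweep with a jump detector for locating the
mutation-led → plasticity-led transition.

## Worked example

A workstation-scale experiment (the `"desk"` preset: 200 individuals, 50
generations per epoch, 3 preparatory + 3 production epochs; model
parameters identical to the full-scale protocol), with a 50% environmental
change between epochs:

```r
library(grnevo)

params <- evolutionParams(preset = "desk", envChangeFraction = 0.5, seed = 1)
res <- runExperiment(params)

tr  <- trajectory(res)
g1  <- tr[tr$generation == 1, ]
mean(g1$projNovelMean)        # 0.515
mean(g1$projAncestralMean)    # 0.372
mean(g1$mismatchNovel)        # 39.4
tail(tr$mismatchNovel, 1)     # ~30.7 by the end of an epoch
```

Read-out: at the first generation after a 50% change, the population's
phenotype cloud developed in the **novel** environment projects at 0.515 on
the ancestral→novel axis versus 0.372 for the same genomes developed in the
**ancestral** environment — an adaptive plastic response of ~0.14 induced
purely by the cue, before any selection.  Within an epoch the mean mismatch
(L1 distance of the 40 selected traits from the optimum; 40 ≈ uncorrelated,
0 = perfect) falls from 39.4 toward 30.7.  The NoCue control shows no
plastic gap (0 by construction) and, at this reduced scale, no measurable
mismatch decline — distinguishing the two adaptation modes.

A sweep over change magnitudes on the equilibrated population:

```r
sw <- transitionSweep(res, params = params,
                      magnitudes = c(0.05, 0.15, 0.25, 0.35, 0.5),
                      nReplicates = 5)
aggregate(cbind(projMean, s1PhenoCue) ~ magnitude, sw, median)
detectTransition(sw, "s1PhenoCue")   # smallest magnitude with a 3x jump (NA if none)
```

A thin command-line front end over the same functions is installed at
`inst/scripts/grnevo.R` (`simulate`, `sweep`, `fixtures` subcommands, YAML
configs as in `inst/extdata/desk-config.yaml`).

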