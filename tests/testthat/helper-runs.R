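# Desk-scale experiment cache: the plasticity-contrast checks share runs
# across assertions instead of re-simulating.

.deskRunCache <- new.env(parent = emptyenv())

deskRun <- function(model, frac, seed) {
  key <- sprintf("%s_%g_%d", model, frac, seed)
  if (!exists(key, envir = .deskRunCache)) {
    params <- evolutionParams(preset = "desk", model = model,
                              envChangeFraction = frac, seed = seed)
    assign(key, runExperiment(params), envir = .deskRunCache)
  }
  get(key, envir = .deskRunCache)
}

# generation-1 plastic-response gap (novel minus ancestral mean projected
# phenotype), averaged over production epochs
gen1PlasticGap <- function(res) {
  tr <- trajectory(res)
  g1 <- tr[tr$generation == 1L, ]
  mean(g1$projNovelMean - g1$projAncestralMean, na.rm = TRUE)
}

# early within-epoch mismatch decline (generation 1 minus generation 10),
# averaged over production epochs
earlyMismatchDecline <- function(res, upto = 10L) {
  tr <- trajectory(res)
  vapply(split(tr, tr$epoch), function(ep)
    ep$mismatchNovel[1L] - ep$mismatchNovel[upto], numeric(1)) |> mean(na.rm = TRUE)
}
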