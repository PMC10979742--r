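# Workstation-scale configuration: full-scale model parameters, reduced
# protocol (population, epoch length, epoch counts).
preset: desk          # popSize 200, 50 generations/epoch, 3 prep + 3 production
model: full           # "full" (cue-driven) or "nocue"
envChangeFraction: 0.5
cueNoise: 0.05        # fraction of environment elements flipped per cue
mutationRate: 0.005   # per-element resampling probability
density: 0.02         # nonzero fraction of each genome matrix
alphaSel: 20          # mismatch weight in log-fitness
betaStep: 0.05        # developmental-step weight in log-fitness
nSelectedTraits: 40
convTol: 1.0e-5
maxSteps: 200
emaAlpha: 0.333333333333
seed: 1
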