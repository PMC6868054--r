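# spikesampler

Spiking sampling networks (SSNs) under analog-hardware constraints, in R.

Networks of deterministic conductance-based leaky integrate-and-fire (LIF)
neurons can sample from Boltzmann distributions over binary random
variables: unit *k* is in the on-state *z_k* = 1 exactly while its neuron
is refractory, and with balanced synaptic background the refractory state
vector performs MCMC-like sampling from

p\*(z) = exp(½ zᵀWz + zᵀb) / Z,  z ∈ {0,1}ⁿ.

`spikesampler` is a pure-software emulation of such networks as they run
on accelerated analog neuromorphic substrates, for computational
neuroscientists and neuromorphic engineers who want to study the approach
— and the robustness of its training loop — without hardware access. It
reproduces the constraints that make the hardware setting interesting:

- **sampling units** built from neuron pairs (a sampling neuron plus a
  regularly firing suprathreshold-leak bias neuron whose synapse pair
  implements the bias),
- **4-bit paired excitatory/inhibitory synaptic weights** with
  deterministic discretization and continuous shadow values,
- **fixed-pattern and trial-to-trial parameter variability** (seeded
  lognormal conductance/time-constant perturbations),
- **two noise backends**: private Poisson input, or a fully deterministic
  recurrent inhibitory random network co-simulated with the SSN,
- **wake-sleep in-the-loop training**: Δb = η(⟨z⟩\* − ⟨z⟩),
  ΔW = η(⟨zz⟩\* − ⟨zz⟩) with momentum, computed from measured spikes and
  written back as rediscretized digital weights each iteration,
- the full experiment suite: target-distribution sampling (DKL
  convergence), conditional inference under clamping, image
  classification, pattern completion of occluded images, and guided
  dreaming, on synthetic 12 × 12 binary image data generated in-package.

The time-stepped LIF core is implemented in C++ (Rcpp) and is fully
deterministic given its seeds.

## Worked example: learning a 5-unit target distribution

```r
library(spikesampler)

target <- randomTarget(5, seed = 42)          # b, W ~ 2[Beta(.5,.5) - .5]
ssn <- buildSamplingNetwork(5, noise = "poisson", substrateSeed = 1)
cfg <- trainingConfig(eta = 1.0, momentum = 0.6, iterations = 100,
                      samplingTimeMs = 1e4, seed = 2)
fit <- trainToTarget(ssn, target, cfg)        # 4-bit, default variability

cat(sprintf("initial DKL: %.3f nats\n", fit$dklHistory[1]))
cat(sprintf("best DKL during training: %.4f nats (iteration %d)\n",
            min(fit$dklHistory), fit$bestIteration))
test <- samplingExperiment(fit$ssn, target, duration = 1e5,
                           trialSeed = 3, noiseSeed = 4)
cat(sprintf("test-run DKL after 1e5 ms: %.4f nats\n",
            test@summary["finalDkl"]))
```

prints

```
initial DKL: 1.696 nats
best DKL during training: 0.0532 nats (iteration 90)
test-run DKL after 1e5 ms: 0.0839 nats
```

The randomly initialized digital weights start almost two nats away from
the target; one hundred in-the-loop iterations bring the sampled joint to
a few times 10⁻² nats, and an independent 10⁵ ms test run (with a fresh
analog trial rewrite) confirms the trained configuration. The full
scaled-down benchmark protocol (200 iterations of 2 × 10⁴ ms, medians
over five targets) reaches a median test DKL of ~1.6 × 10⁻²; longer
per-iteration sampling tightens it further. Relevant knobs:
`variabilityModel()` (set CVs to zero for an ideal substrate),
`discretize = FALSE` (continuous weights), `noise = "rn"` (deterministic
random-network noise; use `eta = 0.5` and more iterations — background
correlations must be learned away).

For the image pipelines, see `makeSyntheticDataset()`,
`buildHierarchicalNetwork()`, `calibrateNetwork()`, `pcdPretrain()`,
`trainOnDataset()`, then `classify()`, `patternComplete()` and
`guidedDream()`. A thin command-line wrapper over the same functions is
installed at `inst/scripts/spikesampler` (commands `make-data`,
`calibrate`, `train-target`, `sample`, `infer`, `train-data`, `classify`,
`complete`, `dream`).

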