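---
title: "Sampling with LIF neurons under analog-hardware constraints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling with LIF neurons under analog-hardware constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spikesampler)
```

## The model

`spikesampler` simulates *spiking sampling networks* (SSNs): recurrent
networks of leaky integrate-and-fire (LIF) neurons whose collective state
performs Markov-chain Monte Carlo sampling from a Boltzmann distribution
over binary random variables,

$$p^*(z) = \frac{1}{Z}\exp\left(\tfrac{1}{2} z^\top W z + z^\top b\right),
\qquad z \in \{0,1\}^n,$$

with a symmetric, zero-diagonal coupling matrix $W$ and biases $b$. Each
random variable is represented by one *sampling neuron*: the variable is in
the on-state $z_k = 1$ exactly while the neuron is refractory, i.e. on the
union of the windows $[t_{sp}, t_{sp} + \tau_{ref})$ following its spikes.
The state sequence is therefore constructed from the output spikes and the
refractory times alone (`extractStates()`), and empirical distributions are
time-weighted state histograms (`empiricalJoint()`).

The membrane follows conductance-based LIF dynamics

$$C_m \dot u = -g_l (u - E_{leak}) - g_e(t)(u - E_{exc})
  - g_i(t)(u - E_{inh}),$$

with $g_l = C_m/\tau_{mem}$ and exponential-kernel synapses: a presynaptic
spike at $t_{sp}$ adds $J$ to the matching conductance at onset
$t_{sp} + d$, decaying with the postsynaptic $\tau_{syn}$; kernels
superpose linearly. Discrepancy against a target is measured by the
Kullback–Leibler divergence
$D_{KL}(p \,\|\, p^*) = \sum_z p(z)\ln[p(z)/p^*(z)]$ (nats), and image
reconstruction by the mean squared error over the reconstructed pixels.

Two properties make a deterministic LIF neuron a usable sampling unit.
First, strong balanced background input (either private Poisson trains or
a recurrent inhibitory *random network*, below) turns it into an
effectively stochastic unit and drives it into a high-conductance state
where the effective membrane time constant
$\tau_{eff} = C_m / g_{tot}$ is much shorter than $\tau_{syn}$ and
$\tau_{ref}$; this symmetrizes the activation function. Second, in that
regime the mean firing rate as a function of an input offset is
approximately logistic, so abstract Boltzmann parameters can be translated
into synaptic weights.

## Substrate constraints

The package emulates the constraints of an accelerated analog neuromorphic
substrate rather than an ideal simulator. All times are expressed in the
biological frame; hardware acceleration is a reporting convention with no
dynamical consequence, so it is not modeled.

*Sampling units.* Biases are implemented synaptically: each sampling neuron
is paired with a *bias neuron* whose leak potential lies above threshold
(`biasNeuronParams()`), so it fires regularly (ISI
$\tau_{ref} + \tau_{mem}\ln[(E_{leak}-V_{reset})/(E_{leak}-V_{thresh})]
\approx 2.32$ ms). It projects onto its sampling neuron through a paired
excitatory/inhibitory synapse whose digital weight $w_b$ is the unit's
bias dial. Bias neurons can be shared across units (`sharedBias`), the
layout used for large networks; the default for small sampling benchmarks
is one bias neuron per unit.

*4-bit paired weights.* Every plastic connection is a pair of one
excitatory and one inhibitory synapse; the sign of the (continuous,
double-precision *shadow*) weight selects the member that carries the
conductance, and the magnitude is rounded half-away-from-zero to an
integer in $[0, 15]$ (`discretizeWeight()`). Training keeps the shadow at
full precision and rewrites the discretized weights each iteration.

*Variability.* A `variabilityModel()` captures two imperfection classes as
multiplicative lognormal factors with mean one: a persistent *fixed
pattern* (default CV 20% on synaptic conductances, 10% on per-neuron
synaptic time constants), drawn once per substrate seed, and a smaller
*trial-to-trial* rewrite (default CV 1% on conductances) redrawn per
experiment run. The fixed-pattern CVs follow the qualitative published
evidence of highly diverse post-calibration PSP heights. The trial CV was
calibrated against the published observation that trial-to-trial
variability of measured activation functions is of sub-Hz order: at 1% CV
the emulated unit's rate jitters by about 2 Hz across rewrites, whereas a
5% CV produced ~10 Hz jitter, two orders above that observable. Digital
weights are never touched by either mechanism.

## Working point (commissioning choices)

The paper-level parameters are fixed (sampling neurons:
$E_{leak} = V_{thresh} = -20$ mV, $V_{reset} = -35$ mV, $\tau_{ref} = 4$
ms, $\tau_{syn} = 8$ ms, $C_m = 0.2$ nF, $\tau_{mem} = 7$ ms; Poisson
noise at 300 Hz per synapse type; synaptic delay 1 ms). Two dials are
genuinely substrate-specific and were fixed here by a commissioning study,
the way analog systems are calibrated to their sampling working point:

- **Noise synapse weight, 30 nS.** Strong enough for a proper
  high-conductance state ($g_{tot} \approx 170$ nS at the mean drive,
  $\tau_{eff} \approx 1.2$ ms $\ll \tau_{syn}, \tau_{ref}$) with a cleanly
  logistic activation function saturating near the refractory limit
  ($\nu_0 \tau_{ref} \approx 0.93$).
- **Unit scale, 2.8 nS per digital weight unit.** Sets the fitted
  activation width to $s \approx 2.7$ digital units, balancing bias
  resolution (one digital step $\approx 0.37$ units of abstract bias)
  against the representable coupling range (about $|W| \lesssim 0.8$
  before the 4-bit ceiling clips). The study selected these values by
  activation shape and by trained/test DKL on random 5-RV targets at the
  scaled-down protocol; a faster membrane (2 ms) was also tried and
  performed slightly worse, so the nominal 7 ms stands.

Initial membrane potentials are staggered deterministically between
$V_{reset}$ and $V_{thresh}$ (golden-ratio phases per neuron index):
populations of identical suprathreshold neurons would otherwise start in
pathological lockstep. This keeps `simulateNetwork()` bit-for-bit
deterministic for identical inputs.

Integration uses exponential Euler for the membrane and exact exponential
decay for conductances, default `dt = 0.1` ms (must satisfy
$dt \le \min(\tau)/4$), threshold detection on the post-step value with
spike timestamps on step boundaries. The ISI convergence test verifies the
integrator against the closed-form suprathreshold oracle as
$dt \to dt/4$; the sampling results are insensitive to halving `dt`.

## Calibration and translation

`calibrateNetwork()` measures every unit's activation function (rate vs.
bias weight, couplings off) and fits
$\nu_0/\{1 + \exp[-(w_b - w_{b0})/s]\}$ by Levenberg–Marquardt
(`fitActivation()`, with a direct least-squares fallback for very sharp
transitions). Translation (`translateParameters()`) maps
$b_i \mapsto w_{b0,i} + s_i b_i$ and
$W_{ij} \mapsto \kappa \sqrt{s_i s_j}\, W_{ij}$, the widths combined by
geometric mean to treat the two directions of each synapse pair
symmetrically.

The conversion factor $\kappa$ between coupling and bias digital units is
*measured*, not derived: a first-order argument (matching the mean
conductance one presynaptic spike delivers during the refractory on-window
to the bias neuron's sustained drive) overestimates the required weight by
roughly 2x, because the 8 ms synaptic kernel outlasts the 4 ms on-state
and keeps interacting after the presynaptic variable has switched off.
`couplingScale()` therefore probes an ideal two-unit network with a known
digital coupling $\pm w_d$ and reads the effective Boltzmann coupling off
the sampled joint, $\hat W = \ln[p_{11}p_{00}/(p_{10}p_{01})]$; at the
default working point $\kappa \approx 3.6$. The kernel tail and the
residual excitatory/inhibitory asymmetry are the dominant systematic
errors of translation-only sampling (DKL $\approx$ 0.04–0.07 for 5-unit
targets with $|W|, |b| \le 0.5$); in-the-loop training removes most of
what they distort.

The linear bias mapping leaves one visible approximation: because the
activation saturates at $\nu_0\tau_{ref}\approx 0.93$ rather than 1, a
translated unit's occupancy undershoots $\sigma(b)$ slightly (about 0.045
at $b = 1$). Training absorbs this; translation-only users should keep
biases moderate.

## Noise backends

The benchmark backend feeds each sampling neuron private 300 Hz excitatory
and inhibitory Poisson trains. The self-contained alternative is a sparse
recurrent *random network* (RN) of 200 inhibitory neurons with
suprathreshold leak ($E_{leak} = -10 > V_{thresh} = -20$ mV), each
receiving exactly 20 inhibitory inputs from distinct other RN neurons;
every sampling neuron receives exactly 15 excitatory and 15 inhibitory
projections from randomly chosen RN neurons (synapse type is a property of
the connection, as on hardware). The RN's internal weight is the published
10 digital units. Its emergent population rate here is ~7 Hz, and the
projection weight — which is not published — was calibrated to 20 digital
units (a 2-fold multapse) so that the RN-driven activation function
overlaps the Poisson-driven one ($s = 2.64$ vs $2.69$), the published
comparison between the two backends. Shared RN projections induce weak
positive input correlations (`noiseStatistics()` makes them visible);
training compensates them, which is why RN-driven networks need more
iterations (at learning rate 0.5) to reach a final divergence within a
factor ~1.5 of the Poisson backend.

## Training

`trainToTarget()` implements wake-sleep in-the-loop training for fully
specified targets: per iteration the discretized weights are written to
the (freshly trial-rewritten) substrate, the free network samples for the
configured sleep time (default scaled-down protocol: 200 iterations of
$2\times10^4$ ms; the first 80 ms $= 10\tau_{syn}$ are discarded as
burn-in), time-weighted moments and the sampled-vs-target DKL are
measured, and the shadow weights are updated by

$$\Delta b_i = \eta(\langle z_i\rangle^* - \langle z_i\rangle), \quad
\Delta W_{ij} = \eta(\langle z_i z_j\rangle^* - \langle z_i z_j\rangle),$$

with classical heavy-ball momentum
$\Delta_t = \eta g_t + m \Delta_{t-1}$ (the published "momentum factor"
names no formula; heavy-ball is the standard reading). Defaults follow the
published learning parameters: $\eta = 1$ (Poisson) or $0.5$ (RN),
$m = 0.6$, initial weights $U(-15, 15)$. Wake statistics for small targets
are computed analytically by enumeration (`analyticWakeStats()`). Shadow
weights are clipped to the representable $[-15, 15]$ to avoid integrator
wind-up against the hardware ceiling. The returned configuration is the
best-DKL iterate, not the last one: near convergence the discretized
weights oscillate between adjacent integers and the trajectory "jumps".

`trainOnDataset()` trains hierarchical networks (144 visible, 60 hidden,
L label units; plastic couplings restricted to visible–hidden and
hidden–label pairs). The wake term is sampled with visible and label
layers clamped and all couplings leaving the hidden layer turned off;
the sleep term comes from a free run; minibatches are 7 images per class.
Clamping uses 5-fold multapses of regular 100 Hz trains (excitatory for 1,
inhibitory for 0), phase-offset by 2 ms to smooth the clamping
conductance. Pre-training uses a standard persistent-contrastive-divergence
RBM (`pcdPretrain()`; conditioned on the hidden layer, visible and label
units are independent, so the three-layer network is an RBM with labels
appended to the visible layer) followed by `translateParameters()`. The
PCD weight decay (default $2\times10^{-3}$, overridable) matters on easily
separable data: without it the weights grow until the translated network
freezes into one attractor.

## Experiments

The five protocol pipelines are pure functions of (network, seeds,
config): `samplingExperiment()` (cumulative-time DKL trace),
`inferenceExperiment()` (clamp a subset, compare the free subspace to the
analytic conditional — converges faster than the joint because the state
space is smaller), `classify()` (500 ms presentations; label = highest
spike count, ties to the lowest index and flagged, all-silent flagged as
error), `patternComplete()` (25% of pixels unclamped, salt & pepper or a
contiguous 6 x 6 patch; MSE over occluded pixels against the reconstructed
binary state, i.e. trailing 10 ms box-filtered occupancy thresholded at
1/2, on a 5 ms grid; 100 ms of random visible input between images), and
`guidedDream()` (visible and hidden free, label layer one-hot clamped at
all times, 100 ms random visible input at each label switch, snapshots =
box-filtered visible occupancy). Classification and completion read
spikes only — no membrane traces.

Two dream-protocol choices deserve note. The label clamp must be
*enforced* against the full trained hidden fan-in, which can exceed what
the standard 5-fold multapse delivers; `guidedDream()` therefore uses a
20-fold label multapse by default. And class-conditional generation
requires an energy landscape shallow enough to mix: on nearly
noise-free synthetic classes (flip probability 0.05) both the spiking
network and the reference RBM stay trapped in one deep mode — the same
limitation reported for hard-to-mix classes on real data — so the
generation checks use noisier classes (flip 0.2), where all per-class mean
images separate.

## Synthetic data

`makeSyntheticDataset()` generates the study's desk-scale stand-in for
reduced, median-binarized visual data: per class a fixed balanced random
12 x 12 prototype (pairwise Hamming distance at least 20 by construction),
samples = prototype plus i.i.d. pixel flips (default 0.05, the
well-separated regime used for the classification benchmarks), split 2:1
into train/test. It reproduces the *format and statistical structure* of
reduced real datasets — binary 144-pixel images with class structure and
pixel noise — but not their intra-class correlation structure (strokes,
deformations), so passing benchmarks here do not predict absolute error
rates on real data; the published rMNIST/rFMNIST numbers require the
original downloads and are out of scope. `reduceAndBinarize()` provides
the documented reduction (nearest-neighbor index map
$\lfloor (j - 0.5)\,m/12 \rfloor + 1$, strict-majority binarization around
the per-image median) for user-supplied grayscale images.

## Numerical and protocol choices

- Empirical distributions are time-weighted, not grid-sampled; a grid
  variant can be emulated by sampling `extractStates()` breakpoints.
- Refractory intervals are half-open $[t_{sp}, t_{sp}+\tau_{ref})$;
  states are read from sampling neurons only.
- The DKL is implemented in its standard non-negative orientation
  $\sum_z p \ln(p/p^*)$.
- Degenerate inputs are rejected with explanations (too-coarse `dt`,
  unknown ports, empty windows, all-equal activation data, clamping every
  unit, non-finite weights).
- Problem sizes in the test suite and the reproduction script are the
  scaled-down study conditions: 5-unit networks trained for 200 (or 300)
  iterations of $2\times10^4$ ms with $10^5$ ms test runs, medians over 5
  target/seed combinations; hierarchical runs use a 144-60-3 network, 8
  in-the-loop iterations on 120 training images, and 60 test images.
- All randomness flows through named integer seed streams (substrate,
  trial, noise, data, training); every result object records its seeds.

## Known limitations

- The residual divergence floor of trained 5-unit networks here
  (median $\approx 1.6\times10^{-2}$) is dominated by the intrinsic
  LIF-vs-Glauber mismatch at this working point (synaptic kernels that
  outlast the on-state, 1 ms delays, reset below threshold), not by the
  4-bit constraint: relaxing discretization or variability moves the
  median only marginally. On the real substrate the same plateau is
  attributed mostly to weight discretization; the emulation reproduces
  the plateau's magnitude, not necessarily its attribution.
- Conditional (clamped) distributions are systematically less accurate
  than the joint — the effective-weight asymmetry induced by per-circuit
  variability is invisible to the learning rule.
- Synapse loss, driver saturation, routing and the analog memory-cell
  write process itself are not modeled; only their statistical effects
  enter through the variability model.
- AdEx adaptation/exponential terms and short-term plasticity are out of
  scope; the sampling model is plain LIF.
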