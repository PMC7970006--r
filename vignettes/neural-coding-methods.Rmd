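---
title: "Comparing neural coding schemes in an unsupervised spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing neural coding schemes in an unsupervised spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikecoding)
```

## The problem

How an input is turned into spikes determines almost everything about a
spiking neural network (SNN): how fast it responds, how many synaptic
operations (SOPs) it spends, how well it tolerates noisy inputs, and how
gracefully it degrades when its synapses are pruned, quantized, or mapped
onto imperfect analog devices. `spikecoding` implements four input coding
schemes — Poisson rate coding, time-to-first-spike (TTFS) coding, phase
coding, and burst coding — in front of the same two-layer unsupervised
network, so that their consequences can be compared under identical
conditions, at desk scale on synthetic data or on MNIST-style IDX files.

## Encoders

All encoders consume 8-bit grayscale images on a discrete time grid
(`time_grid()`; 0.5 ms steps except phase coding, which uses one phase per
1 ms step). Each produces a `spike_raster`: a boolean neuron-by-step spike
matrix plus a spike-weight sequence $w_s(t)$ used during decoding.

* **Rate**: pixel intensity is down-scaled by $\lambda$ (default 4) and
  read as a firing rate in Hz, so 8-bit pixels map to 0–63.75 Hz. Spikes
  are drawn per step as Bernoulli trials with probability
  $\mathrm{rate}\cdot dt$ — the discrete-time approximation of a Poisson
  train, generated by comparing the scaled pixel against uniform random
  numbers. $w_s \equiv 1$.
* **TTFS**: normalized pixels $P$ are compared against a decaying
  threshold $P_{th}(t) = \theta_0 e^{-t/\tau_{th}}$ ($\theta_0 = 1$,
  $\tau_{th} = 6$ ms); a neuron fires at its first strict crossing and
  never again. Spike weight $w_s(t) = e^{-t/\tau_s}$ ($\tau_s = 15$ ms)
  makes earlier spikes more informative. At $t = 0$ the threshold equals
  $\theta_0 = 1$, so even saturated pixels fire no earlier than the first
  decayed step; "exceeds" is implemented as a strict inequality.
* **Phase**: the 8-bit binary expansion of the intensity is emitted
  cyclically, most-significant bit at phase 1, with weight
  $w_s(t) = 2^{-(1+\mathrm{mod}(t-1,8))}$ expressing bit significance. A
  window that is not a multiple of 8 steps simply truncates the final
  period (the weight formula indexes integer steps, so nothing else is
  well-defined).
* **Burst**: a normalized pixel $P$ emits
  $N_s = \lceil N_{max} P\rceil$ spikes with inter-spike interval
  $\mathrm{ISI}(P) = \lceil -(T_{max}-T_{min})P + T_{max}\rceil$ ms
  ($N_{max} = 5$, $T_{min} = 2$ ms, $T_{max} = 10$ ms), clamped to
  $[T_{min}, T_{max}]$ and falling back to $T_{max}$ for single-spike
  bursts. The first spike sits at $t = 0$, the earliest the information
  can be delivered; with the defaults the whole burst ends before 20 ms.
  $w_s \equiv 1$ — the spike-weight decoding is defined for TTFS and
  reused by phase coding, and bursts (like rate trains) are left
  unweighted.

```{r encoders}
img <- matrix(sample(0:255, 64), 8, 8)
raster <- encode(img, "ttfs")
raster
head(raster_events(raster), 3)
```

## Network and plasticity

The processing layer is the standard unsupervised winner-take-all (WTA)
circuit: inputs are fully connected (weights $w_{ij} \in [0,1]$, initialized
uniformly) to leaky integrate-and-fire (LIF) excitatory neurons; each
excitatory neuron drives one dedicated inhibitory neuron, and each
inhibitory neuron inhibits every excitatory neuron except its source.
Synaptic input follows the simplified post-synaptic-potential form
$z_j(t) = w_s(t)\sum_i w_{ij} s_i(t)$ — input neurons contribute only at
their firing step, not cumulatively. Conductances decay with time constant
$\tau_g$; membranes relax toward rest with $\tau_m = 10$ ms
(exponential-Euler steps, unconditionally stable at the default $dt$).
Firing thresholds carry an adaptive offset $\theta$ that grows by
$\theta_+$ at each spike and decays slowly, which shares the competition
across neurons.

Learning is a simplified pair-based STDP on the input weights,
$\Delta w = \pm\mu_\pm\, w(1-w)$ depending on whether the presynaptic
spike precedes or follows the postsynaptic spike, with pairs outside a
20 ms learning window ignored. Taken literally, both branches of the rule
are potentiating; this implementation treats the post-before-pre branch
as depression of the same magnitude — the alternative saturates every
weight and no receptive fields can form — and this reading is flagged
wherever the rule is documented. All in-window pairs contribute
(`rule = "all"`); nearest-neighbour pairing is available as an option.
Updates are accumulated over an image window and applied at the window
end through a hook pipeline (quantize, programming noise, add, clip,
prune mask, stuck-at-fault mask), which is where all the compression and
non-ideality models attach.

### Completions of the network model, and their rationale

The reference parameter set (per-scheme thresholds, time constants,
learning rates, adaptation constants — see `scheme_config()`) leaves
several constants of the membrane equation open. The choices here, made
once and kept:

* $v_{rest} = v_{reset} = 0$ mV, refractory period 2 ms, inhibitory
  neurons use the same LIF parameters — the simplest consistent
  completion.
* **Input drive gain** (`input_gain` in `coupling_params()`): the
  conversion from the summed synaptic input $z_j$ to membrane drive in mV
  is unspecified, yet it sets the operating point of the WTA competition.
  If the peak drive of a typical pattern is far above threshold, every
  neuron fires in the same step, no winner can emerge, and the adaptive
  thresholds inflate uniformly until the network goes silent. The gain is
  therefore calibrated per scheme (0.2 for rate and burst, 0.8 for TTFS, 0.1 for
  phase on the default synthetic task) so that the best-matching
  neuron crosses threshold a few steps before its competitors and
  lateral inhibition (arriving with one step of synaptic delay,
  `w_ei = 15`, `w_ie = 2`) can silence the rest. TTFS needs the largest
  gain because it delivers exactly one spike per input.
* **Threshold-decay constant**: "slow" must be read relative to the
  *total* simulated training time. The default here is $10^4$ ms: under
  1% decay within any one image window — so adaptation is effectively
  constant within a window — while still letting thresholds relax over a
  training run of a few thousand simulated milliseconds. (A value of
  $10^5$ ms, natural for full 60,000-image training runs, makes the
  offsets ratchet upward at desk scale until every neuron falls silent.)
* Transient state (potentials, conductances, refractory counters) resets
  between images; $\theta$ and the weights persist. The adaptive offsets
  evolve within every window (adaptation is intrinsic to the neuron) but
  persist across windows only during training: labeling and inference
  passes leave the stored offsets untouched, the standard protocol for
  this architecture.
* One synaptic operation (SOP) is counted per spike per traversed
  synapse — input spikes times their row's unpruned fan-out, one per
  excitatory spike (its dedicated inhibitory synapse), $n_{exc}-1$ per
  inhibitory spike — plus one per weight actually written during
  training. The count is verified in the tests against a brute-force
  event recount.

## Evaluation protocol

After each training epoch the network is evaluated with plasticity off: a
labeling pass over the training set assigns each excitatory neuron the
class for which it fired most (ties to the lowest class), and an
inference pass predicts, for each test image, the class of the neuron
group with the highest mean spike count. `run_experiment()` orchestrates
the full train → label → infer pipeline with all perturbations attached;
`run_comparison()` runs several schemes on identical data and computes
the figure of merit

$$\mathrm{FOM} = \frac{\text{accuracy}}{\text{latency}\times\text{spikes}\times\text{SOPs}},$$

with every quantity normalized by its maximum over the compared set
(training + inference totals). Cross-scheme radar axes use min-max
normalization $(x_{max}-x_i)/(x_{max}-x_{min})$, so the worst scheme
scores 0 and the best 1 on each axis.

## Perturbation and compression models

* **Input noise**: additive white Gaussian noise specified either by a
  linear signal-to-noise power ratio (9.5 emulates background clutter;
  the values are dimensionless and are read as linear ratios, not dB —
  a `db = TRUE` switch is provided) or by an absolute standard deviation;
  motion blur from a length-5, 15° counterclockwise line kernel
  (rasterized with bilinear sub-pixel weights, unit sum, zero-padded
  borders); and reduced-contrast noise, which halves the contrast range
  about the image mean before applying SNR-12 noise.
* **Quantization**: weights live on an unsigned fixed-point lattice of
  precision $\epsilon = 2^{-\mathrm{bits}}$ (weights are in $[0,1]$, so
  no sign or integer bits are needed). Stochastic rounding maps a value
  onto its two neighbouring lattice points with probabilities
  proportional to proximity — unbiased, so small STDP updates survive in
  expectation. During training the rounding is applied to each window's
  update; post-training it maps the trained weights once.
* **Programming noise**: each device write adds
  $\mathcal{N}(0, (\sigma\epsilon)^2)$ to the written update, $\sigma$
  expressed as a fraction of the precision. Noise attaches to every
  proposed update (even one that quantizes to zero — the write still
  happens), which is why low-precision training accumulates damage
  faster than high-precision training.
* **Stuck-at-fault (SAF)**: a random fraction of synapses is frozen
  before training at the high (`w_on = 1`) or low (`w_off = 0`) bound —
  the extremes of the weight range standing in for the high/low
  conductance states. The mask is re-applied after every update
  (clamp-after-update; equivalent at readout to blocking the update),
  so faults persist through training.
* **Pruning**: weights below a threshold are zeroed and frozen. Online
  pruning re-applies the threshold at the end of each image window once a
  warmup count of images has been presented; post-training pruning is a
  single pass before inference. Connectivity is the percentage of
  surviving synapses.

## The synthetic task

`synthetic_spec()` describes a miniature of the handwritten-digit
datasets: 10×10-pixel images, three classes, 60 training and 30 test
samples by default. Each class template is a shared base stroke (about
12% of the pixels, common to all classes — digits share most of their
ink) plus a smaller class-specific stroke (about 8%), so classification
hinges on graded weight differences rather than disjoint masks, which is
what makes compression and fault effects measurable at all. Samples vary
by Gaussian intensity jitter (s.d. 20) and stroke-pixel dropout
(probability 0.2) on the ink pixels; the background stays exactly zero,
as in the centered, clean-background data this emulates. The generator is
deterministic per seed and class-balanced.

What it does **not** emulate: 10-way class structure, antialiased gray
edges, positional drift (images are centered, like the preprocessed
datasets), or correlated background clutter. Desk-scale results therefore
reproduce orderings and regime boundaries — which scheme spikes most,
where quantization collapses — not absolute full-scale accuracies.

```{r task, fig.width = 5, fig.height = 2.5}
d <- generate_synthetic(synthetic_spec(seed = 7))
ex <- suppressWarnings(
  run_experiment(experiment_config("ttfs", seed = 7, n_exc = 10))
)
tidy(ex)[, c("epoch", "accuracy", "train_sops", "infer_sops")]
```

## Problem sizes and determinism

The package's own experiments (tests, examples, and the reproduction
script) run the 3-class, 10×10, 10-excitatory-neuron configuration with
each scheme's reference windows and epoch counts — large enough for every
encoder to reach high accuracy, small enough that a full four-scheme
comparison takes about a minute on one CPU. Every stochastic step (weight
initialization, rate encoding, dataset generation, fault sampling,
stochastic rounding, programming noise, epoch shuffling) draws from the
single seeded R random stream of the calling experiment, so runs are
bit-for-bit reproducible; the deterministic encoders (TTFS, phase, burst)
are reproducible unconditionally.

## Known limitations

* The network is the shallow two-layer WTA circuit; no convolutional or
  multi-layer variants, and no supervised readout.
* Degradation *trends* at desk scale are qualitative. Regimes that
  depend on the sheer number of weight updates (e.g., programming-noise
  damage during training) shift when the update count shrinks by three
  orders of magnitude; the tests assert orderings and collapses, not the
  full-scale loss surfaces.
* The inhibitory pathway is a calibrated completion (the reference
  architecture fixes the wiring but not the coupling strengths or the
  inhibitory neuron model); conclusions that hinge on precise inhibition
  dynamics are outside what this implementation can support.
* The hardware results surrounding the original comparison (gate counts,
  FPGA power) are out of scope; SOP counts are the compute proxy.
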