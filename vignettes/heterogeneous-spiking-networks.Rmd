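---
title: "Heterogeneous self-inhibiting spiking networks: model, learning scheme and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneous self-inhibiting spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetsnn)
```

## The neuron model

`hetsnn` simulates and trains networks of *self-inhibiting* leaky
integrate-and-fire neurons. Each neuron `k` carries five biophysical
parameters, all learnable and all per-neuron:

| symbol  | field   | meaning                                     | units                 |
|---------|---------|---------------------------------------------|-----------------------|
| τ       | `tau`   | membrane decay per step                     | dimensionless, [0, 1] |
| γ       | `gamma` | autaptic self-inhibition strength           | current per spike     |
| C       | `C`     | input gain (capacitance-like)               | potential per current |
| u_th    | `u_th`  | firing threshold                            | potential             |
| u_re    | `u_re`  | resting / reset potential                   | potential             |

One synchronous step, given the weighted stimulus
`S^k(t) = Σ_i w_ik O^i` and the neuron's last output `O^k(t−1)`:

1. **Self-inhibition** `I = S − γ·O(t−1)`. The autapse subtracts a fixed
   quantum of input current in the step after the neuron fired, giving each
   neuron a one-step memory of its own activity and lengthening inter-spike
   intervals (tested as a strict monotonicity property).
2. **Membrane update** `u = f[(1−τ)·u(t−1) + τ·u_re + C·I]`, with `f` the
   leaky rectifier. `f` is applied to the full bracketed sum, including the
   resting term — the convention this package fixes for deep
   hyperpolarization, where the printed dynamics are ambiguous.
3. **Spike** `O = Θ(u − u_th)`, strictly: exact threshold equality does not
   fire.
4. **Hard reset** `u ← (1−O)·u + O·u_re`: firing restores the resting
   potential exactly.

With `γ = 0` and trajectories on the positive branch of `f`, the model is
exactly the textbook discrete LIF recursion; this limit is enforced by test
against the closed form.

## Surrogate gradients

The spike nonlinearity has measure-zero derivative, so backpropagation
through the unrolled dynamics replaces `Θ'` with the triangle
pseudo-derivative

`g(x) = (1/w)·max(0, 1 − |x|/w)`,   `x = u − u_th` (pre-reset),

with half-width `w` in threshold units (`surrogate_spec(width)`). Three
conventions define the backward contract precisely:

* `g` is evaluated at the **pre-reset** membrane potential;
* the reset is **non-differentiated gating**: the gate value `(1−O)` (resp.
  `O`) multiplies the flowing gradient, but no derivative of the gate itself
  is taken;
* every biophysical parameter receives gradients along all of its forward
  paths, including the initial condition `u(0) = u_re`.

To make this machinery checkable by finite differences, the forward pass has
a *relaxed* mode in which the emitted spike value is the C¹ antiderivative
ramp of `g` (the reset gate stays hard). Surrogate backpropagation is the
exact gradient of that relaxed graph almost everywhere, and the test suite
verifies agreement with central differences to ~1e−9 relative on weights and
biophysics, for every readout, loss and propagation convention.

### Defaults

* Leaky-rectifier slope: 0.01 (common convention), configurable.
* Surrogate width: 1.0 threshold unit by default. The packaged training
  recipes for the fixture tasks use width 2: with badly scaled
  initializations the membrane sits far from threshold, and a wider triangle
  keeps a trickle of gradient alive — the difference between a recoverable
  and a dead network. Width is recorded in every run's resolved config.
* Numeric equality tolerance in tests: 1e−6 relative.

## Network unrolling and readout

`network_spec()` describes dense feed-forward stacks unrolled over `T`
steps. Two timing conventions exist: default *depth-synchronous* (layer `l`
at step `t` sees layer `l−1`'s output of the same step — what makes 2–5-step
latencies meaningful), and `delayed_interlayer = TRUE` for the literal
one-step pipeline. States are per-sample, initialized at `u = u_re`,
`o_prev = 0`.

**Readout.** `spike-count` sums the output layer's spikes under the full
spiking dynamics. The default `membrane-accumulate` readout makes the output
layer a *linear leaky integrator* — no threshold, no reset, no rectifier —
and reads the mean membrane over `T`. This is a deliberate design choice,
not a neutral implementation detail: with a spiking, rectified output layer
the logits are non-negative and are scrambled by resets, so cross-entropy
cannot push a wrong class's score down, and training demonstrably stalls at
chance even on linearly separable data. The linear-integrator readout is
standard practice in surrogate-gradient spiking classifiers and keeps the
readout informative at tiny `T` and in the no-spike regime (an asserted
property).

**Encodings** for static data: `direct-current` repeats the feature vector
as an analog drive (counted as dense MACs in the energy model);
`poisson-rate` draws seeded Bernoulli spikes; `native-spikes` passes binary
sequences through.

## Bi-level heterogeneous learning

Training splits the data into an *orthogonal* sub-training set `D_t` and
sub-validation set `D_v` (stratified, seeded, disjoint). The inner loop
descends the synaptic weights on `D_t`:

`W ← W − ξ1 ∇_W L_t(D_t; W, α)`.

The outer loop updates the biophysics α against the upper-level objective
`L_u = L_v(D_v; W, α) + λ·Ω(α)`:

`α ← α − ξ2 ∇_α L_u`.

The hypergradient accounts (approximately) for the dependence of the trained
weights on α through their one-step update `W' = W − ξ1∇_W L_t`:

* `order = "first"` (default): drop the mixed second-order term — efficient,
  and the scheme the package recommends;
* `order = "second"`: `∇_α L_u(W', α) − ξ1·[∇_α L_t(W⁺) − ∇_α L_t(W⁻)]/(2ε)`
  with `W∓ = W ∓ ε∇_{W'}L_u(W', α)` and `ε = ε₀/‖∇_{W'}L_u‖` (ε₀ = 0.01).
  A vanishing direction norm skips the term and flags the event.

At `ξ1 = 0` both orders coincide exactly (asserted elementwise). The
finite-difference mixed term is verified against an exact mixed-derivative
oracle on an analytic toy with a cubic weight coupling, with the error
decreasing as ε shrinks. After every α step, τ is clamped to `[0, 1]` and γ
to `≥ 0` (projection; the model has no intrinsic parameterization).

**Schedule.** `alternation = k` takes one α step every `k` minibatch weight
steps; `alternation = 0` (default) takes one α step per epoch. The fixture
recipes use `alternation = 2`: under hostile initializations the α loop is
the rescue mechanism, and it needs more frequent steps than one per epoch to
act within a reasonable budget.

**Homogeneous ablation.** `xi2 = 0` freezes α at its initialization — only
the synaptic weights are learned — and is asserted to never touch the
biophysics. On the packaged temporal fixture with a deliberately bad
initialization (`u_th = 2`, `τ = 0.9`), heterogeneous learning lowers
thresholds and decay until spiking resumes and reaches roughly double the
homogeneous held-out accuracy (the acceptance suite reproduces this over
five seeds).

### The Laplacian smoothness penalty

`Ω(α) = Σ_{(i,j)∈E} w_ij ‖α̃_i − α̃_j‖²` over a neighbor graph within each
layer, where `α̃` stacks the five fields divided by per-field scales
(default: unit scales, i.e. raw units; an `sd`-based scaling is available).
Spatial adjacency has no analog in a dense layer, so the default graph is a
chain over neuron index, with complete-graph and k-nearest-in-α-space
alternatives. `Ω ≥ 0` with equality iff connected neurons share parameters;
the implementation is tested against a brute-force edge sum and its gradient
against finite differences. Weights `W` are never penalized. One practical
stability note, asserted as a property: the α dynamics under the quadratic
penalty overshoot when `ξ2·λ` is large relative to the graph degree, so the
penalty-monotonicity experiments run at `ξ2 = 0.1`.

## Single-neuron fitting

`fit_single_neuron()` recovers biophysical parameters from an injected
current and a recorded spike train by minimizing a squared van Rossum
distance: both trains are filtered with a causal exponential kernel (time
constant 20 steps by default — twice the default similarity-evaluation
window) and compared in mean square. The forward simulation stays exactly
binary; descent directions come from surrogate backpropagation, so a perfect
reproduction has exactly zero loss *and* zero update — initializing at the
generating parameters is a genuine fixed point (tested).

Restarts are fitted simultaneously as one unconnected population driven by
the same current (their gradients never interact), which makes a 5-restart
fit cost one simulation per iteration; the best restart by final binary
distance is returned.

**Identifiability.** The dynamics are invariant under joint rescaling of
`(C, u_th, u_re)` — the threshold scale is a gauge freedom. Recovery
experiments therefore fix `u_th = 1, u_re = 0` (the generating convention)
and fit `τ, γ, C`; with `T = 1000` noise-current steps and initializations
50% off the truth, the best of five restarts recovers τ and γ within 10%.
Fitting with `γ` pinned to zero (a plain LIF neuron) to data from a strongly
self-inhibiting ground truth is strictly worse in smoothed distance on all
tested seeds — the package's form of the self-inhibition ablation.

## Evaluation metrics

* **`md_star()`** — similarity between two *sets* of spike trains at a
  time-window resolution: boxcar-smooth each train, average cross-set inner
  products, normalize by the geometric mean of within-set inner products
  with self-pairs excluded (the bias correction). Index-equal pairs are also
  excluded from the cross term when the sets have equal size, which makes
  self-comparison exactly 1. The exact estimator is this package's own
  declared construction; it is symmetric, ≈1 for homogeneous independent
  sets, and degrades with rate-pattern mismatch (all tested).
* **`classification_report()`** — accuracy, per-class F1, macro-F1, a
  rare-class panel below a prevalence threshold, and a true→predicted flow
  table for Sankey-style plots.
* **`generation_mse()`**, **`manifold_project()`** — elementwise MSE against
  template trains, and PCA of boxcar-smoothed rates (the empirical
  neural-manifold construction), verified against a direct
  eigendecomposition.
* **`energy_estimate()`** — event-driven accounting: spike-driven
  accumulates at `e_ac` = 0.9 pJ, dense multiply-accumulates (analog
  reference network, and any direct-current front end) at `e_mac` = 4.6 pJ —
  conventional 45 nm CMOS figures, configurable. The accumulate counts equal
  a brute-force counter and the fold reduction falls as injected spike
  counts rise (tested).

## Synthetic fixtures: what they emulate, and what they do not

All data used by the tests and the acceptance script is generated in code,
seeded, and ships a sidecar with the generating ground truth:

* `gen_neuron_trace()` — Gaussian noise current (default mean 0.5, sd 0.5,
  `T = 1000`) through a known neuron (default τ = 0.3, γ = 0.5); emulates
  noise-current injection protocols.
* `gen_temporal_classes()` — classes whose per-neuron time-collapsed spike
  counts are *identical by construction*, so a rate classifier is at chance
  and all class information is in timing; 10% spike-time jitter. With
  homogeneous decay the usable temporal features are nearly collinear, which
  is exactly why heterogeneity pays on this task.
* `gen_expression_matrix()` — negative-binomial counts (dispersion 0.5) with
  20-gene upregulated marker blocks per cell type and exact prevalence
  bookkeeping down to 0.1% rare classes; the default CI profile uses 1%
  rare prevalence, and every rare-class experiment is pre-certified solvable
  by a nearest-centroid oracle before a network is asked to solve it.
* `gen_generation_task()` — Poisson templates driven by smooth
  two-dimensional latent rates (so a low-dimensional manifold exists by
  construction) plus fixed seeded Poisson noise inputs.

These fixtures establish *mechanism*, not field realism: they contain no
batch effects, no library-size artifacts, no cross-species structure, no
sensor noise. Passing tests show the algorithms do what they claim under
controlled conditions — not that the defaults transfer to any particular
recording or atlas.

## Problem sizes and numerical choices

The shipped experiments run on one CPU in a few minutes: dynamics oracles at
400 neurons × 50 steps, gradient checks on 2-3-2 nets, recovery at
`T = 1000` with 5 restarts × 150 Adam iterations, the bad-init ablation at
2-16-3 × T = 5 × 80 epochs × 5 seeds, and the rare-class task at 500 cells ×
100 genes × 30 epochs × 5 seeds. Degenerate inputs are handled explicitly:
all-silent spike-train sets return a flagged `NA` similarity; a zero
finite-difference direction falls back to the first-order hypergradient with
a flag; all-silent fitting targets converge to a flagged no-spike solution;
non-finite losses abort training with the epoch identified.

## Known limitations

* Dense feed-forward stacks only — no convolutional, recurrent-across-layer
  or event-camera front ends (shapes are supported generically).
* The hypergradient uses a single inner step; implicit-function-theorem
  corrections are out of scope.
* The van Rossum fitting loss and the `md_star` estimator are this package's
  declared constructions; other conventions exist and numerical values are
  not comparable across conventions.
* Energy figures are per-operation bookkeeping, not a platform model.
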