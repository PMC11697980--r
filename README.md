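# hetsnn

Heterogeneous self-inhibiting spiking neural networks with bi-level
learning, in R.

Spiking networks usually learn only their synaptic weights; every neuron
shares one fixed set of membrane dynamics. `hetsnn` is for researchers who
want each neuron to learn its **own** biophysics. It implements a
self-inhibiting (autaptic) leaky integrate-and-fire neuron with five
learnable per-neuron parameters — membrane decay τ, autaptic inhibition
strength γ, input gain C, firing threshold u_th and resting potential u_re —
and trains networks of them with a bi-level scheme that alternates a
network-level weight loop with a neuron-level biophysics loop. The package
targets three uses: fitting single neurons to recorded spike trains,
training small heterogeneous classifiers (including rare-cell-type
identification from expression matrices), and studying when per-neuron
heterogeneity rescues training that homogeneous weight learning cannot.

## The model

One synchronous step of neuron *k*, driven by stimulus
S<sup>k</sup>(t) = Σ<sub>i</sub> w<sub>ik</sub> O<sup>i</sup>:

```
I(t) = S(t) − γ · O(t−1)                        self-inhibiting autapse
u(t) = f[(1 − τ) u(t−1) + τ u_re + C · I(t)]    leaky membrane, f = leaky ReLU
O(t) = Θ(u(t) − u_th)                           spike iff u > u_th strictly
u(t) ← (1 − O) u(t) + O u_re                    hard reset
```

Training is the bi-level program

```
min_α  L_v(D_v; W*(α), α) + λ Ω(α)     s.t.  W*(α) = argmin_W L_t(D_t; W, α)
```

solved by alternating `W ← W − ξ1 ∇_W L_t` with `α ← α − ξ2 ∇_α L_u` over
orthogonal sub-training/sub-validation splits. Gradients flow through the
unrolled spike dynamics via a triangle surrogate pseudo-derivative;
hypergradients come in a first-order form (default) and a finite-difference
second-order form. Ω is a graph-Laplacian penalty that encourages
neighboring neurons to keep similar biophysics. Setting `ξ2 = 0` freezes the
biophysics — ordinary homogeneous SNN training — and is the built-in
ablation.

## Worked example

A three-class task whose information lives purely in spike timing (the
time-collapsed spike counts are identical across classes, so any rate-based
classifier is at chance by construction):

```r
library(hetsnn)

fx <- gen_temporal_classes(n_classes = 3, neurons = 2, T = 5,
                           jitter = 0.1, n_per_class = 50, seed = 1)

spec <- network_spec(c(2, 16, 3), time_steps = 5,
                     encoding = "native-spikes")
cfg <- bilevel_config(xi1 = 0.3, xi2 = 0.3, lam = 0.01, epochs = 40,
                      batch_size = 16, width = 2, alternation = 2, seed = 3)
fit <- snn_train(spec, fx$input, fx$labels, cfg,
                 init = list(tau = 0.3, hetero_sd = 0.2))
fit
#> <snn_fit> heterogeneous net [2-16-3], T = 5, 40 epoch(s)
#>   final loss: train 0.4958, val 0.4837, penalty 6.276

pred <- classification_report(fx$labels, predict(fit, fx$input),
                              class_names = c("1", "2", "3"))
pred
#> <classification_report> accuracy 0.933, macro-F1 0.933
#> # A tibble: 3 × 6
#>   class support prevalence precision recall    f1
#>   <chr>   <int>      <dbl>     <dbl>  <dbl> <dbl>
#> 1 1          50      0.333     0.959   0.94 0.949
#> 2 2          50      0.333     0.957   0.88 0.917
#> 3 3          50      0.333     0.891   0.98 0.933
```

Accuracy 0.93 on a task where rate coding gives 0.33: the per-neuron
parameters have differentiated (each neuron now has its own membrane time
constant) and the timing structure became linearly readable:

```r
head(tidy(fit), 4)   # one row per neuron: tau, gamma, C, u_th, u_re, MTC
#> # A tibble: 4 × 8
#>   layer neuron   tau  gamma     C  u_th     u_re mtc_ms
#>   <int>  <int> <dbl>  <dbl> <dbl> <dbl>    <dbl>  <dbl>
#> 1     1      1 0.266 0.260  0.851  1.13 -0.0653    3.24
#> 2     1      2 0.273 0.218  0.804  1.20 -0.186     3.13
#> 3     1      3 0.279 0.154  0.543  1.26 -0.435     3.06
#> 4     1      4 0.152 0.0745 0.901  1.03 -0.00284   6.06
```

`autoplot(fit)` draws the loss curves; `glance(fit)` gives a one-row
summary. The same surface covers single-neuron fitting
(`fit_single_neuron()`, with a γ = 0 LIF ablation via
`fix = list(gamma = 0)`), spike-train set similarity (`md_star()`), neural
manifolds (`manifold_project()`), event-driven energy accounting
(`energy_estimate()`) and seeded fixture generators for neuron traces,
temporal tasks, rare-cell-type expression matrices and noise-to-template
generation tasks.

A command-line wrapper (`inst/cli/hetsnn.R`) exposes `fixtures`, `train`,
`fit-neuron`, `evaluate` and `replay`; every run writes a manifest from
which it can be replayed bit-identically.

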