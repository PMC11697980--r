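Package: hetsnn
Title: Heterogeneous Self-Inhibiting Spiking Neural Networks with Bi-Level Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and training of spiking neural networks built from
    self-inhibiting (autaptic) leaky integrate-and-fire neurons whose five
    biophysical parameters (membrane decay, autaptic inhibition strength,
    input gain, firing threshold and resting potential) are learnable per
    neuron. Training alternates a network-level synaptic-weight loop with a
    neuron-level biophysics loop in a bi-level scheme, using triangle
    surrogate gradients through the unrolled spike dynamics, first-order or
    finite-difference second-order hypergradients, a graph-Laplacian
    smoothness penalty on neuron parameters, and orthogonal sub-training /
    sub-validation splits. Includes single-neuron parameter fitting to
    recorded spike trains via a van Rossum distance, bias-corrected
    spike-train similarity across time-window resolutions, rare-class-aware
    classification reports, PCA neural-manifold projections, synaptic
    operation and energy accounting, and seeded synthetic generators for
    neuron traces, temporal classification tasks, rare-cell-type expression
    matrices and noise-to-template generation tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
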