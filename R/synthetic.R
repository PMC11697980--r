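# Seeded fixture generators. Every generator is a pure function of its
# arguments (bit-reproducible given the seed) and returns, alongside the
# data, a `sidecar` list carrying the ground truth needed to score any
# downstream stage without re-generation.

#' Ground-truth neuron trace fixture
#'
#' Draws a seeded Gaussian noise current and simulates the spike response of
#' a neuron with known biophysical parameters — the raw material for
#' single-neuron parameter-recovery experiments.
#'
#' @param params_true A [neuron_params] for one neuron (the ground truth).
#' @param mean,sd Mean and standard deviation of the injected current.
#' @param T Trace length in steps (at least 100).
#' @param n_trials Number of independent trials.
#' @param seed Integer seed.
#' @param dt_label Nominal step duration (ms), reporting only.
#' @return A list: `current` (`[trials x T]`), `spikes` ([spike_train]
#'   `[trials x T]`), `sidecar` (ground-truth parameters, current spec,
#'   seed, and a `silent` flag set when no spike was produced).
#' @export
gen_neuron_trace <- function(params_true = neuron_params(1, tau = 0.3,
                                                         gamma = 0.5),
                             mean = 0.5, sd = 0.5, T = 1000, n_trials = 1,
                             seed = 1, dt_label = 1) {
  stopifnot(T >= 100, n_neurons(params_true) == 1)
  set.seed(seed)
  current <- matrix(stats::rnorm(n_trials * T, mean, sd), n_trials, T)
  spikes <- matrix(0, n_trials, T)
  for (b in seq_len(n_trials)) {
    spikes[b, ] <- simulate_neuron(current[b, ], params_true)[1, ]
  }
  silent <- sum(spikes) == 0
  if (silent) warning("gen_neuron_trace: parameterization produced no spikes")
  list(current = current,
       spikes = spike_train(spikes, dt_label = dt_label),
       sidecar = list(kind = "neuron-trace",
                      params_true = unclass(params_true)[alpha_fields],
                      current_mean = mean, current_sd = sd, T = T,
                      n_trials = n_trials, seed = seed,
                      dt_label = dt_label, silent = silent))
}

#' Temporal classification fixture
#'
#' Builds class templates whose information lives purely in spike timing:
#' every class drives each neuron for a burst window of the same length, but
#' the window's position rotates with the class, so the time-collapsed
#' per-neuron spike counts are identical across classes and a rate-summed
#' classifier is at chance by construction. Samples are jittered
#' realizations of their class template: each spike independently shifts by
#' one step left/right with probability `jitter` (split evenly), and with
#' probability `jitter/4` a spike drops out or a spurious spike appears.
#'
#' @param n_classes Number of classes (at least 2).
#' @param neurons Input neurons.
#' @param T Steps per sample.
#' @param jitter Timing-noise level in `[0, 1)`; 0 gives identical samples
#'   within each class.
#' @param n_per_class Samples per class (exact label balance).
#' @param seed Integer seed.
#' @return A list: `input` (`[neurons x T x samples]` binary array),
#'   `labels` (integer `1..n_classes`), `templates`
#'   (`[neurons x T x n_classes]`), `sidecar`.
#' @export
gen_temporal_classes <- function(n_classes = 3, neurons = 2, T = 5,
                                 jitter = 0.1, n_per_class = 50, seed = 1) {
  stopifnot(n_classes >= 2, neurons >= 1, T >= n_classes)
  if (jitter >= 1) warning("gen_temporal_classes: jitter >= 1 is degenerate")
  set.seed(seed)
  burst <- max(1L, T %/% n_classes)
  templates <- array(0, dim = c(neurons, T, n_classes))
  for (cl in seq_len(n_classes)) {
    for (nn in seq_len(neurons)) {
      start <- 1 + ((nn - 1 + (cl - 1) * burst) %% T)
      idx <- ((start - 1 + seq_len(burst) - 1) %% T) + 1
      templates[nn, idx, cl] <- 1
    }
  }
  n <- n_classes * n_per_class
  labels <- rep(seq_len(n_classes), each = n_per_class)
  input <- array(0, dim = c(neurons, T, n))
  for (s in seq_len(n)) {
    tpl <- templates[, , labels[s], drop = FALSE]
    samp <- matrix(tpl, neurons, T)
    if (jitter > 0) {
      out <- matrix(0, neurons, T)
      for (nn in seq_len(neurons)) {
        for (t in which(samp[nn, ] == 1)) {
          if (stats::runif(1) < jitter / 4) next  # dropout
          shift <- sample(c(-1L, 0L, 1L), 1,
                          prob = c(jitter / 2, 1 - jitter, jitter / 2))
          out[nn, min(max(t + shift, 1), T)] <- 1
        }
        if (stats::runif(1) < jitter / 4) {
          out[nn, sample.int(T, 1)] <- 1      # spurious spike
        }
      }
      samp <- out
    }
    input[, , s] <- samp
  }
  list(input = input, labels = labels, templates = templates,
       sidecar = list(kind = "temporal-classes", n_classes = n_classes,
                      neurons = neurons, T = T, jitter = jitter,
                      n_per_class = n_per_class, seed = seed,
                      burst = burst))
}

#' Rare-cell-type expression-matrix fixture
#'
#' Negative-binomial count matrix with type-specific upregulated marker
#' blocks, emulating a single-cell expression profile with a configurable
#' rare population. Baseline counts are NB with mean `base_mean` and
#' dispersion `dispersion`; each cell type upregulates its own block of
#' `markers_per_type` genes by the factor `marker_strength`. Class counts
#' are exact multinomial rounding of `type_proportions`, with every class
#' forced to at least 5 cells by enlarging `n_cells` if needed.
#'
#' @param n_cells Requested number of cells.
#' @param n_genes Number of genes (at least
#'   `markers_per_type * n_types`).
#' @param type_proportions Numeric vector of type proportions summing to 1;
#'   rare types are simply small entries (down to 0.001).
#' @param marker_strength Fold upregulation of a type's marker block (0 =
#'   types indistinguishable in expectation).
#' @param markers_per_type Marker-block size per type.
#' @param base_mean Baseline NB mean.
#' @param dispersion NB dispersion (`size = 1/dispersion`).
#' @param seed Integer seed.
#' @return A list: `counts` (`[cells x genes]` integer matrix), `logcounts`
#'   (`log1p`-normalized), `labels` (integer types), `marker_genes` (list of
#'   marker-column indices per type), `sidecar`.
#' @export
gen_expression_matrix <- function(n_cells = 500, n_genes = 100,
                                  type_proportions = c(0.59, 0.3, 0.1, 0.01),
                                  marker_strength = 4,
                                  markers_per_type = 20,
                                  base_mean = 2, dispersion = 0.5,
                                  seed = 1) {
  stopifnot(abs(sum(type_proportions) - 1) < 1e-8,
            all(type_proportions > 0),
            n_genes >= markers_per_type * length(type_proportions))
  n_types <- length(type_proportions)
  counts_per_type <- pmax(5L, round(type_proportions * n_cells))
  n_cells <- sum(counts_per_type)
  labels <- rep(seq_len(n_types), counts_per_type)
  set.seed(seed)
  labels <- sample(labels)   # shuffle cell order
  marker_genes <- lapply(seq_len(n_types), function(ty) {
    (ty - 1) * markers_per_type + seq_len(markers_per_type)
  })
  mu <- matrix(base_mean, n_cells, n_genes)
  for (ty in seq_len(n_types)) {
    rows <- labels == ty
    mu[rows, marker_genes[[ty]]] <-
      base_mean * (1 + marker_strength)
  }
  counts <- matrix(stats::rnbinom(n_cells * n_genes, size = 1 / dispersion,
                                  mu = as.vector(mu)),
                   n_cells, n_genes)
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  logcounts <- log1p(counts / lib * stats::median(lib))
  list(counts = counts, logcounts = logcounts, labels = labels,
       marker_genes = marker_genes,
       sidecar = list(kind = "expression-matrix", n_cells = n_cells,
                      n_genes = n_genes,
                      type_proportions = type_proportions,
                      marker_strength = marker_strength,
                      markers_per_type = markers_per_type,
                      base_mean = base_mean, dispersion = dispersion,
                      seed = seed))
}

#' Nearest-centroid oracle for expression fixtures
#'
#' Certifies the separability of a generated expression matrix: fits class
#' centroids on one half of the cells (seeded split) and classifies the
#' other half by nearest centroid, returning the held-out
#' [classification_report]. Used to pre-certify that a fixture is solvable
#' before asking a trained network to solve it.
#'
#' @param logcounts `[cells x genes]` normalized matrix.
#' @param labels Integer labels.
#' @param seed Split seed.
#' @return A [classification_report] on the held-out half.
#' @export
centroid_oracle <- function(logcounts, labels, seed = 1) {
  sp <- split_orthogonal(length(labels), 0.5, seed = seed, labels = labels)
  centroids <- do.call(rbind, lapply(sort(unique(labels)), function(ty) {
    colMeans(logcounts[sp$train[labels[sp$train] == ty], , drop = FALSE])
  }))
  test <- logcounts[sp$val, , drop = FALSE]
  d2 <- outer(rowSums(test^2), rowSums(centroids^2), "+") -
    2 * test %*% t(centroids)
  pred <- apply(d2, 1, which.min)
  classification_report(labels[sp$val], pred,
                        class_names = as.character(sort(unique(labels))))
}

#' Noise-to-template generation-task fixture
#'
#' Builds template spike trains as Poisson (Bernoulli per step) realizations
#' of smooth low-dimensional latent rates — so an `latent_dim`-component
#' neural manifold exists by construction — together with a fixed seeded
#' Poisson noise input set; per-trial Gaussian perturbations of the input
#' add variability at generation time.
#'
#' @param neurons Template/population size.
#' @param T Steps.
#' @param trials Number of trials (at least 2).
#' @param latent_dim Latent rate dimensionality.
#' @param input_neurons Size of the noise input population.
#' @param noise_rate Bernoulli rate of the fixed Poisson noise input.
#' @param input_sd Gaussian perturbation added to the input per trial.
#' @param seed Integer seed.
#' @return A list: `input` (`[input_neurons x T x trials]`, fixed noise plus
#'   per-trial Gaussian jitter), `templates` (`[neurons x T x trials]`
#'   binary), `rates` (`[neurons x T]` latent rates), `sidecar`.
#' @export
gen_generation_task <- function(neurons = 30, T = 100, trials = 10,
                                latent_dim = 2, input_neurons = 10,
                                noise_rate = 0.3, input_sd = 0.1,
                                seed = 1) {
  stopifnot(trials >= 2, neurons >= latent_dim)
  set.seed(seed)
  tt <- seq_len(T) / T
  latents <- vapply(seq_len(latent_dim), function(d) {
    ph <- stats::runif(1, 0, 2 * pi)
    0.5 + 0.5 * sin(2 * pi * d * tt + ph)
  }, numeric(T))                       # [T x latent_dim]
  loadings <- matrix(stats::runif(neurons * latent_dim, 0, 1),
                     neurons, latent_dim)
  loadings <- loadings / rowSums(loadings)
  rates <- 0.05 + 0.6 * (loadings %*% t(latents))   # [neurons x T]
  base_noise <- matrix(stats::rbinom(input_neurons * T, 1, noise_rate),
                       input_neurons, T)
  templates <- array(0, dim = c(neurons, T, trials))
  input <- array(0, dim = c(input_neurons, T, trials))
  for (b in seq_len(trials)) {
    templates[, , b] <- matrix(stats::rbinom(neurons * T, 1,
                                             as.vector(rates)),
                               neurons, T)
    input[, , b] <- base_noise +
      matrix(stats::rnorm(input_neurons * T, 0, input_sd), input_neurons, T)
  }
  list(input = input, templates = templates, rates = rates,
       sidecar = list(kind = "generation-task", neurons = neurons, T = T,
                      trials = trials, latent_dim = latent_dim,
                      input_neurons = input_neurons,
                      noise_rate = noise_rate, input_sd = input_sd,
                      seed = seed))
}
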