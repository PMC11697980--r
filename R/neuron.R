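#' Per-neuron biophysical parameters
#'
#' Bundles the five learnable biophysical variables of a population of
#' self-inhibiting leaky integrate-and-fire neurons. Each field is a numeric
#' vector with one entry per neuron:
#'
#' * `tau` — membrane decay, the dimensionless per-step leak fraction in
#'   `[0, 1]`;
#' * `gamma` — autaptic self-inhibition strength (input-current units per
#'   spike), subtracted from the input one step after the neuron fires;
#' * `C` — input gain (capacitance-like), membrane-potential units per unit
#'   input current;
#' * `u_th` — firing threshold potential;
#' * `u_re` — resting potential, also the hard-reset target after a spike.
#'
#' Scalars are recycled to length `n`. With `hetero_sd > 0` each field is
#' perturbed by seeded Gaussian noise to break homogeneity at initialization
#' (`tau` is then clamped to `[0, 1]` and `gamma` to `>= 0` so the
#' initialization invariants hold).
#'
#' @param n Number of neurons.
#' @param tau,gamma,C,u_th,u_re Numeric, scalar or length-`n`.
#' @param hetero_sd Standard deviation of optional Gaussian perturbation
#'   applied to every field (0 = homogeneous init).
#' @param seed Integer seed used when `hetero_sd > 0`.
#' @return An object of class `neuron_params`: a list of the five vectors.
#' @examples
#' p <- neuron_params(3, tau = 0.5)
#' p$tau
#' @export
neuron_params <- function(n, tau = 0.5, gamma = 0.1, C = 1, u_th = 1,
                          u_re = 0, hetero_sd = 0, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  p <- list(
    tau   = rep_len(as.numeric(tau), n),
    gamma = rep_len(as.numeric(gamma), n),
    C     = rep_len(as.numeric(C), n),
    u_th  = rep_len(as.numeric(u_th), n),
    u_re  = rep_len(as.numeric(u_re), n)
  )
  if (hetero_sd > 0) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      set.seed(seed)
      on.exit(restore_seed(old), add = TRUE)
    }
    p <- lapply(p, function(v) v + stats::rnorm(n, sd = hetero_sd))
    p$tau <- pmin(pmax(p$tau, 0), 1)
    p$gamma <- pmax(p$gamma, 0)
    p$u_th <- pmax(p$u_th, p$u_re + 0.01)  # keep threshold above rest
  }
  structure(p, class = "neuron_params")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(list = ".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Validate neuron parameters
#'
#' Checks the initialization invariants (finiteness, `tau` in `[0,1]`,
#' `gamma >= 0`, `u_th > u_re`). Trained parameters may drift outside the
#' initialization box; this reports violations instead of erroring so it can
#' be used as a post-training audit.
#'
#' @param params A [neuron_params] object.
#' @param strict Error on violation instead of returning the report.
#' @return A tibble with one row per checked invariant (`check`, `ok`,
#'   `n_violations`), invisibly when `strict = TRUE`.
#' @export
validate_neuron_params <- function(params, strict = FALSE) {
  stopifnot(inherits(params, "neuron_params"))
  lens <- lengths(unclass(params))
  checks <- tibble::tibble(
    check = c("equal_lengths", "all_finite", "tau_in_unit_interval",
              "gamma_nonnegative", "u_th_above_u_re"),
    n_violations = c(
      as.integer(length(unique(lens)) > 1),
      sum(!vapply(params, function(v) all(is.finite(v)), logical(1))),
      sum(params$tau < 0 | params$tau > 1),
      sum(params$gamma < 0),
      sum(params$u_th <= params$u_re)
    )
  )
  checks$ok <- checks$n_violations == 0
  if (strict && !all(checks$ok)) {
    stop("invalid neuron_params: ",
         paste(checks$check[!checks$ok], collapse = ", "), call. = FALSE)
  }
  checks[, c("check", "ok", "n_violations")]
}

n_neurons <- function(params) length(params$tau)

#' Triangle surrogate-gradient specification
#'
#' During backpropagation the Heaviside spike function's derivative is
#' replaced by the triangle pseudo-derivative
#' `g(x) = (1/width) * max(0, 1 - |x|/width)` evaluated at `x = u - u_th`
#' (the pre-reset membrane potential minus the threshold). `width` is the
#' half-support of the triangle in membrane-potential (threshold) units; the
#' backward signal is exactly zero for `|x| >= width`.
#'
#' @param width Positive half-support, default 1 threshold unit.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(width = 1) {
  stopifnot(is.numeric(width), length(width) == 1, is.finite(width), width > 0)
  structure(list(width = width, shape = "triangle"), class = "surrogate_spec")
}

#' Triangle pseudo-derivative
#'
#' @param x Membrane potential minus threshold (any numeric array).
#' @param surrogate A [surrogate_spec].
#' @return `g(x)` evaluated elementwise.
#' @export
surrogate_grad <- function(x, surrogate = surrogate_spec()) {
  w <- surrogate$width
  (1 / w) * pmax(0, 1 - abs(x) / w)
}

# C1 ramp whose derivative is the triangle pseudo-derivative; used by the
# relaxed (soft-spike) forward pass so that surrogate backpropagation is the
# exact gradient of the relaxed computational graph.
surrogate_ramp <- function(x, surrogate = surrogate_spec()) {
  w <- surrogate$width
  y <- ifelse(x <= -w, 0,
       ifelse(x >= w, 1,
       ifelse(x < 0, (x + w)^2 / (2 * w^2), 1 - (w - x)^2 / (2 * w^2))))
  y
}

#' Weighted synaptic input
#'
#' The external stimulus of one neuron: the dot product of a row of synapse
#' weights with the presynaptic output vector, `S = sum_i w_i O_i`.
#'
#' @param W_row Numeric vector of synapse weights.
#' @param presyn_spikes Numeric (binary) vector of presynaptic outputs.
#' @return Scalar stimulus `S`.
#' @export
weighted_input <- function(W_row, presyn_spikes) {
  if (length(W_row) != length(presyn_spikes)) {
    stop("weighted_input: weight row and presynaptic vector differ in length (",
         length(W_row), " vs ", length(presyn_spikes), ")", call. = FALSE)
  }
  sum(W_row * presyn_spikes)
}

#' Autaptic self-inhibition
#'
#' The effective input current after self-inhibition: `I = S - gamma * o_prev`.
#' If the neuron did not fire at the previous step (`o_prev = 0`) the stimulus
#' passes through unchanged.
#'
#' @param S Stimulus (scalar or vector).
#' @param gamma Self-inhibition strength, `>= 0`.
#' @param o_prev Previous-step binary output, elementwise in `{0, 1}`.
#' @return Effective input current `I`.
#' @export
self_inhibit <- function(S, gamma, o_prev) {
  stopifnot(all(o_prev %in% c(0, 1)))
  S - gamma * o_prev
}

#' Membrane-potential update
#'
#' `u = f[(1 - tau) * u_prev + tau * u_re + C * I]` where `f` is the leaky
#' rectifier with negative slope `slope` (`f(x) = x` for `x >= 0`,
#' `slope * x` otherwise). `f` is applied to the full bracketed sum.
#'
#' @param u_prev Previous (post-reset) membrane potential.
#' @param params A [neuron_params] object (uses `tau`, `C`, `u_re`).
#' @param I Effective input current.
#' @param slope Leaky-rectifier negative slope in `(0, 1)`, default 0.01.
#' @return Updated membrane potential.
#' @export
membrane_update <- function(u_prev, params, I, slope = 0.01) {
  stopifnot(slope > 0, slope < 1)
  pre <- (1 - params$tau) * u_prev + params$tau * params$u_re + params$C * I
  u <- leaky_relu(pre, slope)
  if (any(!is.finite(u))) {
    stop("membrane_update: non-finite membrane potential at neuron index ",
         paste(which(!is.finite(u)), collapse = ", "), call. = FALSE)
  }
  u
}

leaky_relu <- function(x, slope) ifelse(x >= 0, x, slope * x)
leaky_relu_grad <- function(x, slope) ifelse(x >= 0, 1, slope)

#' Spike emission
#'
#' Heaviside comparison of membrane potential against threshold: a spike is
#' emitted iff `u - u_th > 0` strictly; exact equality does not spike.
#'
#' @param u Membrane potential.
#' @param u_th Threshold potential.
#' @return Binary output (0/1) of the same shape.
#' @export
fire <- function(u, u_th) {
  as.numeric(u - u_th > 0)
}

#' Post-spike hard reset
#'
#' `u' = (1 - O) * u + O * u_re`: firing forces the membrane potential back
#' to the resting potential exactly; otherwise the potential is held.
#'
#' @param u Membrane potential (pre-reset).
#' @param O Binary output of [fire].
#' @param u_re Resting potential.
#' @return Post-reset membrane potential.
#' @export
reset_potential <- function(u, O, u_re) {
  stopifnot(all(O %in% c(0, 1)))
  (1 - O) * u + O * u_re
}

#' Population state
#'
#' @param u Membrane-potential vector.
#' @param o_prev Binary previous-step output vector (same length).
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(u, o_prev = numeric(length(u))) {
  stopifnot(length(u) == length(o_prev), all(o_prev %in% c(0, 1)))
  structure(list(u = as.numeric(u), o_prev = as.numeric(o_prev)),
            class = "neuron_state")
}

#' One synchronous step of a neuron population
#'
#' Applies, per neuron, self-inhibition, the membrane update, threshold
#' comparison and the hard reset, returning the new state (with the membrane
#' already reset and `o_prev` set to the fresh output) together with the
#' binary output vector. The forward output is exactly binary; gradients,
#' where needed, use the triangle pseudo-derivative of `surrogate` at the
#' pre-reset membrane potential (see [surrogate_grad]).
#'
#' @param state A [neuron_state].
#' @param S Stimulus vector, one entry per neuron.
#' @param params A [neuron_params] of matching length.
#' @param surrogate A [surrogate_spec] (part of the step's backward
#'   contract; the forward pass does not use it).
#' @param slope Leaky-rectifier negative slope.
#' @return A list with `state` (new [neuron_state]), `O` (binary output) and
#'   `u_pre` (pre-reset membrane potential, the surrogate evaluation point).
#' @export
neuron_step <- function(state, S, params, surrogate = surrogate_spec(),
                        slope = 0.01) {
  stopifnot(inherits(state, "neuron_state"))
  n <- n_neurons(params)
  if (length(state$u) != n || length(S) != n) {
    stop("neuron_step: state/stimulus length does not match population size",
         call. = FALSE)
  }
  I <- self_inhibit(S, params$gamma, state$o_prev)
  u <- membrane_update(state$u, params, I, slope)
  O <- fire(u, params$u_th)
  u_post <- reset_potential(u, O, params$u_re)
  list(state = neuron_state(u_post, O), O = O, u_pre = u)
}

#' Simulate a neuron population driven by an injected current
#'
#' Iterates [neuron_step] over a current trace, with the current playing the
#' role of the stimulus `S(t)` directly (no synapses). The initial state is
#' `u = u_re`, `o_prev = 0`. Deterministic given its inputs.
#'
#' @param current Numeric vector (one neuron) or matrix `[neurons x T]` of
#'   injected current per time step.
#' @param params A [neuron_params].
#' @param surrogate A [surrogate_spec].
#' @param slope Leaky-rectifier negative slope.
#' @param dt_label Optional nominal step duration in ms, carried on the
#'   result for reporting only.
#' @return A [spike_train] `[neurons x T]`, with the membrane trace
#'   (pre-reset) attached as attribute `u_pre`.
#' @export
simulate_neuron <- function(current, params, surrogate = surrogate_spec(),
                            slope = 0.01, dt_label = NULL) {
  if (is.vector(current)) current <- matrix(current, nrow = 1)
  if (!is.matrix(current) || ncol(current) < 1) {
    stop("simulate_neuron: current trace must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(current))) {
    stop("simulate_neuron: current trace contains non-finite values",
         call. = FALSE)
  }
  n <- n_neurons(params)
  stopifnot(nrow(current) == n)
  TT <- ncol(current)
  st <- neuron_state(params$u_re, numeric(n))
  spikes <- matrix(0, n, TT)
  u_pre <- matrix(0, n, TT)
  for (t in seq_len(TT)) {
    step <- neuron_step(st, current[, t], params, surrogate, slope)
    st <- step$state
    spikes[, t] <- step$O
    u_pre[, t] <- step$u_pre
  }
  out <- spike_train(spikes, dt_label = dt_label)
  attr(out, "u_pre") <- u_pre
  out
}

#' Spike train container
#'
#' A binary `[neurons x time]` matrix with an optional nominal step duration
#' label (`dt_label`, ms) used only for reporting.
#'
#' @param spikes Binary matrix (or vector, treated as one neuron).
#' @param dt_label Optional nominal step duration in ms.
#' @return An object of class `spike_train` (a 0/1 matrix).
#' @export
spike_train <- function(spikes, dt_label = NULL) {
  if (is.vector(spikes)) spikes <- matrix(spikes, nrow = 1)
  stopifnot(is.matrix(spikes), ncol(spikes) >= 1)
  if (!all(spikes %in% c(0, 1))) {
    stop("spike_train: entries must be 0/1", call. = FALSE)
  }
  structure(spikes, class = c("spike_train", "matrix"),
            dt_label = dt_label)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d neuron(s) x %d step(s), %d spike(s)",
              nrow(x), ncol(x), sum(x)))
  if (!is.null(attr(x, "dt_label"))) {
    cat(sprintf(", dt = %g ms", attr(x, "dt_label")))
  }
  cat("\n")
  invisible(x)
}

#' Raster plot of a spike train
#'
#' @param object A [spike_train].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spike_train <- function(object, ...) {
  idx <- which(object == 1, arr.ind = TRUE)
  df <- tibble::tibble(neuron = idx[, 1], step = idx[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$neuron)) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time step", y = "neuron") +
    ggplot2::theme_minimal()
}
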