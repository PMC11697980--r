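#' Layered spiking-network architecture
#'
#' Describes a fully connected feed-forward spiking network: layer sizes
#' (input layer first), the number of unrolled time steps, how static inputs
#' are encoded into the time dimension and how the output layer is read out.
#'
#' Inter-layer timing: by default a layer at step `t` receives the output its
#' presynaptic layer computed at the same step (depth-synchronous
#' propagation, which is what makes very small `T` workable);
#' `delayed_interlayer = TRUE` instead delivers the presynaptic output of
#' step `t - 1`, the literal pipelined convention.
#'
#' @param layer_sizes Integer vector of at least two layer widths, e.g.
#'   `c(784, 250, 10)`.
#' @param time_steps Number of unrolled steps `T >= 1`.
#' @param encoding One of `"direct-current"` (analog drive repeated every
#'   step), `"poisson-rate"` (Bernoulli spikes with per-step probability
#'   proportional to the feature) or `"native-spikes"` (input is already a
#'   `[features x T]` spike array).
#' @param readout `"membrane-accumulate"` (default) or `"spike-count"`.
#'   Under membrane accumulation the output layer is a linear leaky
#'   integrator — no threshold, no reset, no rectifier — and the logits are
#'   its mean membrane potential over `T`; this keeps the readout signed and
#'   informative at tiny `T` and in the no-spike regime. Under spike-count the output layer runs the
#'   full spiking dynamics and logits are its summed spikes.
#' @param delayed_interlayer Use the one-step inter-layer delay.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(layer_sizes, time_steps = 5,
                         encoding = c("direct-current", "poisson-rate",
                                      "native-spikes"),
                         readout = c("membrane-accumulate", "spike-count"),
                         delayed_interlayer = FALSE) {
  encoding <- match.arg(encoding)
  readout <- match.arg(readout)
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1),
            time_steps >= 1)
  structure(list(layer_sizes = as.integer(layer_sizes),
                 time_steps = as.integer(time_steps),
                 encoding = encoding, readout = readout,
                 delayed_interlayer = isTRUE(delayed_interlayer)),
            class = "network_spec")
}

#' Initialize network parameters
#'
#' Synaptic weights are drawn from seeded Gaussians with He-style scale
#' `sqrt(2 / fan_in)`; every hidden/output neuron owns one set of biophysical
#' parameters (see [neuron_params]).
#'
#' @param spec A [network_spec].
#' @param seed Integer seed.
#' @param tau,gamma,C,u_th,u_re Initial biophysical values (scalars, shared
#'   across neurons before optional perturbation).
#' @param hetero_sd Gaussian perturbation of the biophysical init (0 =
#'   homogeneous initialization).
#' @param w_scale Multiplier on the He weight scale.
#' @return An object of class `network_params`: `W` (list of
#'   `[post x pre]` matrices) and `alphas` (list of [neuron_params], one per
#'   non-input layer).
#' @export
init_network_params <- function(spec, seed = 1, tau = 0.5, gamma = 0.1,
                                C = 1, u_th = 1, u_re = 0, hetero_sd = 0,
                                w_scale = 1) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(seed)
  sizes <- spec$layer_sizes
  K <- length(sizes) - 1
  W <- vector("list", K)
  alphas <- vector("list", K)
  for (k in seq_len(K)) {
    fan_in <- sizes[k]
    W[[k]] <- matrix(stats::rnorm(sizes[k + 1] * fan_in,
                                  sd = w_scale * sqrt(2 / fan_in)),
                     nrow = sizes[k + 1], ncol = fan_in)
    alphas[[k]] <- neuron_params(sizes[k + 1], tau = tau, gamma = gamma,
                                 C = C, u_th = u_th, u_re = u_re)
    if (hetero_sd > 0) {
      alphas[[k]] <- neuron_params(
        sizes[k + 1], tau = tau, gamma = gamma, C = C, u_th = u_th,
        u_re = u_re, hetero_sd = hetero_sd,
        seed = seed + 1000L + k)
    }
  }
  structure(list(W = W, alphas = alphas), class = "network_params")
}

#' Encode a static feature vector into an input sequence
#'
#' `direct-current` repeats the feature vector at every step (an analog
#' drive); `poisson-rate` draws seeded Bernoulli spikes with per-step
#' probability `x * dt_scale`, which must land in `[0, 1]`.
#'
#' @param x Nonnegative feature vector (or `[features x samples]` matrix).
#' @param T Number of time steps.
#' @param mode `"direct-current"` or `"poisson-rate"`.
#' @param seed Integer seed (poisson mode).
#' @param dt_scale Rate-to-probability scale for poisson mode.
#' @return A `[features x T]` matrix (or `[features x T x samples]` array).
#' @export
encode_static <- function(x, T, mode = c("direct-current", "poisson-rate"),
                          seed = 1, dt_scale = 1) {
  mode <- match.arg(mode)
  stopifnot(all(is.finite(x)), T >= 1)
  vec_in <- is.vector(x)
  if (vec_in) x <- matrix(x, ncol = 1)
  n <- nrow(x); B <- ncol(x)
  if (mode == "direct-current") {
    out <- array(0, dim = c(n, T, B))
    for (b in seq_len(B)) out[, , b] <- matrix(x[, b], n, T)
  } else {
    p <- x * dt_scale
    if (any(p < 0 | p > 1)) {
      stop("encode_static: poisson rates outside [0, 1] after scaling",
           call. = FALSE)
    }
    set.seed(seed)
    # per-(feature, step, sample) Bernoulli with probability p[feature, sample]
    p_arr <- aperm(array(p, dim = c(n, B, T)), c(1, 3, 2))
    out <- array(stats::rbinom(n * T * B, 1, as.vector(p_arr)),
                 dim = c(n, T, B))
  }
  if (vec_in) out[, , 1, drop = TRUE] else out
}

as_input_array <- function(input, spec) {
  # accepts [features x T] (single sample) or [features x T x B]
  if (inherits(input, "spike_train")) input <- unclass(input)
  if (is.matrix(input)) input <- array(input, dim = c(dim(input), 1))
  stopifnot(length(dim(input)) == 3)
  if (dim(input)[1] != spec$layer_sizes[1] ||
      dim(input)[2] != spec$time_steps) {
    stop("forward: input shape [", paste(dim(input), collapse = " x "),
         "] does not match spec (", spec$layer_sizes[1], " features x ",
         spec$time_steps, " steps)", call. = FALSE)
  }
  input
}

#' Unrolled forward pass of a heterogeneous spiking network
#'
#' Runs the network over all `T` steps for a batch of input sequences,
#' recording per-layer spike trains, logits under the spec's readout, and
#' spike / synaptic-operation totals. States are initialized at
#' `u = u_re`, `o_prev = 0` and are per-sample (no cross-sample leakage).
#'
#' The synaptic-operation count is event-driven: each presynaptic spike
#' contributes its fan-out in accumulate operations; a `direct-current`
#' front end instead performs dense multiply–accumulates into the first
#' layer at every step (counted separately as `front_end_macs`).
#'
#' @param spec A [network_spec].
#' @param params A [network_params].
#' @param input `[features x T]` matrix or `[features x T x batch]` array
#'   (real-valued for direct-current, binary otherwise).
#' @param surrogate A [surrogate_spec] (backward contract; forward output is
#'   binary regardless).
#' @param slope Leaky-rectifier negative slope.
#' @param record_trains Keep per-layer spike trains (lists over layers of
#'   `[neurons x T x batch]` arrays).
#' @return An object of class `forward_record`: `logits`
#'   (`[classes x batch]`), `spike_trains`, `total_spikes`, `synops`,
#'   `front_end_macs`, and the cached intermediates needed for
#'   backpropagation (internal).
#' @export
snn_forward <- function(spec, params, input, surrogate = surrogate_spec(),
                        slope = 0.01, record_trains = TRUE) {
  fwd <- snn_forward_engine(spec, params, input, surrogate, slope,
                            relaxed = FALSE, keep_cache = FALSE,
                            record_trains = record_trains)
  fwd
}

# Shared forward engine. relaxed = TRUE replaces the binary spike output fed
# downstream (and into next-step self-inhibition) by the C1 surrogate ramp,
# while the reset gate stays hard; surrogate BPTT is then the exact gradient
# of this relaxed graph almost everywhere, which is what the
# finite-difference gradient checks probe.
snn_forward_engine <- function(spec, params, input, surrogate, slope,
                               relaxed = FALSE, keep_cache = FALSE,
                               record_trains = TRUE) {
  input <- as_input_array(input, spec)
  sizes <- spec$layer_sizes
  K <- length(sizes) - 1
  TT <- spec$time_steps
  B <- dim(input)[3]
  W <- params$W
  al <- params$alphas

  h <- lapply(seq_len(K), function(k) matrix(al[[k]]$u_re, sizes[k + 1], B))
  o_prev <- lapply(seq_len(K), function(k) matrix(0, sizes[k + 1], B))
  # o_interlayer: value of layer k's output available to layer k+1
  o_delay <- o_prev

  trains <- if (record_trains) {
    lapply(seq_len(K), function(k) array(0, dim = c(sizes[k + 1], TT, B)))
  } else NULL
  cache <- if (keep_cache) vector("list", TT) else NULL

  logits_acc <- matrix(0, sizes[K + 1], B)
  total_spikes <- 0
  synops <- 0
  front_end_macs <- 0

  for (t in seq_len(TT)) {
    x_t <- matrix(input[, t, ], nrow = sizes[1], ncol = B)
    below <- x_t
    step_cache <- if (keep_cache) vector("list", K) else NULL
    for (k in seq_len(K)) {
      o_in <- if (k == 1) below else {
        if (spec$delayed_interlayer) o_delay[[k - 1]] else below
      }
      S <- W[[k]] %*% o_in
      # operation accounting (event-driven vs dense front end)
      if (k == 1 && spec$encoding == "direct-current") {
        front_end_macs <- front_end_macs + nrow(W[[k]]) * ncol(W[[k]]) * B
      } else {
        synops <- synops + sum(o_in != 0) * nrow(W[[k]])
      }
      op <- o_prev[[k]]
      I <- S - al[[k]]$gamma * op
      h_prev <- h[[k]]
      pre <- (1 - al[[k]]$tau) * h_prev + al[[k]]$tau * al[[k]]$u_re +
        al[[k]]$C * I
      integrating <- k == K && spec$readout == "membrane-accumulate"
      u <- if (integrating) pre else leaky_relu(pre, slope)
      if (any(!is.finite(u))) {
        stop("forward: non-finite membrane potential in layer ", k,
             " at step ", t, call. = FALSE)
      }
      x_th <- u - al[[k]]$u_th
      if (integrating) {
        # integrating readout layer: no threshold, no reset
        G <- matrix(0, nrow(u), ncol(u))
        O <- G
      } else {
        G <- (x_th > 0) * 1        # hard reset gate
        O <- if (relaxed) surrogate_ramp(x_th, surrogate) else G
      }
      h[[k]] <- (1 - G) * u + G * al[[k]]$u_re
      if (keep_cache) {
        step_cache[[k]] <- list(o_in = o_in, op = op, I = I,
                                h_prev = h_prev, pre = pre, u = u,
                                x_th = x_th, G = G, O = O)
      }
      if (record_trains) trains[[k]][, t, ] <- G
      total_spikes <- total_spikes + sum(G)
      if (k == K) {
        logits_acc <- logits_acc +
          (if (spec$readout == "membrane-accumulate") u else O)
      }
      o_prev[[k]] <- O
      below <- O
    }
    if (spec$delayed_interlayer) o_delay <- o_prev
    if (keep_cache) cache[[t]] <- step_cache
  }

  logits <- if (spec$readout == "membrane-accumulate") logits_acc / TT
            else logits_acc
  out_spikes <- if (record_trains) trains[[K]] else NULL
  structure(list(logits = logits,
                 spike_trains = trains,
                 output_spikes = out_spikes,
                 total_spikes = total_spikes,
                 synops = synops,
                 front_end_macs = front_end_macs,
                 n_batch = B,
                 spec = spec,
                 relaxed = relaxed,
                 cache = cache),
            class = "forward_record")
}

#' @export
print.forward_record <- function(x, ...) {
  cat(sprintf(paste0("<forward_record> %d sample(s), %d step(s), ",
                     "%d spike(s), %d synaptic op(s)\n"),
              x$n_batch, x$spec$time_steps, x$total_spikes, x$synops))
  invisible(x)
}

#' Task loss of a forward record
#'
#' Classification: softmax cross-entropy of the logits against integer class
#' labels in `1..K` (mean over the batch), with optional per-class weights.
#' Generation: mean squared error between the output layer's spike train and
#' a target spike train of the same shape.
#'
#' @param record A [forward_record] (or a logits matrix for classification).
#' @param target Integer labels (classification) or a `[neurons x T x batch]`
#'   binary array / [spike_train] (generation).
#' @param task `"classification"` or `"generation"`.
#' @param class_weights Optional numeric vector of per-class loss weights.
#' @return Scalar loss.
#' @export
snn_loss <- function(record, target, task = c("classification", "generation"),
                     class_weights = NULL) {
  task <- match.arg(task)
  if (task == "classification") {
    logits <- if (inherits(record, "forward_record")) record$logits else record
    if (is.vector(logits)) logits <- matrix(logits, ncol = 1)
    target <- as.integer(target)
    if (any(target < 1 | target > nrow(logits))) {
      stop("snn_loss: label out of range", call. = FALSE)
    }
    p <- softmax_cols(logits)
    w <- if (is.null(class_weights)) rep(1, length(target))
         else class_weights[target]
    ll <- -log(pmax(p[cbind(target, seq_along(target))], 1e-12))
    sum(w * ll) / sum(w)
  } else {
    gen <- if (inherits(record, "forward_record")) record$output_spikes
           else record
    tgt <- as_target_array(target, dim(gen))
    mean((gen - tgt)^2)
  }
}

as_target_array <- function(target, dims) {
  if (inherits(target, "spike_train")) target <- unclass(target)
  if (is.matrix(target)) target <- array(target, dim = c(dim(target), 1))
  if (!identical(dim(target), dims)) {
    stop("snn_loss: generated and template shapes differ", call. = FALSE)
  }
  target
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Per-neuron biophysics summary for histogram export
#'
#' Exports, for every hidden/output neuron, the trained (or initial)
#' biophysical parameters together with the derived membrane time constant.
#' Under the per-step decay convention `u <- (1 - tau) u`, a nominal step
#' duration `dt_label` (ms) maps to the continuous-time constant
#' `MTC = -dt_label / log(1 - tau)` (infinite at `tau = 0`, one-step decay
#' as `tau -> 1`).
#'
#' @param params A [network_params] (or a single [neuron_params]).
#' @param dt_label Nominal step duration in ms, default 1.
#' @return A tibble with columns `layer`, `neuron`, `tau`, `gamma`, `C`,
#'   `u_th`, `u_re`, `mtc_ms`.
#' @export
spike_histograms <- function(params, dt_label = 1) {
  alphas <- if (inherits(params, "network_params")) params$alphas
            else list(params)
  purrr::map_dfr(seq_along(alphas), function(k) {
    a <- alphas[[k]]
    tibble::tibble(
      layer = k, neuron = seq_along(a$tau),
      tau = a$tau, gamma = a$gamma, C = a$C,
      u_th = a$u_th, u_re = a$u_re,
      mtc_ms = ifelse(a$tau <= 0, Inf, -dt_label / log(1 - a$tau))
    )
  })
}
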