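# Independent reference implementations used as oracles. These are written
# as plain scalar loops over the defining equations, deliberately sharing no
# code with the package's vectorized engine.

# Scalar reference for one neuron over one time step.
oracle_step <- function(u_prev, o_prev, S, tau, gamma, C, u_th, u_re,
                        slope = 0.01) {
  I <- S - gamma * o_prev
  pre <- (1 - tau) * u_prev + tau * u_re + C * I
  u <- if (pre >= 0) pre else slope * pre
  O <- if (u - u_th > 0) 1 else 0
  u_post <- if (O == 1) u_re else u
  list(u_pre = u, O = O, u_post = u_post)
}

# Scalar reference simulator for a population driven by per-neuron currents.
oracle_simulate <- function(current, tau, gamma, C, u_th, u_re,
                            slope = 0.01) {
  n <- nrow(current); TT <- ncol(current)
  spikes <- matrix(0, n, TT)
  u_pre <- matrix(0, n, TT)
  for (i in seq_len(n)) {
    u <- u_re[i]; o <- 0
    for (t in seq_len(TT)) {
      st <- oracle_step(u, o, current[i, t], tau[i], gamma[i], C[i],
                        u_th[i], u_re[i], slope)
      spikes[i, t] <- st$O
      u_pre[i, t] <- st$u_pre
      u <- st$u_post; o <- st$O
    }
  }
  list(spikes = spikes, u_pre = u_pre)
}

# Brute-force synaptic-operation counter for a forward record: every nonzero
# presynaptic value into a spiking layer contributes its fan-out.
oracle_synops <- function(spec, params, input, record) {
  trains <- record$spike_trains
  K <- length(params$W)
  TT <- spec$time_steps
  B <- dim(input)[3]
  total <- 0
  for (t in seq_len(TT)) for (k in seq_len(K)) for (b in seq_len(B)) {
    o_in <- if (k == 1) input[, t, b] else trains[[k - 1]][, t, b]
    if (k == 1 && spec$encoding == "direct-current") next
    total <- total + sum(o_in != 0) * nrow(params$W[[k]])
  }
  total
}

# Quadratic/cubic toy bi-level objectives with closed-form gradients, used
# to verify the hypergradient core. W in R^2, alpha in R^3.
toy_fns <- function() {
  A <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  Bm <- matrix(c(1, -1, 0.5, 0.2, 0.3, -0.4), 2, 3)
  # L_t = 0.5 W'AW + W'B alpha + quartic coupling c * W1^3 * alpha1, so the
  # alpha-gradient is cubic in W and central differences carry an O(eps^2)
  # truncation error that the convergence tests can observe
  cc <- 0.3
  list(
    L_t = function(W, a) {
      0.5 * sum(W * (A %*% W)) + sum(W * (Bm %*% a)) + cc * W[1]^3 * a[1]
    },
    grad_W_t = function(W, a) {
      as.numeric(A %*% W + Bm %*% a) + c(3 * cc * W[1]^2 * a[1], 0)
    },
    grad_alpha_t = function(W, a) {
      as.numeric(crossprod(Bm, W)) + c(cc * W[1]^3, 0, 0)
    },
    # mixed second derivative d^2 L_t / d alpha dW applied to vector v:
    # rows alpha, cols W
    hess_alphaW_times = function(W, a, v) {
      H <- t(Bm)                      # [3 x 2]
      H[1, 1] <- H[1, 1] + 3 * cc * W[1]^2
      as.numeric(H %*% v)
    },
    # L_u = 0.5 ||W - w0||^2 + 0.5 ||alpha - a0||^2 + W' C alpha
    w0 = c(1, -2), a0 = c(0.5, 0, -1),
    Cm = matrix(c(0.2, -0.1, 0.4, 0, -0.3, 0.1), 2, 3),
    grad_W_u = function(W, a, w0 = c(1, -2),
                        Cm = matrix(c(0.2, -0.1, 0.4, 0, -0.3, 0.1), 2, 3)) {
      (W - w0) + as.numeric(Cm %*% a)
    },
    grad_alpha_u = function(W, a, a0 = c(0.5, 0, -1),
                            Cm = matrix(c(0.2, -0.1, 0.4, 0, -0.3, 0.1),
                                        2, 3)) {
      (a - a0) + as.numeric(crossprod(Cm, W))
    })
}

# Small deterministic network fixture used across tests.
tiny_net <- function(seed = 7, T = 3, readout = "membrane-accumulate",
                     hetero_sd = 0.1) {
  spec <- network_spec(c(2, 3, 2), time_steps = T,
                       encoding = "direct-current", readout = readout)
  params <- init_network_params(spec, seed = seed, hetero_sd = hetero_sd)
  set.seed(seed + 1)
  B <- 4
  input <- array(stats::runif(2 * T * B), dim = c(2, T, B))
  target <- rep(1:2, length.out = B)
  list(spec = spec, params = params, input = input, target = target)
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  denom <- max(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected)) / denom, tol)
}
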