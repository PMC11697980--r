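#' Squared van Rossum distance between spike trains
#'
#' Both trains are convolved with a causal exponential kernel of time
#' constant `vr_tau` steps and the mean squared difference of the filtered
#' traces is returned. This is the smoothed spike-train distance used as the
#' single-neuron fitting loss; it is differentiable in the (relaxed) spike
#' values, unlike a raw coincidence count.
#'
#' @param a,b `[neurons x T]` matrices (or vectors) of spikes.
#' @param vr_tau Kernel time constant in steps.
#' @return Scalar distance (0 iff the trains coincide).
#' @export
van_rossum_distance <- function(a, b, vr_tau = 20) {
  if (is.vector(a)) a <- matrix(a, nrow = 1)
  if (is.vector(b)) b <- matrix(b, nrow = 1)
  a <- unclass(a); b <- unclass(b)
  stopifnot(identical(dim(a), dim(b)))
  van_rossum_residual(a, b, vr_tau)$loss
}

#' Fit the biophysical parameters of a single neuron to recorded spikes
#'
#' Gradient-based minimization of the van Rossum distance between the spike
#' train simulated from an injected current and a recorded target train.
#' The forward simulation is the exact binary dynamics; descent directions
#' come from surrogate backpropagation (triangle pseudo-derivative), so at a
#' perfect reproduction the loss — and hence the update — is exactly zero.
#'
#' All restarts are fitted simultaneously as one neuron population driven by
#' the same current (their gradients are independent because the neurons are
#' unconnected); the restart with the lowest final distance is returned.
#'
#' @param current Injected current: vector of length `T`, or a
#'   `[trials x T]` matrix of per-trial traces.
#' @param target A [spike_train] (or 0/1 matrix/vector) of the same shape.
#' @param init Named list of starting biophysical values (defaults
#'   `tau = 0.5, gamma = 0.1, C = 1, u_th = 1, u_re = 0`). Restart 1 starts
#'   exactly at `init`; later restarts perturb it multiplicatively by
#'   seeded `U(0.5, 1.5)` factors (additively for fields at zero).
#' @param restarts Number of restarts.
#' @param iters Adam iterations.
#' @param lr Adam learning rate.
#' @param vr_tau Van Rossum kernel time constant in steps (default 20, twice
#'   the default similarity-evaluation window).
#' @param width Triangle surrogate half-width used during fitting.
#' @param fix Named list of fields to hold fixed (e.g. `list(gamma = 0)`
#'   fits a plain LIF neuron for ablation).
#' @param seed Integer seed (restart perturbations only; the fit itself is
#'   deterministic).
#' @param slope Leaky-rectifier negative slope.
#' @return An object of class `neuron_fit`: `params` (best restart's
#'   [neuron_params]), `distance` (its final van Rossum distance),
#'   `restart_distances`, `history` (per-iteration mean loss tibble),
#'   `no_spikes` flag, `md_star` (similarity of simulated vs target trains
#'   at the default window when `>= 2` trials are available, else `NA`) and
#'   the fitted `spikes`.
#' @export
fit_single_neuron <- function(current, target, init = list(),
                              restarts = 5, iters = 200, lr = 0.02,
                              vr_tau = 20, width = 1, fix = list(),
                              seed = 1, slope = 0.01) {
  if (is.vector(current)) current <- matrix(current, nrow = 1)
  if (inherits(target, "spike_train")) target <- unclass(target)
  if (is.vector(target)) target <- matrix(target, nrow = 1)
  stopifnot(identical(dim(current), dim(target)),
            all(target %in% c(0, 1)), nrow(current) >= 1)
  n_trials <- nrow(current)
  TT <- ncol(current)
  R <- as.integer(restarts)

  defaults <- list(tau = 0.5, gamma = 0.1, C = 1, u_th = 1, u_re = 0)
  init <- utils::modifyList(defaults, init)
  set.seed(seed)
  a <- neuron_params(R, tau = init$tau, gamma = init$gamma, C = init$C,
                     u_th = init$u_th, u_re = init$u_re)
  if (R > 1) {
    for (f in alpha_fields) {
      fac <- stats::runif(R - 1, 0.5, 1.5)
      base <- a[[f]][-1]
      a[[f]][-1] <- ifelse(base == 0, fac - 1, base * fac)
    }
    a$tau <- pmin(pmax(a$tau, 0.02), 0.98)
  }
  for (f in names(fix)) a[[f]][] <- fix[[f]]

  spec <- network_spec(c(1, R), time_steps = TT,
                       encoding = "direct-current", readout = "spike-count")
  params <- structure(list(W = list(matrix(1, R, 1)), alphas = list(a)),
                      class = "network_params")
  input <- array(t(current), dim = c(1, TT, n_trials))
  tgt <- array(0, dim = c(R, TT, n_trials))
  for (b in seq_len(n_trials)) {
    tgt[, , b] <- matrix(target[b, ], R, TT, byrow = TRUE)
  }
  sur <- surrogate_spec(width)

  # Adam over the five per-restart parameter fields
  m <- zero_alpha_grad(params$alphas)
  v <- zero_alpha_grad(params$alphas)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  hist_loss <- numeric(iters)
  for (it in seq_len(iters)) {
    g <- snn_grad(spec, params, input, tgt, task = "vanrossum",
                  surrogate = sur, slope = slope, vr_tau = vr_tau)
    ga <- g$galpha
    for (f in names(fix)) ga[[1]][[f]][] <- 0
    for (f in alpha_fields) {
      m[[1]][[f]] <- b1 * m[[1]][[f]] + (1 - b1) * ga[[1]][[f]]
      v[[1]][[f]] <- b2 * v[[1]][[f]] + (1 - b2) * ga[[1]][[f]]^2
      mh <- m[[1]][[f]] / (1 - b1^it)
      vh <- v[[1]][[f]] / (1 - b2^it)
      params$alphas[[1]][[f]] <- params$alphas[[1]][[f]] -
        lr * mh / (sqrt(vh) + adam_eps)
    }
    params$alphas <- project_alphas(params$alphas)
    for (f in names(fix)) params$alphas[[1]][[f]][] <- fix[[f]]
    hist_loss[it] <- g$loss
  }

  # score each restart on the exact binary simulation
  a_fit <- params$alphas[[1]]
  dist_r <- numeric(R)
  sims <- vector("list", R)
  for (r in seq_len(R)) {
    pr <- neuron_params(1, tau = a_fit$tau[r], gamma = a_fit$gamma[r],
                        C = a_fit$C[r], u_th = a_fit$u_th[r],
                        u_re = a_fit$u_re[r])
    sim <- matrix(0, n_trials, TT)
    for (b in seq_len(n_trials)) {
      sim[b, ] <- simulate_neuron(current[b, ], pr, sur, slope)[1, ]
    }
    sims[[r]] <- sim
    dist_r[r] <- van_rossum_distance(sim, target, vr_tau)
  }
  best <- which.min(dist_r)
  best_params <- neuron_params(1, tau = a_fit$tau[best],
                               gamma = a_fit$gamma[best], C = a_fit$C[best],
                               u_th = a_fit$u_th[best],
                               u_re = a_fit$u_re[best])
  no_spikes <- sum(sims[[best]]) == 0
  if (no_spikes) {
    warning("fit_single_neuron: fitted model emits no spikes")
  }
  md <- NA_real_
  if (n_trials >= 2 && sum(sims[[best]]) > 0 && sum(target) > 0) {
    set_sim <- lapply(seq_len(n_trials),
                      function(b) spike_train(sims[[best]][b, ]))
    set_tgt <- lapply(seq_len(n_trials),
                      function(b) spike_train(target[b, ]))
    md <- md_star(set_sim, set_tgt, window = 10)
  }
  structure(list(params = best_params, distance = dist_r[best],
                 restart_distances = dist_r, best_restart = best,
                 history = tibble::tibble(iter = seq_len(iters),
                                          loss = hist_loss),
                 no_spikes = no_spikes, md_star = md,
                 spikes = spike_train(sims[[best]])),
            class = "neuron_fit")
}

#' @export
print.neuron_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<neuron_fit> best of %d restart(s): tau = %.3f, ",
                     "gamma = %.3f, C = %.3f, u_th = %.3f, u_re = %.3f\n"),
              length(x$restart_distances), p$tau, p$gamma, p$C, p$u_th,
              p$u_re))
  cat(sprintf("  van Rossum distance %.4g%s\n", x$distance,
              if (x$no_spikes) " [no spikes]" else ""))
  invisible(x)
}

#' Tidy fitted single-neuron parameters
#'
#' @param x A `neuron_fit`.
#' @param ... Unused.
#' @return A one-row tibble of the fitted biophysical parameters.
#' @export
tidy.neuron_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(tau = p$tau, gamma = p$gamma, C = p$C, u_th = p$u_th,
                 u_re = p$u_re)
}

#' @export
glance.neuron_fit <- function(x, ...) {
  tibble::tibble(distance = x$distance, md_star = x$md_star,
                 best_restart = x$best_restart, no_spikes = x$no_spikes)
}
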