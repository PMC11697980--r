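test_that("single-step primitives follow the membrane equations", {
  # weighted input is a plain dot product
  expect_equal(weighted_input(c(0.5, -0.2, 1.0), c(1, 0, 1)), 1.5)
  expect_equal(weighted_input(rnorm(10), rep(0, 10)), 0)
  expect_error(weighted_input(1:3, 1:2), "length")
  set.seed(1)
  w <- rnorm(50); o <- rbinom(50, 1, 0.5)
  s_loop <- 0
  for (i in 1:50) s_loop <- s_loop + w[i] * o[i]
  expect_equal(weighted_input(w, o), s_loop)

  # self-inhibition subtracts gamma only after a spike
  expect_equal(self_inhibit(2.5, 0.2, 1), 2.3)
  expect_equal(self_inhibit(2.5, 0.2, 0), 2.5)
  expect_equal(self_inhibit(0, 5, 1), -5)

  # membrane update: leak, rest and gain composed under the leaky rectifier
  p <- neuron_params(1, tau = 0.5, gamma = 0, C = 1, u_th = 1, u_re = 0)
  expect_equal(membrane_update(0.8, p, 0), 0.4)
  expect_equal(membrane_update(0, p, -1, slope = 0.01), -0.01)
  p2 <- neuron_params(1, tau = 1, u_re = 0.3)
  expect_equal(membrane_update(5, p2, 0), 0.3)  # full decay to rest

  # strict-threshold firing: ties do not spike
  expect_equal(fire(2.3, 1), 1)
  expect_equal(fire(1.0, 1.0), 0)
  expect_equal(fire(-0.5, 1), 0)

  # hard reset
  expect_equal(reset_potential(2.3, 1, 0), 0)
  expect_equal(reset_potential(0.4, 0, 0), 0.4)
  expect_equal(reset_potential(2.3, 1, -0.1), -0.1)
})

test_that("neuron_step composes the primitives with post-step state", {
  p <- neuron_params(1, tau = 0.5, gamma = 0.2, C = 1, u_th = 1, u_re = 0)
  st <- neuron_state(0, 0)
  out <- neuron_step(st, 2.5, p)
  expect_equal(out$O, 1)
  expect_equal(out$state$u, 0)       # reset applied
  expect_equal(out$state$o_prev, 1)
  out2 <- neuron_step(neuron_state(0, 1), 1.1, p)
  expect_equal(out2$O, 0)
  expect_equal(out2$state$u, 0.9)    # I = 1.1 - 0.2 = 0.9
  expect_error(neuron_step(neuron_state(0, 0), c(1, 2), p), "length")
})

test_that("vectorized trajectories equal the scalar reference loop", {
  set.seed(10)
  n <- 200; TT <- 100
  p <- neuron_params(n, tau = runif(n), gamma = runif(n, 0, 1),
                     C = runif(n, 0.5, 1.5), u_th = runif(n, 0.5, 1.5),
                     u_re = runif(n, -0.3, 0.3))
  current <- matrix(rnorm(n * TT, 0.5, 0.8), n, TT)
  sim <- simulate_neuron(current, p)
  orc <- oracle_simulate(current, p$tau, p$gamma, p$C, p$u_th, p$u_re)
  expect_equal(unclass(sim), orc$spikes, ignore_attr = TRUE)
  expect_rel_equal(attr(sim, "u_pre"), orc$u_pre, tol = 1e-6)
  # binarity and hard-reset invariants on the same trajectories
  expect_true(all(sim %in% c(0, 1)))
})

test_that("hard reset stores u_re exactly wherever a spike is emitted", {
  set.seed(11)
  n <- 20; TT <- 200
  p <- neuron_params(n, tau = 0.4, gamma = 0.3, u_re = -0.1)
  current <- matrix(rnorm(n * TT, 0.6, 0.6), n, TT)
  st <- neuron_state(p$u_re, numeric(n))
  for (t in seq_len(TT)) {
    out <- neuron_step(st, current[, t], p)
    fired <- out$O == 1
    if (any(fired)) {
      expect_identical(out$state$u[fired], p$u_re[fired])
    }
    st <- out$state
  }
})

test_that("with gamma = 0 the positive-branch dynamics reduce to LIF", {
  # constructed input keeps the bracketed sum nonnegative throughout
  TT <- 60
  tau <- 0.3; C <- 0.9; u_re <- 0.1; u_th <- 5
  current <- rep(0.8, TT)
  p <- neuron_params(1, tau = tau, gamma = 0, C = C, u_th = u_th,
                     u_re = u_re)
  sim <- simulate_neuron(current, p)
  u <- attr(sim, "u_pre")[1, ]
  ulif <- numeric(TT)
  prev <- u_re
  for (t in seq_len(TT)) {
    ulif[t] <- (1 - tau) * prev + tau * u_re + C * current[t]
    prev <- ulif[t]
  }
  expect_equal(u, ulif, tolerance = 1e-12)
  expect_equal(sum(sim), 0)
})

test_that("constant suprathreshold drive with gamma = 0 spikes periodically", {
  # between spikes u follows the LIF recursion from u_re; the period is the
  # first-passage time of that closed-form recursion over u_th
  tau <- 0.5; C <- 1; u_th <- 1; u_re <- 0; S <- 0.7
  p <- neuron_params(1, tau = tau, gamma = 0, C = C, u_th = u_th,
                     u_re = u_re)
  sim <- simulate_neuron(rep(S, 100), p)
  u <- u_re; period <- 0
  repeat {
    period <- period + 1
    u <- (1 - tau) * u + tau * u_re + C * S
    if (u - u_th > 0) break
  }
  times <- which(sim[1, ] == 1)
  expect_gt(length(times), 2)
  expect_true(all(diff(times) == period))
  expect_equal(times[1], period)
})

test_that("self-inhibition strictly lengthens inter-spike intervals", {
  S <- 0.8
  p0 <- neuron_params(1, tau = 0.5, gamma = 0)
  p1 <- neuron_params(1, tau = 0.5, gamma = 0.6)
  s0 <- simulate_neuron(rep(S, 200), p0)
  s1 <- simulate_neuron(rep(S, 200), p1)
  isi <- function(s) diff(which(s[1, ] == 1))
  expect_gt(min(isi(s1)), max(isi(s0)))
  # local monotonicity: with o_prev = 1, I strictly decreases in gamma
  gammas <- seq(0, 2, by = 0.25)
  I <- self_inhibit(1.5, gammas, 1)
  expect_true(all(diff(I) < 0))
})

test_that("triangle surrogate matches its analytic form and support", {
  sur <- surrogate_spec(width = 1)
  xs <- seq(-2, 2, by = 0.05)
  expect_equal(surrogate_grad(xs, sur), pmax(0, 1 - abs(xs)))
  expect_true(all(surrogate_grad(c(-1, 1, 5), sur) == 0))
  # the surrogate is the exact derivative of the relaxed spike ramp
  h <- 1e-6
  ramp_fd <- (hetsnn:::surrogate_ramp(xs + h, sur) -
                hetsnn:::surrogate_ramp(xs - h, sur)) / (2 * h)
  expect_equal(ramp_fd, surrogate_grad(xs, sur), tolerance = 1e-6)
  expect_error(surrogate_spec(0), "width")
})

test_that("parameter validation flags initialization violations", {
  p <- neuron_params(3)
  expect_true(all(validate_neuron_params(p)$ok))
  p$tau[2] <- 1.5
  p$u_th[1] <- -1
  rep <- validate_neuron_params(p)
  expect_false(rep$ok[rep$check == "tau_in_unit_interval"])
  expect_false(rep$ok[rep$check == "u_th_above_u_re"])
  expect_error(validate_neuron_params(p, strict = TRUE), "invalid")
  # heterogeneous init respects the constraint box
  ph <- neuron_params(500, hetero_sd = 0.5, seed = 3)
  expect_true(all(validate_neuron_params(ph)$ok))
})

test_that("simulate_neuron rejects degenerate traces and is deterministic", {
  p <- neuron_params(1)
  expect_error(simulate_neuron(matrix(numeric(0), 1, 0), p), "non-empty")
  expect_error(simulate_neuron(c(1, NA, 1), p), "non-finite")
  cur <- rnorm(50)
  expect_identical(unclass(simulate_neuron(cur, p)),
                   unclass(simulate_neuron(cur, p)))
  expect_equal(sum(simulate_neuron(rep(0, 50), p)), 0)
})
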