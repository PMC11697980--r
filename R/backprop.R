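# Backpropagation through time for the unrolled self-inhibiting network.
#
# Differentiation conventions (the "backward contract"):
#  * the Heaviside spike derivative is replaced by the triangle
#    pseudo-derivative g(x) at x = u - u_th, with u the PRE-reset membrane
#    potential;
#  * the hard reset u <- (1-O)u + O*u_re is treated as non-differentiated
#    gating: the gate value multiplies the flowing gradient ((1-O) on the
#    membrane path, O on the u_re path) but no derivative is taken of the
#    gate itself;
#  * all five biophysical parameters receive gradients through every step:
#    tau via the leak and rest terms, gamma via self-inhibition, C via the
#    input gain, u_th via the spike comparison, u_re via the rest term and
#    the reset path.
#
# With relaxed = TRUE the forward pass emits the C1 surrogate ramp instead of
# binary spikes (reset gate stays hard); the identical backward recursion is
# then the exact gradient of the relaxed graph almost everywhere, which is
# what the finite-difference checks verify.

zero_alpha_grad <- function(alphas) {
  lapply(alphas, function(a)
    lapply(unclass(a)[c("tau", "gamma", "C", "u_th", "u_re")],
           function(v) numeric(length(v))))
}

#' Loss and gradients of an unrolled spiking network
#'
#' Runs a forward pass with cached intermediates and backpropagates the task
#' loss through the unrolled dynamics, returning gradients with respect to
#' the synaptic weights and/or the per-neuron biophysical parameters.
#'
#' @param spec A [network_spec].
#' @param params A [network_params].
#' @param input `[features x T]` or `[features x T x batch]` input.
#' @param target Labels (classification), a binary target array
#'   (generation), or a `[T]`/`[neurons x T]` target for the van Rossum
#'   fitting loss.
#' @param task `"classification"`, `"generation"` or `"vanrossum"`.
#' @param surrogate A [surrogate_spec].
#' @param slope Leaky-rectifier negative slope.
#' @param relaxed Use the soft-spike (surrogate ramp) forward pass; the
#'   returned gradient is then the exact gradient of the relaxed loss.
#' @param class_weights Optional per-class loss weights (classification).
#' @param vr_tau Van Rossum kernel time constant in steps (vanrossum task).
#' @return A list: `loss`, `gW` (list like `params$W`), `galpha` (list of
#'   per-field gradient vectors per layer), `logits`.
#' @export
snn_grad <- function(spec, params, input, target,
                     task = c("classification", "generation", "vanrossum"),
                     surrogate = surrogate_spec(), slope = 0.01,
                     relaxed = FALSE, class_weights = NULL, vr_tau = 20) {
  task <- match.arg(task)
  fwd <- snn_forward_engine(spec, params, input, surrogate, slope,
                            relaxed = relaxed, keep_cache = TRUE,
                            record_trains = FALSE)
  sizes <- spec$layer_sizes
  K <- length(sizes) - 1
  TT <- spec$time_steps
  B <- fwd$n_batch
  W <- params$W
  al <- params$alphas
  cache <- fwd$cache

  # ---- loss and gradient at the readout -------------------------------
  out_O <- array(0, dim = c(sizes[K + 1], TT, B))
  for (t in seq_len(TT)) out_O[, t, ] <- cache[[t]][[K]]$O
  glogits <- NULL
  gO_out <- NULL   # [neurons x T x B] adjoint on output-layer spike values
  if (task == "classification") {
    logits <- fwd$logits
    target <- as.integer(target)
    p <- softmax_cols(logits)
    onehot <- matrix(0, nrow(logits), ncol(logits))
    onehot[cbind(target, seq_along(target))] <- 1
    w <- if (is.null(class_weights)) rep(1, length(target))
         else class_weights[target]
    loss <- {
      ll <- -log(pmax(p[cbind(target, seq_along(target))], 1e-12))
      sum(w * ll) / sum(w)
    }
    glogits <- sweep(p - onehot, 2, w / sum(w), "*")
  } else if (task == "generation") {
    tgt <- as_target_array(target, dim(out_O))
    loss <- mean((out_O - tgt)^2)
    gO_out <- 2 * (out_O - tgt) / length(out_O)
  } else { # vanrossum
    tgt <- as_target_array(target, dim(out_O))
    loss <- 0
    gO_out <- array(0, dim = dim(out_O))
    for (b in seq_len(B)) {
      vr <- van_rossum_residual(matrix(out_O[, , b], sizes[K + 1], TT),
                                matrix(tgt[, , b], sizes[K + 1], TT), vr_tau)
      loss <- loss + vr$loss / B
      gO_out[, , b] <- vr$gO / B
    }
  }

  # ---- backward recursion --------------------------------------------
  gW <- lapply(W, function(w) matrix(0, nrow(w), ncol(w)))
  gA <- zero_alpha_grad(al)
  gh <- lapply(seq_len(K), function(k) matrix(0, sizes[k + 1], B))
  cO <- gh  # adjoint on O^k(t) arriving from step t+1
  for (t in rev(seq_len(TT))) {
    gdown <- NULL  # adjoint on O^{k}(t) from layer k+1 within the same step
    new_gh <- vector("list", K)
    new_cO <- lapply(seq_len(K), function(k) matrix(0, sizes[k + 1], B))
    for (k in rev(seq_len(K))) {
      cc <- cache[[t]][[k]]
      a <- al[[k]]
      gO <- cO[[k]]
      if (k == K) {
        if (!is.null(gO_out)) gO <- gO + matrix(gO_out[, t, ],
                                                sizes[K + 1], B)
        if (task == "classification" && spec$readout == "spike-count") {
          gO <- gO + glogits
        }
      } else if (!is.null(gdown)) {
        gO <- gO + gdown
      }
      integrating <- k == K && spec$readout == "membrane-accumulate"
      g_tri <- if (integrating) 0 * cc$x_th
               else surrogate_grad(cc$x_th, surrogate)
      gu <- gO * g_tri + gh[[k]] * (1 - cc$G)
      if (k == K && task == "classification" &&
          spec$readout == "membrane-accumulate") {
        gu <- gu + glogits / TT
      }
      gA[[k]]$u_th <- gA[[k]]$u_th - rowSums(gO * g_tri)
      gA[[k]]$u_re <- gA[[k]]$u_re + rowSums(gh[[k]] * cc$G)
      gpre <- if (integrating) gu
              else gu * leaky_relu_grad(cc$pre, slope)
      gA[[k]]$tau   <- gA[[k]]$tau + rowSums(gpre * (a$u_re - cc$h_prev))
      gA[[k]]$u_re  <- gA[[k]]$u_re + rowSums(gpre) * a$tau
      gA[[k]]$C     <- gA[[k]]$C + rowSums(gpre * cc$I)
      gA[[k]]$gamma <- gA[[k]]$gamma - rowSums(gpre * cc$op) * a$C
      gS <- gpre * a$C
      gW[[k]] <- gW[[k]] + gS %*% t(cc$o_in)
      g_below <- crossprod(W[[k]], gS)
      if (k > 1) {
        if (spec$delayed_interlayer) {
          new_cO[[k - 1]] <- new_cO[[k - 1]] + g_below
          gdown <- NULL
        } else {
          gdown <- g_below
        }
      }
      new_gh[[k]] <- gpre * (1 - a$tau)
      new_cO[[k]] <- new_cO[[k]] - gpre * (a$C * a$gamma)
    }
    gh <- new_gh
    cO <- new_cO
  }
  # initial condition u(0) = u_re: the leftover adjoint on h(0) lands on u_re
  for (k in seq_len(K)) {
    gA[[k]]$u_re <- gA[[k]]$u_re + rowSums(gh[[k]])
  }
  list(loss = loss, gW = gW, galpha = gA, logits = fwd$logits)
}

# Squared van Rossum distance between a (possibly soft) output train and a
# binary target, both [neurons x T], with a causal exponential kernel of
# time constant vr_tau steps: L = mean_t,n e(t)^2 with
# e = kernel * (o - target). Returns the loss and dL/do.
van_rossum_residual <- function(o, target, vr_tau) {
  a <- exp(-1 / vr_tau)
  d <- o - target
  n <- nrow(d); TT <- ncol(d)
  e <- matrix(0, n, TT)
  for (i in seq_len(n)) {
    e[i, ] <- stats::filter(d[i, ], a, method = "recursive")
  }
  loss <- mean(e^2)
  # dL/de = 2e/(n*TT); dL/do(t) = sum_{s>=t} a^(s-t) dL/de(s): reverse filter
  ge <- 2 * e / length(e)
  gO <- matrix(0, n, TT)
  for (i in seq_len(n)) {
    gO[i, ] <- rev(stats::filter(rev(ge[i, ]), a, method = "recursive"))
  }
  list(loss = loss, gO = gO)
}

#' Flatten / restore weight lists and biophysical parameters
#'
#' Utilities mapping the structured parameter containers to flat numeric
#' vectors and back, used by the hypergradient core and by gradient checks.
#'
#' @param W List of weight matrices (or `galpha`-shaped gradient lists for
#'   the alpha variants).
#' @return `flatten_W`/`flatten_alpha` return numeric vectors;
#'   `unflatten_W`/`unflatten_alpha` restore the original structure from a
#'   flat vector and a template.
#' @export
flatten_W <- function(W) unlist(lapply(W, as.vector), use.names = FALSE)

#' @rdname flatten_W
#' @param flat Flat numeric vector.
#' @param template Object with the target structure.
#' @export
unflatten_W <- function(flat, template) {
  out <- template
  pos <- 0
  for (k in seq_along(template)) {
    n <- length(template[[k]])
    out[[k]] <- matrix(flat[pos + seq_len(n)], nrow(template[[k]]),
                       ncol(template[[k]]))
    pos <- pos + n
  }
  out
}

alpha_fields <- c("tau", "gamma", "C", "u_th", "u_re")

#' @rdname flatten_W
#' @param alphas List of [neuron_params] (or same-shaped gradient lists).
#' @export
flatten_alpha <- function(alphas) {
  unlist(lapply(alphas, function(a) unlist(unclass(a)[alpha_fields],
                                           use.names = FALSE)),
         use.names = FALSE)
}

#' @rdname flatten_W
#' @export
unflatten_alpha <- function(flat, template) {
  out <- template
  pos <- 0
  for (k in seq_along(template)) {
    n <- length(template[[k]]$tau)
    for (f in alpha_fields) {
      out[[k]][[f]] <- flat[pos + seq_len(n)]
      pos <- pos + n
    }
  }
  out
}
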