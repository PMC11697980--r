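#' Bi-level training configuration
#'
#' Collects the hyperparameters of heterogeneous learning: the network-level
#' weight loop minimizes the training loss on the sub-training split `D_t`,
#' while the neuron-level loop updates the biophysical parameters against the
#' validation loss on the orthogonal sub-validation split `D_v` plus a
#' graph-Laplacian smoothness penalty.
#'
#' @param xi1 Network-level (weight) learning rate, `> 0`.
#' @param xi2 Neuron-level (biophysics) learning rate, `>= 0`; `xi2 = 0`
#'   freezes the biophysics and reduces training to the homogeneous scheme
#'   in which only synaptic weights are learned.
#' @param lam Laplacian penalty weight `lambda >= 0`.
#' @param eps0 Base finite-difference scalar; the perturbation actually used
#'   is `eps0 / ||grad_W' L_u||` (standard normalization).
#' @param order `"first"` (default; drops the mixed second-order term, i.e.
#'   treats the one-step weight update as frozen) or `"second"` (full
#'   finite-difference hypergradient).
#' @param split_fraction Fraction of the data assigned to `D_t`.
#' @param alternation Weight (minibatch) steps per biophysics step; the
#'   special value 0 (default) runs one biophysics step per epoch.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (samples).
#' @param seed Integer seed controlling the split, batching and init.
#' @param slope Leaky-rectifier negative slope.
#' @param width Triangle surrogate half-width.
#' @param class_weights `NULL`, `"balanced"` (inverse-prevalence weights) or
#'   a numeric vector of per-class loss weights.
#' @return An object of class `bilevel_config`.
#' @export
bilevel_config <- function(xi1 = 0.1, xi2 = 0.05, lam = 0.01, eps0 = 0.01,
                           order = c("first", "second"),
                           split_fraction = 0.8, alternation = 0,
                           epochs = 30, batch_size = 32, seed = 1,
                           slope = 0.01, width = 1, class_weights = NULL) {
  order <- match.arg(order)
  stopifnot(xi1 >= 0, xi2 >= 0, lam >= 0, eps0 > 0,
            split_fraction > 0, split_fraction < 1, alternation >= 0,
            epochs >= 1)
  structure(list(xi1 = xi1, xi2 = xi2, lam = lam, eps0 = eps0,
                 order = order, split_fraction = split_fraction,
                 alternation = as.integer(alternation),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), slope = slope, width = width,
                 class_weights = class_weights),
            class = "bilevel_config")
}

#' Orthogonal sub-training / sub-validation split
#'
#' Disjoint, exhaustive, seeded partition of sample indices into the
#' sub-training set `D_t` (feeding the weight loop) and the orthogonal
#' sub-validation set `D_v` (feeding the biophysics loop), stratified by
#' label when labels are supplied. Classes too small to stratify (fewer than
#' 2 members) trigger a warning and a plain shuffled split.
#'
#' @param n Number of samples (or a vector/list whose length is used).
#' @param split_fraction Fraction assigned to `D_t`.
#' @param seed Integer seed.
#' @param labels Optional label vector for stratification.
#' @return A list with integer index vectors `train` and `val`.
#' @export
split_orthogonal <- function(n, split_fraction = 0.8, seed = 1,
                             labels = NULL) {
  if (length(n) > 1) n <- length(n)
  stopifnot(n >= 2, split_fraction > 0, split_fraction < 1)
  set.seed(seed)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    tab <- table(labels)
    if (any(tab < 2)) {
      warning("split_orthogonal: a class has < 2 samples; ",
              "falling back to a non-stratified split")
      labels <- NULL
    }
  }
  if (is.null(labels)) {
    idx <- sample.int(n)
    n_t <- max(1, min(n - 1, round(split_fraction * n)))
    return(list(train = sort(idx[seq_len(n_t)]),
                val = sort(idx[-seq_len(n_t)])))
  }
  train <- integer(0)
  for (cl in unique(labels)) {
    members <- sample(which(labels == cl))
    n_t <- max(1, min(length(members) - 1,
                      round(split_fraction * length(members))))
    train <- c(train, members[seq_len(n_t)])
  }
  list(train = sort(train), val = sort(setdiff(seq_len(n), train)))
}

#' Neighbor graph over the neurons of one layer
#'
#' The Laplacian penalty needs a notion of neighborhood among the neurons of
#' a dense layer. The default is a chain over neuron index (unit weights);
#' `"complete"` connects all pairs; `"knn"` connects each neuron to its `k`
#' nearest neighbors in biophysical-parameter space.
#'
#' @param n Number of neurons (or, for `"knn"`, a [neuron_params] object).
#' @param type `"chain"`, `"complete"` or `"knn"`.
#' @param k Number of neighbors for `"knn"`.
#' @return An object of class `neighbor_graph`: a tibble of undirected edges
#'   (`i`, `j`, `w`) with `i < j` and no self-loops.
#' @export
neighbor_graph <- function(n, type = c("chain", "complete", "knn"), k = 2) {
  type <- match.arg(type)
  params <- NULL
  if (inherits(n, "neuron_params")) { params <- n; n <- n_neurons(params) }
  edges <- switch(type,
    chain = if (n < 2) tibble::tibble(i = integer(0), j = integer(0))
            else tibble::tibble(i = seq_len(n - 1), j = seq_len(n - 1) + 1),
    complete = {
      pairs <- utils::combn(n, 2)
      tibble::tibble(i = pairs[1, ], j = pairs[2, ])
    },
    knn = {
      if (is.null(params)) {
        stop("neighbor_graph(type = 'knn') needs a neuron_params object",
             call. = FALSE)
      }
      X <- scale(do.call(cbind, unclass(params)[alpha_fields]))
      X[is.nan(X)] <- 0
      D <- as.matrix(stats::dist(X))
      diag(D) <- Inf
      ij <- do.call(rbind, lapply(seq_len(n), function(i) {
        cbind(i, order(D[i, ])[seq_len(min(k, n - 1))])
      }))
      tibble::tibble(i = pmin(ij[, 1], ij[, 2]),
                     j = pmax(ij[, 1], ij[, 2])) |> dplyr::distinct()
    })
  edges$w <- rep(1, nrow(edges))
  structure(list(edges = edges, n = n), class = "neighbor_graph")
}

#' Graph-Laplacian smoothness penalty on neuron parameters
#'
#' `Omega = sum_(i,j) w_ij * ||alpha~_i - alpha~_j||^2` over the edges of a
#' neighbor graph, where `alpha~` stacks the five per-neuron biophysical
#' fields divided by per-field scales. `Omega >= 0`, and `Omega = 0` iff all
#' connected neurons share identical parameters. The penalty encourages
#' neighboring neurons to keep similar intra-neuron systems; synaptic
#' weights are never penalized.
#'
#' @param alphas A [neuron_params] object (one layer).
#' @param graph A [neighbor_graph] over the same neurons.
#' @param scales Per-field positive scales used for standardization, in the
#'   order tau, gamma, C, u_th, u_re. Default all 1 (raw units).
#' @param grad Also return the gradient with respect to each field.
#' @return Scalar penalty, or (with `grad = TRUE`) a list `value`, `grad`.
#' @export
laplacian_penalty <- function(alphas, graph, scales = rep(1, 5),
                              grad = FALSE) {
  stopifnot(inherits(graph, "neighbor_graph"),
            n_neurons(alphas) >= graph$n)
  A <- do.call(cbind, unclass(alphas)[alpha_fields])
  A <- sweep(A, 2, scales, "/")
  e <- graph$edges
  if (nrow(e) == 0) {
    val <- 0
    if (!grad) return(val)
    return(list(value = 0, grad = lapply(unclass(alphas)[alpha_fields],
                                         function(v) numeric(length(v)))))
  }
  diffs <- A[e$i, , drop = FALSE] - A[e$j, , drop = FALSE]
  val <- sum(e$w * rowSums(diffs^2))
  if (!grad) return(val)
  G <- matrix(0, nrow(A), ncol(A))
  wd <- 2 * e$w * diffs
  for (r in seq_len(nrow(e))) {
    G[e$i[r], ] <- G[e$i[r], ] + wd[r, ]
    G[e$j[r], ] <- G[e$j[r], ] - wd[r, ]
  }
  G <- sweep(G, 2, scales, "/")
  gl <- stats::setNames(lapply(seq_len(5), function(f) G[, f]), alpha_fields)
  list(value = val, grad = gl)
}

# Penalty and gradient summed over all layers of a network_params object,
# with one graph per layer.
network_penalty <- function(alphas, graphs, scales = rep(1, 5),
                            grad = FALSE) {
  vals <- 0
  gl <- if (grad) zero_alpha_grad(alphas) else NULL
  for (k in seq_along(alphas)) {
    r <- laplacian_penalty(alphas[[k]], graphs[[k]], scales, grad = grad)
    if (grad) {
      vals <- vals + r$value
      for (f in alpha_fields) gl[[k]][[f]] <- gl[[k]][[f]] + r$grad[[f]]
    } else {
      vals <- vals + r
    }
  }
  if (grad) list(value = vals, grad = gl) else vals
}

#' Neuron-level objective
#'
#' The upper-level objective of heterogeneous learning: validation loss on
#' the orthogonal sub-validation data plus `lambda` times the Laplacian
#' smoothness penalty. With `lam = 0` this is exactly the validation loss.
#'
#' @param spec A [network_spec].
#' @param params A [network_params].
#' @param input_v,target_v Sub-validation inputs and targets.
#' @param lam Penalty weight.
#' @param graphs List of [neighbor_graph]s, one per non-input layer.
#' @param task,surrogate,slope,class_weights Passed to [snn_loss].
#' @return Scalar objective value.
#' @export
neuron_objective <- function(spec, params, input_v, target_v, lam = 0,
                             graphs = NULL,
                             task = "classification",
                             surrogate = surrogate_spec(), slope = 0.01,
                             class_weights = NULL) {
  if (length(target_v) == 0) stop("neuron_objective: empty validation set",
                                  call. = FALSE)
  rec <- snn_forward(spec, params, input_v, surrogate, slope,
                     record_trains = (task != "classification"))
  lv <- snn_loss(rec, target_v, task = task, class_weights = class_weights)
  pen <- if (lam > 0) {
    if (is.null(graphs)) graphs <- default_graphs(params)
    lam * network_penalty(params$alphas, graphs)
  } else 0
  lv + pen
}

default_graphs <- function(params) {
  lapply(params$alphas, function(a) neighbor_graph(n_neurons(a)))
}

#' One network-level weight step
#'
#' `W <- W - xi1 * grad_W L_t(D_t; W, alpha)` with the biophysical
#' parameters held fixed; the gradient flows through the unrolled network
#' via the triangle pseudo-derivative. Only the weights change.
#'
#' @param spec,params Network architecture and parameters.
#' @param input,target A sub-training batch.
#' @param xi1 Learning rate.
#' @param task,surrogate,slope,class_weights Loss options.
#' @return The updated [network_params].
#' @export
network_step <- function(spec, params, input, target, xi1,
                         task = "classification",
                         surrogate = surrogate_spec(), slope = 0.01,
                         class_weights = NULL) {
  g <- snn_grad(spec, params, input, target, task = task,
                surrogate = surrogate, slope = slope,
                class_weights = class_weights)
  if (any(!vapply(g$gW, function(m) all(is.finite(m)), logical(1)))) {
    stop("network_step: non-finite weight gradient (loss = ", g$loss, ")",
         call. = FALSE)
  }
  params$W <- purrr::map2(params$W, g$gW, function(w, gw) w - xi1 * gw)
  params
}

#' Hypergradient core over flat parameter vectors
#'
#' Computes the gradient of the upper-level objective with respect to the
#' outer variables `alpha`, treating the inner weight problem through its
#' one-step update. With `order = "first"` the mixed second-order term is
#' dropped (equivalently the inner learning rate is set to zero inside the
#' chain rule) and the result is plainly `grad_alpha L_u(W, alpha)`. With
#' `order = "second"`:
#' `W' = W - xi1 * grad_W L_t(W, alpha)`, then
#' `grad_alpha L_u(W', alpha) - xi1 * (grad_alpha L_t(W+, alpha) -
#'  grad_alpha L_t(W-, alpha)) / (2 eps)` with
#' `W+- = W +- eps * grad_W L_u(W', alpha)` and
#' `eps = eps0 / ||grad_W L_u(W', alpha)||`. A vanishing norm skips the
#' second term (logged via a `"degenerate"` attribute).
#'
#' All arguments are plain numeric vectors and gradient closures, so the
#' same core drives both the spiking network and analytic toy problems.
#'
#' @param W,alpha Flat numeric parameter vectors.
#' @param grad_W_t `function(W, alpha)` gradient of the inner (training)
#'   loss in `W`.
#' @param grad_alpha_t `function(W, alpha)` gradient of the inner loss in
#'   `alpha`.
#' @param grad_alpha_u `function(W, alpha)` gradient of the outer objective
#'   in `alpha`.
#' @param grad_W_u `function(W, alpha)` gradient of the outer objective in
#'   `W`.
#' @param xi1 Inner learning rate.
#' @param eps0 Base finite-difference scalar.
#' @param order `"first"` or `"second"`.
#' @return The hypergradient as a flat vector, with attribute `degenerate`
#'   set when the finite-difference direction vanished.
#' @export
hypergrad_core <- function(W, alpha, grad_W_t, grad_alpha_t, grad_alpha_u,
                           grad_W_u, xi1, eps0 = 0.01,
                           order = c("first", "second")) {
  order <- match.arg(order)
  if (order == "first" || xi1 == 0) {
    g <- grad_alpha_u(W, alpha)
    if (order == "second" && xi1 == 0) {
      # Wp = W exactly; second term carries the factor xi1 = 0
      g <- grad_alpha_u(W, alpha)
    }
    return(g)
  }
  Wp <- W - xi1 * grad_W_t(W, alpha)
  g1 <- grad_alpha_u(Wp, alpha)
  v <- grad_W_u(Wp, alpha)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    attr(g1, "degenerate") <- TRUE
    return(g1)
  }
  eps <- eps0 / nrm
  gp <- grad_alpha_t(W + eps * v, alpha)
  gm <- grad_alpha_t(W - eps * v, alpha)
  g1 - xi1 * (gp - gm) / (2 * eps)
}

#' Hypergradient of the neuron-level objective for a spiking network
#'
#' Wraps [hypergrad_core] with the spiking network's losses: the inner loss
#' is the training loss on a sub-training batch, the outer objective is the
#' validation loss on a sub-validation batch plus the Laplacian penalty
#' (which depends on `alpha` only).
#'
#' @param spec,params Network architecture and parameters.
#' @param input_t,target_t Sub-training batch.
#' @param input_v,target_v Sub-validation batch.
#' @param config A [bilevel_config].
#' @param graphs Neighbor graphs per layer (default chain graphs).
#' @param task Task type.
#' @return A `galpha`-shaped list of gradients (per layer, per field), with
#'   attribute `degenerate` when the finite-difference direction vanished.
#' @export
alpha_grad <- function(spec, params, input_t, target_t, input_v, target_v,
                       config, graphs = NULL, task = "classification") {
  if (is.null(graphs)) graphs <- default_graphs(params)
  sur <- surrogate_spec(config$width)
  cw <- resolve_class_weights(config$class_weights, target_t, task)
  a0 <- flatten_alpha(params$alphas)
  w0 <- flatten_W(params$W)
  with_params <- function(Wf, af) {
    p <- params
    p$W <- unflatten_W(Wf, params$W)
    p$alphas <- unflatten_alpha(af, params$alphas)
    p
  }
  grad_of <- function(Wf, af, input, target, what) {
    p <- with_params(Wf, af)
    g <- snn_grad(spec, p, input, target, task = task, surrogate = sur,
                  slope = config$slope, class_weights = cw)
    if (what == "W") flatten_W(g$gW) else flatten_alpha(g$galpha)
  }
  pen_grad <- function(af) {
    p <- with_params(w0, af)
    r <- network_penalty(p$alphas, graphs, grad = TRUE)
    config$lam * flatten_alpha(r$grad)
  }
  g <- hypergrad_core(
    W = w0, alpha = a0,
    grad_W_t = function(W, a) grad_of(W, a, input_t, target_t, "W"),
    grad_alpha_t = function(W, a) grad_of(W, a, input_t, target_t, "alpha"),
    grad_alpha_u = function(W, a)
      grad_of(W, a, input_v, target_v, "alpha") + pen_grad(a),
    grad_W_u = function(W, a) grad_of(W, a, input_v, target_v, "W"),
    xi1 = config$xi1, eps0 = config$eps0, order = config$order)
  out <- unflatten_alpha(as.numeric(g), zero_alpha_grad(params$alphas))
  attr(out, "degenerate") <- isTRUE(attr(g, "degenerate"))
  out
}

resolve_class_weights <- function(class_weights, target, task) {
  if (task != "classification" || is.null(class_weights)) return(NULL)
  if (is.numeric(class_weights)) return(class_weights)
  if (identical(class_weights, "balanced")) {
    tab <- tabulate(as.integer(target))
    tab[tab == 0] <- 1
    w <- 1 / tab
    return(w / mean(w))
  }
  stop("unknown class_weights specification", call. = FALSE)
}

project_alphas <- function(alphas) {
  lapply(alphas, function(a) {
    a$tau <- pmin(pmax(a$tau, 0), 1)
    a$gamma <- pmax(a$gamma, 0)
    a
  })
}

alpha_axpy <- function(alphas, galpha, step) {
  out <- alphas
  for (k in seq_along(alphas)) {
    for (f in alpha_fields) {
      out[[k]][[f]] <- alphas[[k]][[f]] - step * galpha[[k]][[f]]
    }
  }
  project_alphas(out)
}

#' Train a heterogeneous spiking network by bi-level alternation
#'
#' Splits the data into orthogonal sub-training and sub-validation sets,
#' then repeats: `alternation` minibatch weight steps on the sub-training
#' split, followed by one biophysics step
#' `alpha <- alpha - xi2 * alpha_grad` against the sub-validation split (the
#' biophysics step runs once per epoch). After each biophysics step `tau` is
#' clamped to `[0, 1]` and `gamma` to `>= 0`. With `xi2 = 0` the biophysics
#' stay frozen at their initialization — homogeneous training, in which only
#' the synaptic weights are learned.
#'
#' @param spec A [network_spec].
#' @param input `[features x T x samples]` array of encoded inputs.
#' @param target Integer class labels (classification) or target spike
#'   arrays (generation).
#' @param config A [bilevel_config].
#' @param params Optional starting [network_params]; default seeded init.
#' @param graphs Neighbor graphs per layer for the Laplacian penalty.
#' @param task `"classification"` or `"generation"`.
#' @param init Named list of biophysical init values passed to
#'   [init_network_params] (e.g. `list(u_th = 2, tau = 0.9)`).
#' @return An object of class `snn_fit`: trained `params`, per-epoch
#'   `history` tibble (`epoch`, `loss_train`, `loss_val`, `penalty`,
#'   `alpha_sd`), the resolved `config`, `spec` and split indices.
#' @export
snn_train <- function(spec, input, target, config = bilevel_config(),
                      params = NULL, graphs = NULL,
                      task = "classification", init = list()) {
  stopifnot(inherits(spec, "network_spec"), inherits(config, "bilevel_config"))
  input <- as_input_array(input, spec)
  n <- dim(input)[3]
  labels <- if (task == "classification") as.integer(target) else NULL
  sp <- split_orthogonal(n, config$split_fraction, seed = config$seed,
                         labels = labels)
  if (is.null(params)) {
    params <- do.call(init_network_params,
                      c(list(spec = spec, seed = config$seed), init))
  }
  if (is.null(graphs)) graphs <- default_graphs(params)
  sur <- surrogate_spec(config$width)
  cw <- resolve_class_weights(config$class_weights, target, task)

  take <- function(idx) {
    list(input = input[, , idx, drop = FALSE],
         target = if (task == "classification") labels[idx]
                  else index_targets(target, idx))
  }
  d_t <- take(sp$train)
  d_v <- take(sp$val)

  history <- vector("list", config$epochs)
  set.seed(config$seed + 17L)
  n_t <- length(sp$train)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_t)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    bi <- 0
    for (b in batches) {
      params <- network_step(spec, params,
                             d_t$input[, , b, drop = FALSE],
                             if (task == "classification") d_t$target[b]
                             else index_targets(d_t$target, b),
                             xi1 = config$xi1, task = task,
                             surrogate = sur, slope = config$slope,
                             class_weights = cw)
      bi <- bi + 1
      if (config$xi2 > 0 && config$alternation > 0 &&
          bi %% config$alternation == 0) {
        ga <- alpha_grad(spec, params, d_t$input, d_t$target,
                         d_v$input, d_v$target, config, graphs, task)
        params$alphas <- alpha_axpy(params$alphas, ga, config$xi2)
      }
    }
    if (config$xi2 > 0 && config$alternation == 0) {
      ga <- alpha_grad(spec, params, d_t$input, d_t$target,
                       d_v$input, d_v$target, config, graphs, task)
      params$alphas <- alpha_axpy(params$alphas, ga, config$xi2)
    }
    lt <- snn_loss(snn_forward(spec, params, d_t$input, sur, config$slope,
                               record_trains = (task != "classification")),
                   d_t$target, task = task, class_weights = cw)
    lv <- snn_loss(snn_forward(spec, params, d_v$input, sur, config$slope,
                               record_trains = (task != "classification")),
                   d_v$target, task = task, class_weights = cw)
    pen <- network_penalty(params$alphas, graphs)
    if (!is.finite(lt) || !is.finite(lv)) {
      stop("snn_train: loss diverged at epoch ", ep, call. = FALSE)
    }
    history[[ep]] <- tibble::tibble(
      epoch = ep, loss_train = lt, loss_val = lv, penalty = pen,
      alpha_sd = mean(vapply(params$alphas,
                             function(a) mean(vapply(unclass(a)[alpha_fields],
                                                     stats::sd, numeric(1))),
                             numeric(1))))
  }
  structure(list(params = params, history = dplyr::bind_rows(history),
                 config = config, spec = spec, split = sp, task = task),
            class = "snn_fit")
}

index_targets <- function(target, idx) {
  if (is.array(target) && length(dim(target)) == 3) {
    target[, , idx, drop = FALSE]
  } else {
    target[idx]
  }
}

#' Predict class labels from a fitted spiking network
#'
#' @param object An `snn_fit`.
#' @param input `[features x T x samples]` input array.
#' @param ... Unused.
#' @return Integer vector of predicted class labels.
#' @export
predict.snn_fit <- function(object, input, ...) {
  rec <- snn_forward(object$spec, object$params, input,
                     surrogate_spec(object$config$width),
                     object$config$slope, record_trains = FALSE)
  apply(rec$logits, 2, which.max)
}

#' @export
print.snn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<snn_fit> %s net [%s], T = %d, %d epoch(s)\n",
    if (x$config$xi2 > 0) "heterogeneous" else "homogeneous",
    paste(x$spec$layer_sizes, collapse = "-"), x$spec$time_steps, nrow(h)))
  cat(sprintf("  final loss: train %.4f, val %.4f, penalty %.4g\n",
              h$loss_train[nrow(h)], h$loss_val[nrow(h)],
              h$penalty[nrow(h)]))
  invisible(x)
}

#' Tidy per-neuron parameters of a fitted network
#'
#' @param x An `snn_fit`.
#' @param ... Passed to [spike_histograms] (e.g. `dt_label`).
#' @return A tibble with one row per neuron.
#' @export
tidy.snn_fit <- function(x, ...) spike_histograms(x$params, ...)

#' One-row training summary
#'
#' @param x An `snn_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.snn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    loss_train = h$loss_train[nrow(h)],
    loss_val = h$loss_val[nrow(h)],
    penalty = h$penalty[nrow(h)],
    alpha_sd = h$alpha_sd[nrow(h)],
    heterogeneous = x$config$xi2 > 0)
}

#' Training-history curves
#'
#' @param object An `snn_fit`.
#' @param ... Unused.
#' @return A ggplot object with training and validation loss per epoch.
#' @export
autoplot.snn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("loss_train", "loss_val"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
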