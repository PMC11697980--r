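make_train_set <- function(n, neurons, T, p, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    spike_train(matrix(rbinom(neurons * T, 1, p), neurons, T))
  })
}

test_that("spike-train similarity is 1 on self-comparison and symmetric", {
  A <- make_train_set(5, 3, 200, 0.1, 1)
  B <- make_train_set(5, 3, 200, 0.1, 2)
  expect_equal(md_star(A, A, window = 10), 1, tolerance = 1e-9)
  expect_equal(md_star(A, B, window = 10), md_star(B, A, window = 10))
  val <- md_star(A, B, window = 10)
  expect_gte(val, 0)
  expect_lte(val, 1.2)
  # silent sets give a flagged sentinel
  S <- lapply(1:3, function(i) spike_train(matrix(0, 2, 50)))
  out <- md_star(S, A[1:3], window = 5)
  expect_true(is.na(out))
  expect_true(attr(out, "flagged"))
})

test_that("similarity of independent homogeneous sets concentrates near 1", {
  # for iid Bernoulli trains every pairwise smoothed inner product has the
  # same expectation, so the estimator's numerator and denominator share
  # their mean and the statistic concentrates near 1
  set.seed(30)
  vals <- replicate(100, {
    A <- lapply(1:4, function(i)
      spike_train(matrix(rbinom(400, 1, 0.05), 1, 400)))
    B <- lapply(1:4, function(i)
      spike_train(matrix(rbinom(400, 1, 0.05), 1, 400)))
    md_star(A, B, window = 50)
  })
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se + 0.02)
})

test_that("similarity discriminates matched from mismatched rate patterns", {
  set.seed(31)
  rates <- rep(c(0.02, 0.3), each = 100)
  gen <- function() spike_train(matrix(rbinom(200, 1, rates), 1, 200))
  gen_flip <- function() spike_train(matrix(rbinom(200, 1, rev(rates)),
                                            1, 200))
  A <- replicate(4, gen(), simplify = FALSE)
  B <- replicate(4, gen(), simplify = FALSE)
  C <- replicate(4, gen_flip(), simplify = FALSE)
  expect_gt(md_star(A, B, window = 20), 0.8)
  expect_lt(md_star(A, C, window = 20), md_star(A, B, window = 20))
})

test_that("classification reports match a hand confusion-matrix oracle", {
  yt <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 3)
  yp <- c(1, 2, 1, 2, 2, 3, 3, 1, 3, 3)
  rep <- classification_report(yt, yp, class_names = c("1", "2", "3"))
  # oracle by direct counting
  cm <- matrix(0, 3, 3)
  for (i in seq_along(yt)) cm[yt[i], yp[i]] <- cm[yt[i], yp[i]] + 1
  expect_equal(unname(rep$confusion[,]), cm, ignore_attr = TRUE)
  expect_equal(rep$accuracy, mean(yt == yp))
  prec1 <- cm[1, 1] / sum(cm[, 1]); rec1 <- cm[1, 1] / sum(cm[1, ])
  expect_equal(rep$per_class$f1[1], 2 * prec1 * rec1 / (prec1 + rec1))
  # confusion-matrix row sums equal class supports
  expect_equal(unname(rowSums(rep$confusion)), rep$per_class$support)
  # flow table totals
  expect_equal(sum(rep$flow$n), length(yt))
})

test_that("classification report edge cases behave as documented", {
  rep1 <- classification_report(c(1, 2, 1), c(1, 2, 1))
  expect_equal(rep1$accuracy, 1)
  expect_true(all(rep1$per_class$f1 == 1))
  # all-majority predictions: minority F1 = 0
  yt <- rep(c(1, 2), times = c(18, 2))
  rep2 <- classification_report(yt, rep(1, 20), rare_threshold = 0.2)
  expect_equal(rep2$per_class$f1[2], 0)
  expect_equal(rep2$rare_classes$class, "2")
  # class absent from both vectors: NA
  rep3 <- classification_report(c(1, 1), c(1, 1), class_names = c("1", "9"))
  expect_true(is.na(rep3$per_class$f1[2]))
})

test_that("generation MSE is the elementwise mean square", {
  a <- array(1, c(2, 3, 2)); b <- array(0, c(2, 3, 2))
  expect_equal(generation_mse(a, a), 0)
  expect_equal(generation_mse(a, b), 1)
  set.seed(5)
  x <- array(rbinom(12, 1, 0.5), c(2, 3, 2))
  y <- array(rbinom(12, 1, 0.5), c(2, 3, 2))
  expect_equal(generation_mse(x, y), sum((x - y)^2) / 12)
  expect_error(generation_mse(a, array(0, c(2, 2, 2))), "mismatch")
})

test_that("manifold projection recovers planted low-dimensional structure", {
  # rate traces lying exactly on an affine 2-plane: the third principal
  # component carries ~no variance
  set.seed(6)
  T <- 300; n <- 8
  lat <- cbind(sin(seq_len(T) / 20), cos(seq_len(T) / 35))
  load <- matrix(runif(n * 2), n, 2)
  rates <- 0.1 + load %*% t(lat)
  mp <- manifold_project(rates, n_components = 3, window = 1)
  ev <- mp$explained_variance
  expect_equal(sum(ev[1:2]), 1, tolerance = 1e-10)
  expect_lt(ev[3], 1e-10)
  # orthonormal loadings
  expect_equal(unname(crossprod(mp$rotation)), diag(3), tolerance = 1e-8)
  # noisy spike realizations of the same plane still concentrate variance
  trains <- lapply(1:6, function(i)
    spike_train(matrix(rbinom(n * T, 1, 0.1 + 0.3 * (rates - min(rates)) /
                                diff(range(rates))), n, T)))
  mp2 <- manifold_project(trains, n_components = 3, window = 25)
  expect_gt(sum(mp2$explained_variance[1:2]), 0.5)
  # explained variances agree with a direct eigendecomposition
  sm <- do.call(rbind, lapply(trains, function(s)
    t(hetsnn:::boxcar_smooth(unclass(s), 25))))
  X <- scale(sm, center = TRUE, scale = FALSE)
  ev_direct <- eigen(crossprod(X) / (nrow(X) - 1))$values
  expect_equal(mp2$explained_variance[1:3],
               (ev_direct / sum(ev_direct))[1:3], tolerance = 1e-6)
})

test_that("energy accounting matches hand counts and scales with spikes", {
  # hand-sized 2-2-2 net, native spikes so every op is an accumulate
  spec <- network_spec(c(2, 2, 2), time_steps = 2,
                       encoding = "native-spikes", readout = "spike-count")
  params <- structure(list(
    W = list(matrix(c(2, 0, 0, 2), 2, 2), matrix(0, 2, 2)),
    alphas = list(neuron_params(2, tau = 1, gamma = 0),
                  neuron_params(2, tau = 1, gamma = 0))),
    class = "network_params")
  x <- array(0, c(2, 2, 1)); x[1, 1, 1] <- 1; x[2, 2, 1] <- 1; x[1, 2, 1] <- 1
  rec <- snn_forward(spec, params, x)
  # 3 input spikes x fan-out 2 + hidden spikes x fan-out 2
  hidden_spikes <- sum(rec$spike_trains[[1]])
  expect_equal(rec$synops, 3 * 2 + hidden_spikes * 2)
  er <- energy_estimate(rec, ann_ops = 8, e_mac = 4.6, e_ac = 0.9)
  expect_equal(er$snn_energy_pj, 0.9 * rec$synops)
  expect_equal(er$ann_energy_pj, 4.6 * 8)
  expect_equal(er$fold_reduction, 4.6 * 8 / (0.9 * rec$synops))
  # zero-spike sentinel
  params0 <- params
  params0$W <- lapply(params0$W, function(w) w * 0)
  rec0 <- snn_forward(spec, params0, array(0, c(2, 2, 1)))
  expect_true(is.na(energy_estimate(rec0)$fold_reduction))
})

test_that("energy fold reduction falls as injected spike counts rise", {
  spec <- network_spec(c(10, 8, 2), time_steps = 5,
                       encoding = "native-spikes", readout = "spike-count")
  params <- init_network_params(spec, seed = 7)
  folds <- vapply(c(0.05, 0.2, 0.5), function(p) {
    set.seed(8)
    x <- array(rbinom(10 * 5 * 4, 1, p), c(10, 5, 4))
    energy_estimate(snn_forward(spec, params, x))$fold_reduction
  }, numeric(1))
  expect_true(all(diff(folds) < 0))
})
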