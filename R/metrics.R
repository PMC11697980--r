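#' Bias-corrected spike-train set similarity
#'
#' Similarity between two sets of spike trains at a given time-window
#' resolution. Every train is smoothed with a boxcar of `window` steps; the
#' statistic is the mean cross-set inner product of the smoothed traces
#' normalized by the geometric mean of the within-set inner products, with
#' the bias correction that self-pairs are excluded from the within-set
#' means. When the two sets have equal size, index-equal pairs are also
#' excluded from the cross term, so comparing a set against an identical
#' copy of itself yields exactly 1. The statistic is symmetric in its two
#' arguments and lies in `[0, 1]` up to sampling noise.
#'
#' @param setA,setB Lists of [spike_train]s (or 0/1 matrices/vectors) with a
#'   common `[neurons x T]` shape; each set needs at least 2 trains for the
#'   bias correction.
#' @param window Boxcar window length. Interpreted in steps; with a
#'   `dt_label` of 1 ms a window of 10 is a 10 ms resolution.
#' @param dt_label Nominal step duration in ms (reporting only; `window` is
#'   divided by it to obtain the window in steps when supplied).
#' @return Scalar similarity, or `NA` with attribute `flagged = TRUE` when
#'   either set is entirely silent.
#' @export
md_star <- function(setA, setB, window = 10, dt_label = NULL) {
  A <- smooth_set(setA, window, dt_label)
  B <- smooth_set(setB, window, dt_label)
  stopifnot(length(A) >= 2, length(B) >= 2)
  if (all(vapply(A, function(x) all(x == 0), logical(1))) ||
      all(vapply(B, function(x) all(x == 0), logical(1)))) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  within <- function(S) {
    n <- length(S)
    tot <- 0; cnt <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      tot <- tot + sum(S[[i]] * S[[j]]); cnt <- cnt + 1
    }
    tot / cnt
  }
  cross <- function(SA, SB) {
    skip_diag <- length(SA) == length(SB)
    tot <- 0; cnt <- 0
    for (i in seq_along(SA)) for (j in seq_along(SB)) {
      if (skip_diag && i == j) next
      tot <- tot + sum(SA[[i]] * SB[[j]]); cnt <- cnt + 1
    }
    tot / cnt
  }
  caa <- within(A); cbb <- within(B)
  if (caa <= 0 || cbb <= 0) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  cross(A, B) / sqrt(caa * cbb)
}

smooth_set <- function(set, window, dt_label = NULL) {
  if (!is.list(set)) set <- list(set)
  if (!is.null(dt_label)) window <- window / dt_label
  window <- max(1L, as.integer(round(window)))
  lapply(set, function(s) {
    if (inherits(s, "spike_train")) s <- unclass(s)
    if (is.vector(s)) s <- matrix(s, nrow = 1)
    boxcar_smooth(s, window)
  })
}

# Centered moving average with shrinking windows at the edges, row-wise.
boxcar_smooth <- function(m, window) {
  if (window <= 1) return(m)
  TT <- ncol(m)
  lo <- pmax(1, seq_len(TT) - (window %/% 2))
  hi <- pmin(TT, seq_len(TT) + ((window - 1) %/% 2))
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  sums <- cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]
  sweep(sums, 2, hi - lo + 1, "/")
}

#' Classification report with rare-class panel
#'
#' Overall accuracy, per-class precision/recall/F1, macro-F1, a rare-class
#' panel (classes whose prevalence in `y_true` falls below
#' `rare_threshold`), and a true-to-predicted flow table suitable for
#' Sankey-style plotting.
#'
#' @param y_true,y_pred Vectors of true and predicted labels (factors,
#'   integers or characters) of equal length.
#' @param class_names Optional vector fixing the label set and order.
#' @param rare_threshold Prevalence below which a class is reported as rare.
#' @return An object of class `classification_report`: tibbles `per_class`,
#'   `rare_classes` and `flow`, plus scalars `accuracy` and `macro_f1`.
#'   Classes absent from both vectors get `NA` F1.
#' @export
classification_report <- function(y_true, y_pred, class_names = NULL,
                                  rare_threshold = 0.05) {
  stopifnot(length(y_true) == length(y_pred))
  if (is.null(class_names)) {
    class_names <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  }
  yt <- factor(as.character(y_true), levels = class_names)
  yp <- factor(as.character(y_pred), levels = class_names)
  cm <- table(true = yt, pred = yp)
  support <- rowSums(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- support - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  absent <- support == 0 & colSums(cm) == 0
  f1[absent] <- NA_real_
  prec[absent] <- NA_real_
  rec[absent] <- NA_real_
  per_class <- tibble::tibble(
    class = class_names, support = as.integer(support),
    prevalence = support / length(yt),
    precision = as.numeric(prec), recall = as.numeric(rec),
    f1 = as.numeric(f1))
  flow <- as.data.frame(cm, responseName = "n") |>
    tibble::as_tibble() |>
    dplyr::filter(.data$n > 0)
  rare <- dplyr::filter(per_class, .data$prevalence < rare_threshold,
                        .data$support > 0)
  structure(list(
    per_class = per_class,
    rare_classes = rare,
    flow = flow,
    accuracy = sum(tp) / length(yt),
    macro_f1 = mean(f1, na.rm = TRUE),
    confusion = cm), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> accuracy %.3f, macro-F1 %.3f\n",
              x$accuracy, x$macro_f1))
  print(x$per_class)
  if (nrow(x$rare_classes) > 0) {
    cat("rare classes:\n")
    print(x$rare_classes[, c("class", "support", "prevalence", "f1")])
  }
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) x$per_class

#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_f1 = x$macro_f1,
                 n_rare = nrow(x$rare_classes),
                 rare_min_f1 = if (nrow(x$rare_classes) > 0)
                   min(x$rare_classes$f1) else NA_real_)
}

#' Mean squared error between generated and template spike trains
#'
#' @param generated,template Spike-train sets: `[neurons x T]` matrices,
#'   `[neurons x T x trials]` arrays, or lists of [spike_train]s of matching
#'   shapes.
#' @return Elementwise mean squared error over neurons, time and trials.
#' @export
generation_mse <- function(generated, template) {
  ga <- as_train_stack(generated)
  ta <- as_train_stack(template)
  if (!identical(dim(ga), dim(ta))) {
    stop("generation_mse: shape mismatch", call. = FALSE)
  }
  mean((ga - ta)^2)
}

as_train_stack <- function(x) {
  if (is.list(x) && !is.array(x)) {
    x <- lapply(x, function(s) {
      if (inherits(s, "spike_train")) unclass(s) else s
    })
    return(array(unlist(x), dim = c(dim(x[[1]]), length(x))))
  }
  if (inherits(x, "spike_train")) x <- unclass(x)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1))
  x
}

#' Project population spiking activity onto its principal neural modes
#'
#' Boxcar-smooths the per-neuron firing rates of one or more trials, mean
#' centers the pooled `[time x neurons]` matrix and projects it onto the
#' leading principal axes — the empirical neural-manifold construction.
#'
#' @param trains A [spike_train], matrix, array or list of trains
#'   (`[neurons x T]` each).
#' @param n_components Number of principal components (requires at least
#'   this many neurons).
#' @param window Boxcar smoothing window in steps.
#' @return A list: `scores` tibble (`trial`, `step`, `PC1..PCk`),
#'   `rotation` (orthonormal loadings), `explained_variance` ratios.
#' @export
manifold_project <- function(trains, n_components = 3, window = 5) {
  stack <- as_train_stack(trains)
  n <- dim(stack)[1]
  stopifnot(n >= n_components)
  sm <- lapply(seq_len(dim(stack)[3]), function(b) {
    t(boxcar_smooth(matrix(stack[, , b], n, dim(stack)[2]), window))
  })
  X <- do.call(rbind, sm)   # [trials*T x neurons]
  if (all(apply(X, 2, stats::sd) == 0)) {
    warning("manifold_project: constant input, zero variance")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- n_components
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores$trial <- rep(seq_len(dim(stack)[3]), each = dim(stack)[2])
  scores$step <- rep(seq_len(dim(stack)[2]), times = dim(stack)[3])
  list(scores = scores[, c("trial", "step",
                           paste0("PC", seq_len(k)))],
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2)))
}

#' Event-driven energy estimate of a forward pass
#'
#' Converts the operation counts of a [snn_forward] record into energy:
#' spike-driven accumulates cost `e_ac` each, dense multiply–accumulates
#' (the direct-current front end, and the reference analog network) cost
#' `e_mac` each. `fold_reduction` is the analog network's energy divided by
#' the spiking network's. The default constants are conventional 45 nm CMOS
#' figures (4.6 pJ per MAC, 0.9 pJ per AC).
#'
#' @param record A [forward_record].
#' @param ann_ops Reference dense MAC count of the same architecture
#'   evaluated once per sample (default: sum of weight-matrix sizes times
#'   the batch size).
#' @param e_mac,e_ac Energy per operation in pJ.
#' @return An object of class `energy_report` (a one-row tibble with
#'   `snn_ac_ops`, `snn_mac_ops`, `snn_energy_pj`, `ann_ops`,
#'   `ann_energy_pj`, `fold_reduction`, `e_mac`, `e_ac`). When the spiking
#'   energy is zero, `fold_reduction` is `NA` (sentinel).
#' @export
energy_estimate <- function(record, ann_ops = NULL, e_mac = 4.6,
                            e_ac = 0.9) {
  stopifnot(inherits(record, "forward_record"))
  if (is.null(ann_ops)) {
    sizes <- record$spec$layer_sizes
    ann_ops <- sum(sizes[-length(sizes)] * sizes[-1]) * record$n_batch
  }
  snn_energy <- e_ac * record$synops + e_mac * record$front_end_macs
  ann_energy <- e_mac * ann_ops
  out <- tibble::tibble(
    snn_ac_ops = record$synops,
    snn_mac_ops = record$front_end_macs,
    snn_energy_pj = snn_energy,
    ann_ops = ann_ops,
    ann_energy_pj = ann_energy,
    fold_reduction = if (snn_energy > 0) ann_energy / snn_energy
                     else NA_real_,
    e_mac = e_mac, e_ac = e_ac)
  class(out) <- c("energy_report", class(out))
  out
}
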