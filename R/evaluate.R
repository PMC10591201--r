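truth_adjacency <- function(truth, observed = NULL) {
  if (inherits(truth, "ground_truth_network")) {
    obs <- if (is.null(observed)) truth$observed else observed
    A <- (as.matrix(truth$weights[obs, obs, drop = FALSE]) != 0) * 1L
  } else {
    A <- (as.matrix(truth) != 0) * 1L
  }
  diag(A) <- 0L
  A
}

#' Confusion counts of a reconstruction against ground truth
#'
#' Counts true/false positives/negatives over all ordered pairs of observed
#' cells (presynaptic != postsynaptic). The evaluation universe is the
#' observed ensemble only: connections involving unobserved cells are
#' invisible to the decoder and are not scored.
#'
#' @param estimate Binary estimated adjacency (postsynaptic x presynaptic
#'   over observed cells), e.g. `reconstruction$adjacency`.
#' @param truth A `ground_truth_network` (its observed subset is used) or a
#'   weight/adjacency matrix of matching dimension.
#' @return A `confusion_counts` list with integers `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(estimate, truth) {
  A <- truth_adjacency(truth)
  if (!all(dim(estimate) == dim(A)))
    stop("Estimate and truth dimensions differ.", call. = FALSE)
  est <- (estimate != 0) * 1L
  diag(est) <- 0L
  off <- row(A) != col(A)
  e <- est[off]; a <- A[off]
  structure(list(tp = sum(e == 1 & a == 1), fp = sum(e == 1 & a == 0),
                 fn = sum(e == 0 & a == 1), tn = sum(e == 0 & a == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp %d  fp %d  fn %d  tn %d (recall %.3f, precision %.3f)\n",
              x$tp, x$fp, x$fn, x$tn, recall(x), precision(x)))
  invisible(x)
}

#' Recall of declared connections
#'
#' `TP / (TP + FN)`: the fraction of true connections recovered. Undefined
#' (no true connections) is reported as `NA`, never 0 or 1.
#'
#' @param counts A `confusion_counts`.
#' @return Numeric scalar in `[0, 1]`, or `NA` if undefined.
#' @export
recall <- function(counts) {
  if (counts$tp + counts$fn == 0) return(NA_real_)
  counts$tp / (counts$tp + counts$fn)
}

#' Precision of declared connections
#'
#' `TP / (TP + FP)`: the fraction of declared connections that are real.
#' Undefined (nothing declared) is reported as `NA`.
#'
#' @param counts A `confusion_counts`.
#' @return Numeric scalar in `[0, 1]`, or `NA` if undefined.
#' @export
precision <- function(counts) {
  if (counts$tp + counts$fp == 0) return(NA_real_)
  counts$tp / (counts$tp + counts$fp)
}

#' Per-postsynaptic-cell recall and precision
#'
#' Restricts the confusion counts to each postsynaptic cell's row of the
#' adjacency. Undefined metrics are `NA`.
#'
#' @inheritParams confusion_counts
#' @return Tibble with one row per observed postsynaptic cell: `cell`,
#'   `tp`, `fp`, `fn`, `tn`, `recall`, `precision`.
#' @export
per_cell_metrics <- function(estimate, truth) {
  A <- truth_adjacency(truth)
  if (!all(dim(estimate) == dim(A)))
    stop("Estimate and truth dimensions differ.", call. = FALSE)
  est <- (estimate != 0) * 1L
  diag(est) <- 0L
  n <- nrow(A)
  purrr::map_dfr(seq_len(n), function(i) {
    keep <- setdiff(seq_len(n), i)
    e <- est[i, keep]; a <- A[i, keep]
    tp <- sum(e == 1 & a == 1); fp <- sum(e == 1 & a == 0)
    fn <- sum(e == 0 & a == 1); tn <- sum(e == 0 & a == 0)
    tibble::tibble(
      cell = i, tp = tp, fp = fp, fn = fn, tn = tn,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  })
}

#' Static sparse linear fixture
#'
#' Generates a plain compressed-sensing instance `y = M x + e` without any
#' network dynamics: a Bernoulli design, a k-sparse signed weight vector,
#' and Gaussian measurement noise. Used to exercise the decoders in
#' isolation.
#'
#' @param n Number of unknowns.
#' @param n_trials Number of measurements.
#' @param sparsity Fraction of nonzero entries in `x`
#'   (`k = round(sparsity * n)`).
#' @param noise_sd Gaussian noise s.d. (0 for noiseless).
#' @param fraction_stim Bernoulli probability of the design entries.
#'   Default 0.3.
#' @param weight_range Magnitude range of the nonzero entries.
#' @param prop_negative Probability a nonzero entry is negative.
#' @return List with `M`, `x_true`, `y`, `support`.
#' @export
make_linear_fixture <- function(n, n_trials, sparsity, noise_sd = 0,
                                fraction_stim = 0.3,
                                weight_range = c(0.5, 1.5),
                                prop_negative = 0.2) {
  stopifnot(n >= 1, n_trials >= 1)
  M <- matrix(as.integer(stats::runif(n_trials * n) < fraction_stim),
              n_trials, n)
  k <- as.integer(floor(sparsity * n + 0.5))
  x <- numeric(n)
  support <- integer(0)
  if (k > 0) {
    support <- sort(sample.int(n, k))
    mag <- stats::runif(k, weight_range[1], weight_range[2])
    sign <- ifelse(stats::runif(k) < prop_negative, -1, 1)
    x[support] <- mag * sign
  }
  e <- if (noise_sd > 0) stats::rnorm(n_trials, 0, noise_sd) else numeric(n_trials)
  list(M = M, x_true = x, y = drop(M %*% x) + e, support = support)
}
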