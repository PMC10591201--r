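#' Solve the L1-regularised reconstruction for one neuron
#'
#' Minimises `lambda * ||x||_1 + 1/2 * ||y - M x||^2` (the lasso form of
#' the sparse-recovery problem), optionally under per-coordinate bounds,
#' by cyclic coordinate descent on the Gram system. The printed objective
#' uses the squared residual norm by default; `squared = FALSE` instead
#' solves the unsquared variant `lambda * ||x||_1 + 1/2 * ||y - M x||_2`,
#' which shares its solution path with the squared form: it is solved by a
#' fixed-point iteration on the effective penalty
#' `lambda_eff = 2 * lambda * ||y - M x||_2`.
#'
#' @param M Trials x N design matrix (the neuron's non-excluded rows of the
#'   stimulation matrix).
#' @param y Response vector (length `nrow(M)`).
#' @param lambda Sparsity-error trade-off, > 0.
#' @param lower,upper Per-coordinate bounds (recycled); used for cell-type
#'   sign constraints.
#' @param squared Use the squared residual norm (default `TRUE`).
#' @param tol Coordinate-descent convergence tolerance. Default 1e-7.
#' @param max_iter Maximum full sweeps. Default 100000.
#' @return Numeric vector `x` with attributes `objective`, `residual_norm`,
#'   `sweeps` and `status` (`"optimal"`).
#' @examples
#' # Identity design: the solution is the soft-thresholded data.
#' solve_lasso(diag(4), c(10, 0, 0, 0), lambda = 0.25)
#' @export
solve_lasso <- function(M, y, lambda, lower = -Inf, upper = Inf,
                        squared = TRUE, tol = 1e-7, max_iter = 100000L) {
  if (lambda < 0) stop("`lambda` must be >= 0.", call. = FALSE)
  M <- as.matrix(M)
  p <- ncol(M)
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  G <- crossprod(M)
  q <- drop(crossprod(M, y))
  solve_at <- function(lam, x0) {
    fit <- cd_lasso_cpp(G, q, lam, lower, upper, x0, tol, max_iter)
    if (fit$sweeps < 0)
      stop(sprintf("Coordinate descent did not converge in %d sweeps.",
                   max_iter), call. = FALSE)
    fit$x
  }
  if (squared) {
    x <- solve_at(lambda, numeric(p))
  } else {
    # Unsquared residual norm: stationarity matches the squared problem at
    # lambda_eff = 2 * lambda * ||r||, so iterate that fixed point.
    x <- numeric(p)
    lam_eff <- 2 * lambda * sqrt(sum(y^2))
    for (i in 1:50) {
      x <- solve_at(lam_eff, x)
      r <- sqrt(sum((y - M %*% x)^2))
      lam_new <- 2 * lambda * r
      if (abs(lam_new - lam_eff) <= 1e-10 * max(1, lam_eff)) break
      lam_eff <- lam_new
    }
  }
  r <- sqrt(sum((y - M %*% x)^2))
  obj <- if (squared) lambda * sum(abs(x)) + 0.5 * r^2
         else lambda * sum(abs(x)) + 0.5 * r
  structure(drop(x), objective = obj, residual_norm = r,
            status = "optimal")
}

#' Solve the noise-bounded basis-pursuit reconstruction
#'
#' Minimises `||x||_1` subject to `||y - M x||_2 <= epsilon`. The solution
#' coincides with a point on the lasso path, so it is found by bisecting
#' the lasso penalty until the residual norm matches the noise bound: the
#' residual is non-decreasing and the L1 norm non-increasing in the
#' penalty.
#'
#' @inheritParams solve_lasso
#' @param epsilon Noise bound, >= 0.
#' @param resid_tol Relative tolerance on matching the residual bound.
#' @return Numeric vector `x` with attributes `l1_norm`, `residual_norm`,
#'   `status`.
#' @export
solve_basis_pursuit <- function(M, y, epsilon, lower = -Inf, upper = Inf,
                                resid_tol = 1e-4, tol = 1e-10,
                                max_iter = 100000L) {
  if (epsilon < 0) stop("`epsilon` must be >= 0.", call. = FALSE)
  M <- as.matrix(M)
  p <- ncol(M)
  ynorm <- sqrt(sum(y^2))
  finish <- function(x) {
    r <- sqrt(sum((y - M %*% x)^2))
    structure(drop(x), l1_norm = sum(abs(x)), residual_norm = r,
              status = "optimal")
  }
  if (ynorm <= epsilon) return(finish(numeric(p)))
  lower <- rep_len(lower, p); upper <- rep_len(upper, p)
  G <- crossprod(M)
  q <- drop(crossprod(M, y))
  lam_max <- max(abs(q))  # x = 0 at and above this penalty
  slack <- max(resid_tol * max(epsilon, 1e-8), 1e-8)
  resid <- function(x) sqrt(sum((y - M %*% x)^2))
  solve_at <- function(lam, x0) {
    fit <- cd_lasso_cpp(G, q, lam, lower, upper, x0, tol, max_iter)
    if (fit$sweeps < 0)
      stop(sprintf("Coordinate descent did not converge in %d sweeps.",
                   max_iter), call. = FALSE)
    fit$x
  }
  # Warm-started descent of the penalty path: the residual norm decreases
  # along it, so stop at the first penalty whose residual meets the bound.
  lams <- lam_max * exp(seq(log(0.98), log(1e-12), length.out = 80))
  x <- numeric(p)
  lam_hi <- lam_max
  r <- ynorm
  hit <- FALSE
  for (lam in lams) {
    x <- solve_at(lam, x)
    r <- resid(x)
    if (r <= epsilon + slack) {
      hit <- TRUE
      lam_lo <- lam
      break
    }
    lam_hi <- lam
  }
  if (!hit)
    stop(sprintf(
      "Infeasible: smallest attainable residual %.6g exceeds epsilon = %.6g.",
      r, epsilon), call. = FALSE)
  # Refine towards the penalty whose residual matches the bound exactly.
  for (i in 1:50) {
    if (r >= epsilon - slack || lam_hi / lam_lo < 1 + 1e-10) break
    mid <- sqrt(lam_lo * lam_hi)
    xm <- solve_at(mid, x)
    rm <- resid(xm)
    if (rm <= epsilon + slack) {
      lam_lo <- mid; x <- xm; r <- rm
    } else {
      lam_hi <- mid
    }
  }
  finish(x)
}

#' Solve the cell-type sign-constrained reconstruction
#'
#' Lasso objective with excitatory presynaptic coordinates constrained
#' non-negative and inhibitory coordinates non-positive.
#'
#' @inheritParams solve_lasso
#' @param e_idx,i_idx Integer indices of excitatory / inhibitory
#'   presynaptic coordinates; together they must partition `1:ncol(M)`.
#' @return As [solve_lasso()].
#' @export
solve_sign_constrained <- function(M, y, lambda, e_idx, i_idx,
                                   squared = TRUE, tol = 1e-9,
                                   max_iter = 100000L) {
  p <- ncol(M)
  if (length(intersect(e_idx, i_idx)) ||
      !setequal(union(e_idx, i_idx), seq_len(p)))
    stop("`e_idx` and `i_idx` must partition the presynaptic index set.",
         call. = FALSE)
  lower <- rep(-Inf, p); upper <- rep(Inf, p)
  lower[e_idx] <- 0
  upper[i_idx] <- 0
  solve_lasso(M, y, lambda, lower, upper, squared, tol, max_iter)
}

#' Classify presynaptic cells from an unconstrained reconstruction
#'
#' A presynaptic cell is labelled by the sign of the sum of its inferred
#' outgoing weights across all postsynaptic cells (a magnitude-weighted
#' vote); a zero or tied sum defaults to excitatory, the majority type.
#'
#' @param x_hat Estimated weight matrix, postsynaptic x presynaptic.
#' @return Character vector of inferred types, one per presynaptic column.
#' @export
classify_cell_types <- function(x_hat) {
  ifelse(colSums(x_hat) < 0, "inhibitory", "excitatory")
}

#' Threshold estimated weights into a binary adjacency
#'
#' Declares a connection wherever the estimated weight magnitude exceeds
#' `rel_threshold` (default 1%) of the largest magnitude — globally by
#' default, per postsynaptic cell with `per_neuron = TRUE`. An all-zero
#' estimate yields an empty adjacency.
#'
#' @param x_hat Estimated weight matrix (postsynaptic x presynaptic).
#' @param rel_threshold Relative threshold in (0, 1). Default 0.01.
#' @param per_neuron Use each postsynaptic cell's own row maximum as the
#'   reference. Default `FALSE` (global maximum).
#' @return Integer 0/1 matrix of the same shape.
#' @export
threshold_weights <- function(x_hat, rel_threshold = 0.01,
                              per_neuron = FALSE) {
  if (rel_threshold <= 0 || rel_threshold >= 1)
    stop("`rel_threshold` must be in (0, 1).", call. = FALSE)
  if (!all(is.finite(x_hat))) stop("`x_hat` must be finite.", call. = FALSE)
  a <- abs(x_hat)
  ref <- if (per_neuron) apply(a, 1, max) else max(a)
  adj <- (a > rel_threshold * ref) * 1L
  adj[!is.finite(adj)] <- 0L
  adj
}

#' Decode the connectivity of every observed neuron
#'
#' Runs the sparse reconstruction for each observed cell from its
#' non-excluded trials. The self-weight is excluded from the unknowns
#' whenever self-stimulation trials are excluded (its design column would
#' be all zero); the diagonal of the estimate is fixed at zero.
#'
#' Modes:
#' \describe{
#'   \item{`unconstrained`}{plain lasso.}
#'   \item{`oracle_sign_constrained`}{sign constraints from the true cell
#'     types of the observed cells (`types`).}
#'   \item{`inferred_sign_constrained`}{a first unconstrained pass, cell
#'     types classified from it via [classify_cell_types()], then a
#'     constrained re-solve — so every presynaptic column of the final
#'     estimate has a uniform sign.}
#' }
#'
#' @param measurements A `measurement_set`.
#' @param M The full stimulation matrix used in the experiment.
#' @param lambda Sparsity-error trade-off. Default 0.25.
#' @param mode Decoder mode, see above.
#' @param types True cell types of the observed cells (required for
#'   `oracle_sign_constrained`).
#' @param rel_threshold Relative connection threshold. Default 0.01.
#' @param per_neuron_threshold Threshold per postsynaptic cell instead of
#'   globally. Default `FALSE`.
#' @param squared Squared-residual objective (see [solve_lasso()]).
#' @return A `reconstruction`: estimated weight matrix `x_hat`
#'   (postsynaptic x presynaptic over observed cells), thresholded
#'   `adjacency`, `inferred_types`, `mode` and per-neuron solver
#'   `diagnostics` (tibble with objective, residual norm, sweeps, status).
#' @export
decode_connectivity <- function(measurements, M, lambda = 0.25,
                                mode = c("unconstrained",
                                         "oracle_sign_constrained",
                                         "inferred_sign_constrained"),
                                types = NULL, rel_threshold = 0.01,
                                per_neuron_threshold = FALSE,
                                squared = TRUE) {
  mode <- match.arg(mode)
  n_obs <- ncol(measurements$y)
  stopifnot(ncol(M) == n_obs, nrow(M) == nrow(measurements$y))
  if (mode == "oracle_sign_constrained" && is.null(types))
    stop("`types` is required for oracle sign constraints.", call. = FALSE)

  solve_all <- function(lower_of, upper_of) {
    x_hat <- matrix(0, n_obs, n_obs)
    diag_ok <- logical(n_obs)
    diags <- vector("list", n_obs)
    for (n in seq_len(n_obs)) {
      keep <- !measurements$excluded[, n]
      unknowns <- setdiff(seq_len(n_obs), n)
      M_sub <- M[keep, unknowns, drop = FALSE]
      y_sub <- measurements$y[keep, n]
      fit <- tryCatch(
        solve_lasso(M_sub, y_sub, lambda,
                    lower = lower_of(unknowns), upper = upper_of(unknowns),
                    squared = squared),
        error = function(e) e)
      if (inherits(fit, "error")) {
        diags[[n]] <- tibble::tibble(neuron = n, objective = NA_real_,
                                     residual_norm = NA_real_,
                                     status = conditionMessage(fit))
      } else {
        x_hat[n, unknowns] <- as.numeric(fit)
        diag_ok[n] <- TRUE
        diags[[n]] <- tibble::tibble(neuron = n,
                                     objective = attr(fit, "objective"),
                                     residual_norm = attr(fit, "residual_norm"),
                                     status = attr(fit, "status"))
      }
    }
    list(x_hat = x_hat, diagnostics = dplyr::bind_rows(diags))
  }

  unconstrained <- function() {
    solve_all(function(u) rep(-Inf, length(u)),
              function(u) rep(Inf, length(u)))
  }
  constrained <- function(type_vec) {
    lower <- ifelse(type_vec == "excitatory", 0, -Inf)
    upper <- ifelse(type_vec == "excitatory", Inf, 0)
    solve_all(function(u) lower[u], function(u) upper[u])
  }

  if (mode == "unconstrained") {
    fit <- unconstrained()
    inferred <- classify_cell_types(fit$x_hat)
  } else if (mode == "oracle_sign_constrained") {
    fit <- constrained(types)
    inferred <- types
  } else {
    first <- unconstrained()
    inferred <- classify_cell_types(first$x_hat)
    fit <- constrained(inferred)
  }
  structure(
    list(x_hat = fit$x_hat,
         adjacency = threshold_weights(fit$x_hat, rel_threshold,
                                       per_neuron_threshold),
         inferred_types = inferred,
         mode = mode, lambda = lambda, rel_threshold = rel_threshold,
         diagnostics = fit$diagnostics),
    class = "reconstruction"
  )
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf(
    "<reconstruction> %d observed cells, %d declared connections (mode %s, lambda %g)\n",
    nrow(x$x_hat), sum(x$adjacency), x$mode, x$lambda))
  invisible(x)
}

#' One-cell-per-trial (sequential) baseline reconstruction
#'
#' The sequential single-input single-output baseline: each trial
#' stimulates exactly one cell, so after one trial per observed cell the
#' estimated weight of connection j to i is directly proportional to the
#' response of i on the trial in which j alone was stimulated. The same
#' relative thresholding as the compressive decoder applies downstream.
#'
#' @param measurements A `measurement_set` from a one-cell-per-trial
#'   experiment (its `M` rows must be one-hot and jointly cover every
#'   observed cell).
#' @param M The one-hot stimulation matrix.
#' @return Estimated weight matrix (postsynaptic x presynaptic); responses
#'   from excluded (self) trials are zero.
#' @export
siso_baseline <- function(measurements, M) {
  if (any(rowSums(M) != 1L))
    stop("SISO baseline requires exactly one stimulated cell per trial.",
         call. = FALSE)
  n_obs <- ncol(M)
  x_hat <- matrix(0, n_obs, n_obs)
  for (t in seq_len(nrow(M))) {
    j <- which(M[t, ] == 1L)
    resp <- measurements$y[t, ]
    resp[measurements$excluded[t, ]] <- 0
    resp[j] <- 0
    x_hat[, j] <- x_hat[, j] + resp
  }
  x_hat / pmax(1, colSums(M))[col(x_hat)]
}

#' Export a reconstruction as plain-text files
#'
#' Writes `x_hat.csv`, `adjacency.csv`, `inferred_types.csv` and
#' `diagnostics.json` into `dir`.
#'
#' @param reconstruction A `reconstruction`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_reconstruction <- function(reconstruction, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(reconstruction$x_hat, file.path(dir, "x_hat.csv"),
                   row.names = FALSE)
  utils::write.csv(reconstruction$adjacency, file.path(dir, "adjacency.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(cell = seq_along(reconstruction$inferred_types),
               type = reconstruction$inferred_types),
    file.path(dir, "inferred_types.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(mode = reconstruction$mode, lambda = reconstruction$lambda,
         rel_threshold = reconstruction$rel_threshold,
         diagnostics = reconstruction$diagnostics),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
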