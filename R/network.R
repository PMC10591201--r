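#' Assign excitatory/inhibitory cell types
#'
#' Randomly labels neurons as excitatory or inhibitory at a fixed fraction,
#' mimicking the roughly 80/20 split of mammalian cortex. Exactly
#' `round(excitatory_fraction * total_cells)` cells (round-half-up) are
#' excitatory; their positions are randomised.
#'
#' @param total_cells Number of neurons in the network.
#' @param excitatory_fraction Fraction of excitatory cells, in `[0, 1]`.
#'   Default 0.8.
#' @return Character vector of length `total_cells` with values
#'   `"excitatory"` / `"inhibitory"`.
#' @examples
#' set.seed(1)
#' table(assign_cell_types(10, 0.8))
#' @export
assign_cell_types <- function(total_cells, excitatory_fraction = 0.8) {
  if (!is.numeric(total_cells) || length(total_cells) != 1L || total_cells <= 0)
    stop("`total_cells` must be a positive integer.", call. = FALSE)
  if (excitatory_fraction < 0 || excitatory_fraction > 1)
    stop("`excitatory_fraction` must be in [0, 1].", call. = FALSE)
  total_cells <- as.integer(total_cells)
  n_exc <- as.integer(floor(excitatory_fraction * total_cells + 0.5))
  labels <- rep("inhibitory", total_cells)
  labels[sample.int(total_cells, n_exc)] <- "excitatory"
  labels
}

#' Uniform synaptic weight sampler
#'
#' Weight magnitudes are drawn uniformly on `(0, max]` with the sign forced
#' by the presynaptic cell type: excitatory columns are positive, inhibitory
#' columns negative, and inhibitory synapses are twice as strong on average
#' (the classical E/I network convention). The default scale is set so that
#' the single-step voltage deflection of the strongest (inhibitory) weight is
#' roughly ten times the per-step background voltage noise of the calibrated
#' base network; equivalently, a weight at the 1%-of-maximum detection floor
#' moves the membrane by about a tenth of the noise level. See the package
#' vignette for the calibration.
#'
#' @param exc_max Maximum excitatory weight magnitude (injected-current
#'   increment per presynaptic spike). Default 10.
#' @param inh_max Maximum inhibitory weight magnitude. Default 20.
#' @return An object of class `weight_sampler`: a list with a
#'   `sample(n, type)` function returning signed weights.
#' @export
weight_sampler_uniform <- function(exc_max = 10, inh_max = 20) {
  stopifnot(exc_max > 0, inh_max > 0)
  structure(
    list(
      exc_max = exc_max,
      inh_max = inh_max,
      sample = function(n, type) {
        if (type == "excitatory") stats::runif(n, 0, exc_max)
        else -stats::runif(n, 0, inh_max)
      }
    ),
    class = "weight_sampler"
  )
}

new_ground_truth_network <- function(weights, labels, observed, connect_prob,
                                     topology, ws_beta = NA_real_) {
  structure(
    list(
      weights = weights, labels = labels, observed = observed,
      connect_prob = connect_prob, topology = topology, ws_beta = ws_beta
    ),
    class = "ground_truth_network"
  )
}

#' @export
print.ground_truth_network <- function(x, ...) {
  n <- nrow(x$weights)
  ne <- length(x$weights@x)
  cat(sprintf(
    "<ground_truth_network> %d cells (%d excitatory), %d connections (density %.3f)\n",
    n, sum(x$labels == "excitatory"), ne, ne / (n * (n - 1))
  ))
  cat(sprintf("  topology: %s%s; observed: %d cells\n", x$topology,
              if (x$topology == "watts_strogatz")
                sprintf(" (beta = %g)", x$ws_beta) else "",
              length(x$observed)))
  invisible(x)
}

#' Build a uniform-random ground-truth network
#'
#' Every ordered off-diagonal pair is connected independently with
#' probability `connect_prob` ("sparsity"); connected entries get weights
#' from `weights` with sign set by the presynaptic cell type. No autapses.
#'
#' @param labels Cell-type labels from [assign_cell_types()].
#' @param connect_prob Connection probability in `[0, 1]`.
#' @param n_observed Number of observed cells (sampled uniformly without
#'   replacement). Default: all cells.
#' @param weights A [weight_sampler_uniform()] object.
#' @return A `ground_truth_network`: sparse weight matrix `W` (entry
#'   `W[i, j]` = weight of connection j to i), labels, observed index set and
#'   construction metadata.
#' @seealso [build_watts_strogatz_network()], [build_network()]
#' @export
build_uniform_network <- function(labels, connect_prob,
                                  n_observed = length(labels),
                                  weights = weight_sampler_uniform()) {
  if (connect_prob < 0 || connect_prob > 1)
    stop("`connect_prob` must be in [0, 1].", call. = FALSE)
  n <- length(labels)
  # Draw presence column-by-column so weight signs follow presynaptic type.
  pre <- integer(0); post <- integer(0); w <- numeric(0)
  for (j in seq_len(n)) {
    targets <- which(stats::runif(n) < connect_prob)
    targets <- targets[targets != j]
    if (length(targets)) {
      pre <- c(pre, rep.int(j, length(targets)))
      post <- c(post, targets)
      w <- c(w, weights$sample(length(targets), labels[j]))
    }
  }
  W <- Matrix::sparseMatrix(i = post, j = pre, x = w, dims = c(n, n))
  observed <- select_observed_subset(n, n_observed)
  new_ground_truth_network(W, labels, observed, connect_prob, "uniform")
}

#' Build a Watts-Strogatz small-world ground-truth network
#'
#' Starts from a directed ring lattice in which every node projects to its
#' `k/2` nearest neighbours on each side, with
#' `k = ` nearest even integer to `connect_prob * (n - 1)` so the expected
#' density matches the uniform-random construction. Each edge's target
#' endpoint is then rewired independently with probability `ws_beta` to a
#' uniformly chosen node, resampling to avoid self-loops and duplicate
#' edges. `ws_beta = 0` keeps the clustered ring lattice; `ws_beta = 1`
#' yields a random digraph. Rewiring conserves the edge count and every
#' node's out-degree. Weights are assigned by presynaptic cell type as in
#' [build_uniform_network()].
#'
#' @inheritParams build_uniform_network
#' @param ws_beta Rewiring probability in `[0, 1]`.
#' @return A `ground_truth_network`.
#' @export
build_watts_strogatz_network <- function(labels, connect_prob, ws_beta,
                                         n_observed = length(labels),
                                         weights = weight_sampler_uniform()) {
  if (connect_prob < 0 || connect_prob > 1)
    stop("`connect_prob` must be in [0, 1].", call. = FALSE)
  if (ws_beta < 0 || ws_beta > 1)
    stop("`ws_beta` must be in [0, 1].", call. = FALSE)
  n <- length(labels)
  k <- 2L * as.integer(floor(connect_prob * (n - 1) / 2 + 0.5))
  if (k < 2L)
    stop(sprintf(paste0(
      "Ring-lattice out-degree k = %d < 2; connect_prob must be at least ",
      "~%.3f for n = %d."), k, 1 / (n - 1), n), call. = FALSE)
  half <- k %/% 2L
  # Directed ring lattice: j -> j +/- 1..half (mod n).
  pre <- rep(seq_len(n), each = k)
  offs <- c(seq_len(half), -seq_len(half))
  post <- as.integer(outer(offs, seq_len(n) - 1L, `+`) %% n + 1L)
  # Rewire target endpoints with probability ws_beta.
  edge_set <- new.env(hash = TRUE, size = n * k)
  for (e in seq_along(pre))
    assign(paste0(pre[e], ".", post[e]), TRUE, envir = edge_set)
  rewire <- which(stats::runif(length(pre)) < ws_beta)
  for (e in rewire) {
    key_old <- paste0(pre[e], ".", post[e])
    repeat {
      tgt <- sample.int(n, 1L)
      key <- paste0(pre[e], ".", tgt)
      if (tgt != pre[e] && !exists(key, envir = edge_set, inherits = FALSE)) {
        rm(list = key_old, envir = edge_set)
        assign(key, TRUE, envir = edge_set)
        post[e] <- tgt
        break
      }
    }
  }
  w <- numeric(length(pre))
  for (type in c("excitatory", "inhibitory")) {
    idx <- which(labels[pre] == type)
    if (length(idx)) w[idx] <- weights$sample(length(idx), type)
  }
  W <- Matrix::sparseMatrix(i = post, j = pre, x = w, dims = c(n, n))
  observed <- select_observed_subset(n, n_observed)
  new_ground_truth_network(W, labels, observed, connect_prob,
                           "watts_strogatz", ws_beta)
}

#' Build a ground-truth network
#'
#' Convenience wrapper dispatching on `topology`.
#'
#' @param total_cells Network size.
#' @param connect_prob Connection probability ("sparsity").
#' @param topology `"uniform"` or `"watts_strogatz"`.
#' @param ws_beta Watts-Strogatz rewiring probability (used only for
#'   `topology = "watts_strogatz"`).
#' @param excitatory_fraction Fraction of excitatory cells.
#' @inheritParams build_uniform_network
#' @return A `ground_truth_network`.
#' @examples
#' set.seed(7)
#' net <- build_network(50, connect_prob = 0.1, n_observed = 20)
#' net
#' @export
build_network <- function(total_cells, connect_prob,
                          topology = c("uniform", "watts_strogatz"),
                          ws_beta = 1, n_observed = total_cells,
                          excitatory_fraction = 0.8,
                          weights = weight_sampler_uniform()) {
  topology <- match.arg(topology)
  labels <- assign_cell_types(total_cells, excitatory_fraction)
  if (topology == "uniform")
    build_uniform_network(labels, connect_prob, n_observed, weights)
  else
    build_watts_strogatz_network(labels, connect_prob, ws_beta, n_observed,
                                 weights)
}

#' Select the observed subset of a network
#'
#' Uniform sampling without replacement, returned sorted ascending.
#'
#' @param total_cells Network size.
#' @param n_obs Number of observed cells; must satisfy
#'   `1 <= n_obs <= total_cells`.
#' @return Sorted integer vector of observed cell indices.
#' @export
select_observed_subset <- function(total_cells, n_obs) {
  if (!is.numeric(n_obs) || n_obs < 1 || n_obs > total_cells)
    stop("`n_obs` must satisfy 1 <= n_obs <= total_cells.", call. = FALSE)
  sort(sample.int(total_cells, as.integer(n_obs)))
}

#' Tabulate a network as an edge list
#'
#' @param x A `ground_truth_network`.
#' @param ... Unused.
#' @return A tibble with columns `pre`, `post`, `weight` (one row per
#'   connection) ordered by presynaptic cell.
#' @export
tidy.ground_truth_network <- function(x, ...) {
  W <- methods::as(x$weights, "TsparseMatrix")
  tibble::tibble(pre = W@j + 1L, post = W@i + 1L, weight = W@x) |>
    dplyr::arrange(.data$pre, .data$post)
}

#' Export a ground-truth network as plain-text files
#'
#' Writes the dense weight matrix (`weights.csv`, header row of neuron ids),
#' a three-column edge list (`edges.csv`: pre, post, weight), the cell-type
#' table (`labels.csv`: id, type) and the observed index set
#' (`observed.txt`, one id per line) into `dir`.
#'
#' @param network A `ground_truth_network`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(network$weights)
  dense <- as.matrix(network$weights)
  colnames(dense) <- paste0("n", seq_len(n))
  utils::write.csv(dense, file.path(dir, "weights.csv"), row.names = FALSE)
  utils::write.csv(tidy.ground_truth_network(network),
                   file.path(dir, "edges.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(id = seq_len(n), type = network$labels),
    file.path(dir, "labels.csv"), row.names = FALSE)
  writeLines(as.character(network$observed), file.path(dir, "observed.txt"))
  invisible(dir)
}

#' Import a ground-truth network written by [write_network()]
#'
#' Also accepts externally supplied connectivity: any directory with an
#' `edges.csv` edge list, a `labels.csv` cell-type table, and an
#' `observed.txt` id list can be mapped instead of a generated network.
#'
#' @param dir Directory containing the files.
#' @return A `ground_truth_network`.
#' @export
read_network <- function(dir) {
  edges <- utils::read.csv(file.path(dir, "edges.csv"))
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  n <- nrow(lab)
  observed <- as.integer(readLines(file.path(dir, "observed.txt")))
  W <- Matrix::sparseMatrix(i = edges$post, j = edges$pre, x = edges$weight,
                            dims = c(n, n))
  density <- length(W@x) / (n * (n - 1))
  new_ground_truth_network(W, lab$type, sort(observed), density, "imported")
}
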