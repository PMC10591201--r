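#' Experiment configuration
#'
#' Bundles every tunable of a simulated mapping experiment under the
#' conventional parameter names. Base values follow the reference
#' experimental grid: a 1,000-cell network with 200 observed cells, 10%
#' connection probability, 10% of the observed ensemble stimulated per
#' trial, no off-target stimulation, fully reliable synapses, 1 ms fixed
#' latency, uniform-random topology, and a decoder penalty of 0.25.
#'
#' @param TotalCells Total network size. Default 1000.
#' @param N_obsCell Number of observed cells. Default 200.
#' @param sparsity Connection probability. Default 0.1.
#' @param fractionStim Fraction of observed cells stimulated per trial.
#'   Default 0.1.
#' @param offTargetProb Per-trial probability of one off-target forced
#'   spike. Default 0.
#' @param synFailProb Per-event synaptic failure probability. Default 0.
#' @param latency_mean,latency_sd Propagation latency model, ms. Defaults
#'   1.0 and 0.
#' @param WSbeta Watts-Strogatz rewiring probability (only used when
#'   `topology = "watts_strogatz"`). Default 1.
#' @param lambda Decoder sparsity-error trade-off. Default 0.25.
#' @param n_trials Number of stimulation trials T. Default
#'   `N_obsCell / 2`, the headline half-of-sequential budget.
#' @param topology `"uniform"` or `"watts_strogatz"`.
#' @param excitatory_fraction Fraction of excitatory cells. Default 0.8.
#' @param exc_max,inh_max Weight-magnitude bounds (see
#'   [weight_sampler_uniform()]).
#' @param dt Simulation step, ms. Default 0.5.
#' @param interval Inter-trial interval, ms. Default 50.
#' @param warmup Settling time before the first trial, ms. Default 500.
#' @param target_rate Spontaneous-rate calibration target, Hz. Default 0.2.
#' @param rel_threshold Connection declaration threshold. Default 0.01.
#' @param retain_self_trials Keep self-stimulation trials in the decoding.
#'   Default `FALSE`.
#' @return A named list of class `cocomap_config`.
#' @export
cocomap_config <- function(TotalCells = 1000, N_obsCell = 200,
                           sparsity = 0.1, fractionStim = 0.1,
                           offTargetProb = 0, synFailProb = 0,
                           latency_mean = 1.0, latency_sd = 0.0,
                           WSbeta = 1.0, lambda = 0.25,
                           n_trials = NULL,
                           topology = c("uniform", "watts_strogatz"),
                           excitatory_fraction = 0.8,
                           exc_max = 10, inh_max = 20,
                           dt = 0.5, interval = 50, warmup = 500,
                           target_rate = 0.2, rel_threshold = 0.01,
                           retain_self_trials = FALSE) {
  topology <- match.arg(topology)
  if (is.null(n_trials)) n_trials <- as.integer(round(N_obsCell / 2))
  cfg <- list(TotalCells = TotalCells, N_obsCell = N_obsCell,
              sparsity = sparsity, fractionStim = fractionStim,
              offTargetProb = offTargetProb, synFailProb = synFailProb,
              latency_mean = latency_mean, latency_sd = latency_sd,
              WSbeta = WSbeta, lambda = lambda, n_trials = n_trials,
              topology = topology,
              excitatory_fraction = excitatory_fraction,
              exc_max = exc_max, inh_max = inh_max,
              dt = dt, interval = interval, warmup = warmup,
              target_rate = target_rate, rel_threshold = rel_threshold,
              retain_self_trials = retain_self_trials)
  structure(cfg, class = c("cocomap_config", "list"))
}

#' Read or write a configuration file
#'
#' Flat key-value YAML or JSON (by file extension) using the conventional
#' parameter names; unknown keys are rejected.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return For `read_config()`, a `cocomap_config`.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(cocomap_config)))
  if (length(unknown))
    stop("Unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(cocomap_config, vals)
}

#' @param config A `cocomap_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(unclass(config), path)
  else jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                            digits = NA)
  invisible(path)
}

build_network_from_config <- function(config) {
  build_network(config$TotalCells, config$sparsity,
                topology = config$topology, ws_beta = config$WSbeta,
                n_observed = config$N_obsCell,
                excitatory_fraction = config$excitatory_fraction,
                weights = weight_sampler_uniform(config$exc_max,
                                                 config$inh_max))
}

#' Run one complete mapping experiment
#'
#' The full pipeline on a freshly generated ground-truth network: build the
#' network, calibrate (or reuse) the background-noise level, draw the
#' stimulation matrix and schedule, simulate, extract responses (single
#' step for fixed latency, decay-normalised window for random latency),
#' decode every observed cell, threshold, and score against ground truth.
#'
#' @param config A [cocomap_config()].
#' @param mode Decoder mode, see [decode_connectivity()].
#' @param noise_sigma Background current s.d.; calibrated from scratch if
#'   `NULL` (see [calibrate_background_noise()]).
#' @param network Optional pre-built `ground_truth_network` to map instead
#'   of generating one (its size must match the configuration).
#' @param keep_recording Retain the full voltage traces in the returned
#'   object (large). Default `FALSE`.
#' @return A `cocomap_run`: list with the network, reconstruction,
#'   measurement set, confusion counts, and a one-row `metrics` tibble
#'   (recall, precision, counts, mean firing rate, sigma).
#' @examples
#' \donttest{
#' set.seed(1)
#' cfg <- cocomap_config(TotalCells = 120, N_obsCell = 60, n_trials = 40)
#' run <- map_connectivity(cfg, noise_sigma = 2)
#' glance(run)
#' }
#' @export
map_connectivity <- function(config = cocomap_config(),
                             mode = c("unconstrained",
                                      "oracle_sign_constrained",
                                      "inferred_sign_constrained"),
                             noise_sigma = NULL, network = NULL,
                             keep_recording = FALSE) {
  mode <- match.arg(mode)
  if (is.null(network)) network <- build_network_from_config(config)
  params <- neuron_params(network$labels)
  if (is.null(noise_sigma)) {
    cal <- calibrate_background_noise(network, config$target_rate,
                                      params = params, dt = config$dt)
    noise_sigma <- cal$sigma
  }
  M <- generate_stimulation_matrix(config$n_trials, config$N_obsCell,
                                   config$fractionStim)
  schedule <- schedule_trials(config$n_trials, config$dt, config$interval,
                              config$warmup)
  recording <- run_mapping_experiment(
    network, M, schedule, noise_sigma, params = params,
    syn_fail_prob = config$synFailProb,
    off_target_prob = config$offTargetProb,
    latency_mean = config$latency_mean, latency_sd = config$latency_sd)
  measurements <- if (config$latency_sd > 0)
    extract_windowed_responses(recording,
                               retain_self_trials = config$retain_self_trials)
  else
    extract_point_responses(recording,
                            retain_self_trials = config$retain_self_trials)
  reconstruction <- decode_connectivity(
    measurements, M, lambda = config$lambda, mode = mode,
    types = network$labels[network$observed],
    rel_threshold = config$rel_threshold)
  counts <- confusion_counts(reconstruction$adjacency, network)
  metrics <- tibble::tibble(
    mode = mode, n_trials = config$n_trials,
    recall = recall(counts), precision = precision(counts),
    tp = counts$tp, fp = counts$fp, fn = counts$fn, tn = counts$tn,
    mean_rate = mean_firing_rate(recording), noise_sigma = noise_sigma)
  structure(
    list(config = config, network = network,
         recording = if (keep_recording) recording else NULL,
         measurements = measurements, reconstruction = reconstruction,
         counts = counts, metrics = metrics, noise_sigma = noise_sigma),
    class = "cocomap_run")
}

#' @export
print.cocomap_run <- function(x, ...) {
  cat(sprintf("<cocomap_run> %d/%d cells observed, T = %d trials, mode %s\n",
              x$config$N_obsCell, x$config$TotalCells, x$config$n_trials,
              x$reconstruction$mode))
  cat(sprintf("  recall %.3f, precision %.3f (tp %d, fp %d, fn %d)\n",
              x$metrics$recall, x$metrics$precision,
              x$counts$tp, x$counts$fp, x$counts$fn))
  invisible(x)
}

#' @rdname map_connectivity
#' @param x A `cocomap_run`.
#' @param ... Unused.
#' @export
glance.cocomap_run <- function(x, ...) x$metrics

#' Tabulate estimated against true connections
#'
#' @param x A `cocomap_run`.
#' @param ... Unused.
#' @return Tibble with one row per ordered observed pair: `post`, `pre`,
#'   `estimate`, `truth`, `declared`, `connected`.
#' @export
tidy.cocomap_run <- function(x, ...) {
  est <- x$reconstruction$x_hat
  tru <- as.matrix(x$network$weights[x$network$observed, x$network$observed])
  n <- nrow(est)
  out <- tibble::tibble(
    post = rep(seq_len(n), times = n),
    pre = rep(seq_len(n), each = n),
    estimate = as.vector(est),
    truth = as.vector(tru),
    declared = as.vector(x$reconstruction$adjacency) == 1L,
    connected = as.vector(tru) != 0)
  dplyr::filter(out, .data$post != .data$pre)
}

#' Sweep one experiment parameter over a grid
#'
#' Re-runs the full pipeline for every value of one parameter over
#' `n_seeds` independent replicates, holding every other parameter at its
#' base value. The background-noise level is calibrated once per grid
#' value (on the first replicate's network) and reused across that value's
#' replicates. Each row is an independent experiment fully determined by
#' `seed + replicate`, so any execution order gives identical results.
#'
#' @param parameter Name of a [cocomap_config()] field, e.g. `"sparsity"`.
#' @param grid Vector of values for that parameter.
#' @param n_seeds Replicates per value. Default 5.
#' @param base Base configuration. Default [cocomap_config()].
#' @param mode Decoder mode.
#' @param seed Base random seed; replicate r of value v runs under
#'   `seed + r - 1`.
#' @return A `cocomap_sweep` tibble: one row per (value, seed) with recall,
#'   precision, mean firing rate, noise sigma and any error message.
#' @export
run_parameter_sweep <- function(parameter, grid, n_seeds = 5,
                                base = cocomap_config(),
                                mode = "unconstrained", seed = 1) {
  if (!parameter %in% names(base))
    stop(sprintf("Unknown parameter '%s'.", parameter), call. = FALSE)
  # Parameters that change the network or its spontaneous dynamics force a
  # recalibration per grid value; the rest share one calibrated sigma.
  network_affecting <- c("TotalCells", "sparsity", "WSbeta", "topology",
                         "excitatory_fraction", "exc_max", "inh_max",
                         "target_rate", "dt")
  shared_sigma <- NULL
  rows <- list()
  for (value in grid) {
    cfg <- base
    cfg[[parameter]] <- value
    # Trial budgets track the observed-ensemble size (half of it, the
    # headline compression) unless the caller fixed n_trials explicitly.
    if (parameter == "N_obsCell")
      cfg$n_trials <- as.integer(round(value / 2))
    sigma <- if (parameter %in% network_affecting) NULL else shared_sigma
    for (r in seq_len(n_seeds)) {
      run_seed <- seed + r - 1L
      set.seed(run_seed)
      row <- tryCatch({
        run <- map_connectivity(cfg, mode = mode, noise_sigma = sigma)
        sigma <- run$noise_sigma
        shared_sigma <- run$noise_sigma
        tibble::tibble(parameter = parameter, value = value,
                       n_trials = cfg$n_trials, seed = run_seed,
                       recall = run$metrics$recall,
                       precision = run$metrics$precision,
                       mean_rate = run$metrics$mean_rate,
                       noise_sigma = run$noise_sigma,
                       error = NA_character_)
      }, error = function(e) {
        tibble::tibble(parameter = parameter, value = value,
                       n_trials = cfg$n_trials, seed = run_seed,
                       recall = NA_real_, precision = NA_real_,
                       mean_rate = NA_real_, noise_sigma = NA_real_,
                       error = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cocomap_sweep", class(out))
  out
}

#' Plot a parameter sweep
#'
#' Mean recall and precision (with one standard deviation ribbons) against
#' the swept parameter.
#'
#' @param object A `cocomap_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cocomap_sweep <- function(object, ...) {
  summ <- object |>
    tidyr_pivot() |>
    dplyr::group_by(.data$value, .data$metric) |>
    dplyr::summarise(mean = mean(.data$score, na.rm = TRUE),
                     sd = stats::sd(.data$score, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$value, .data$mean,
                                     colour = .data$metric,
                                     fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(object$parameter), y = "score",
                  colour = NULL, fill = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

tidyr_pivot <- function(df) {
  dplyr::bind_rows(
    dplyr::transmute(df, value = .data$value, metric = "recall",
                     score = .data$recall),
    dplyr::transmute(df, value = .data$value, metric = "precision",
                     score = .data$precision))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
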