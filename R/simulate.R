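#' Draw Izhikevich neuron parameters by cell type
#'
#' Parameters are randomised over the biophysical range following the
#' classical heterogeneous E/I network recipe: excitatory cells interpolate
#' from regular-spiking towards chattering with `(a, b) = (0.02, 0.2)`,
#' `(c, d) = (-65 + 15 r^2, 8 - 6 r^2)`; inhibitory cells interpolate from
#' fast-spiking towards low-threshold-spiking with
#' `(a, b) = (0.02 + 0.08 r, 0.25 - 0.05 r)`, `(c, d) = (-65, 2)`, with an
#' independent r drawn uniformly on (0, 1) per cell.
#'
#' @param labels Cell-type label vector (see [assign_cell_types()]).
#' @return A tibble with columns `a`, `b`, `c`, `d`, one row per neuron.
#' @export
neuron_params <- function(labels) {
  n <- length(labels)
  r <- stats::runif(n)
  exc <- labels == "excitatory"
  tibble::tibble(
    a = ifelse(exc, 0.02, 0.02 + 0.08 * r),
    b = ifelse(exc, 0.2, 0.25 - 0.05 * r),
    c = ifelse(exc, -65 + 15 * r^2, -65),
    d = ifelse(exc, 8 - 6 * r^2, 2)
  )
}

#' One forward-Euler step of the Izhikevich model
#'
#' Advances membrane voltage `v` and recovery variable `u` by one step of
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`, `du/dt = a (b v - u)`. If the
#' updated voltage reaches the 30 mV spike cutoff the neuron spikes and the
#' state resets to `(c, u + d)`.
#'
#' @param state List with numeric `v` (mV) and `u`.
#' @param params List or one-row data frame with `a`, `b`, `c`, `d`.
#' @param input_current Injected current for this step.
#' @param dt Step size, ms. Default 0.5.
#' @return List with `v`, `u`, and logical `spiked`.
#' @examples
#' # Resting fixed point of a regular-spiking cell:
#' izhikevich_step(list(v = -70, u = -14),
#'                 list(a = 0.02, b = 0.2, c = -65, d = 8), 0)
#' @export
izhikevich_step <- function(state, params, input_current, dt = 0.5) {
  v <- state$v; u <- state$u
  vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + input_current)
  un <- u + dt * params$a * (params$b * v - u)
  if (!is.finite(vn))
    stop("Non-finite membrane voltage after step.", call. = FALSE)
  if (vn >= 30)
    list(v = params$c, u = un + params$d, spiked = TRUE)
  else
    list(v = vn, u = un, spiked = FALSE)
}

#' Simulate a single neuron under a prescribed current series
#'
#' Convenience wrapper around the compiled single-neuron path. The returned
#' voltage trace is clamped to 30 mV at spike steps, as in recordings.
#'
#' @inheritParams izhikevich_step
#' @param input_current Numeric vector, one current value per step.
#' @param v0,u0 Initial state. Defaults: `v0 = -65`, `u0 = b * v0`.
#' @return List with `v`, `u` traces and integer `spikes` (spike steps).
#' @export
izhikevich_trace <- function(params, input_current, dt = 0.5,
                             v0 = -65, u0 = params$b * v0) {
  izhikevich_trace_cpp(params$a, params$b, params$c, params$d,
                       as.numeric(input_current), dt, v0, u0)
}

#' Draw per-connection propagation delays
#'
#' Each connection's latency is a normal draw rounded to the nearest time
#' step and clipped to a minimum of one step; delays are frozen for the
#' whole run.
#'
#' @param n_connections Number of stored connections.
#' @param latency_mean,latency_sd Latency mean and s.d., ms.
#' @param dt Step size, ms.
#' @return Integer vector of step delays (length `n_connections`).
#' @export
draw_latency_delays <- function(n_connections, latency_mean, latency_sd,
                                dt = 0.5) {
  if (latency_mean <= 0) stop("`latency_mean` must be > 0.", call. = FALSE)
  if (latency_sd < 0) stop("`latency_sd` must be >= 0.", call. = FALSE)
  lat <- if (latency_sd > 0)
    stats::rnorm(n_connections, latency_mean, latency_sd)
  else rep(latency_mean, n_connections)
  pmax(1L, as.integer(round(lat / dt)))
}

#' Run a full stimulation-mapping experiment
#'
#' Steps the recurrent network through the trial schedule: on every trial
#' step the cells flagged in the scheduled row of `M` are forced to their
#' firing threshold (their stimulation current is assumed known); every
#' presynaptic spike delivers its synaptic weight as an instantaneous
#' current increment to each target after the connection's frozen
#' propagation delay, independently zeroed with probability
#' `syn_fail_prob` per (spike, connection) event; with probability
#' `off_target_prob` per trial one uniformly chosen cell outside the
#' stimulated set is also forced to spike (logged, never reflected in `M`);
#' and a zero-mean Gaussian current of s.d. `noise_sigma` is injected into
#' every cell at every step.
#'
#' @param network A `ground_truth_network`.
#' @param M Stimulation matrix from [generate_stimulation_matrix()]
#'   (columns = observed cells, in the order of `network$observed`).
#' @param schedule Trial schedule from [schedule_trials()].
#' @param noise_sigma Background current s.d. (see
#'   [calibrate_background_noise()]).
#' @param params Neuron parameter tibble; drawn via [neuron_params()] if
#'   `NULL`.
#' @param syn_fail_prob,off_target_prob Probabilities in `[0, 1]`.
#' @param latency_mean,latency_sd Per-connection latency model, ms.
#' @param n_steps Total steps; default runs one full inter-trial interval
#'   past the last trial.
#' @param record_voltages Keep the observed-cell voltage traces (needed for
#'   response extraction). Default `TRUE`.
#' @return An `experiment_recording`: observed voltage traces
#'   (cells x steps), spike table, schedule, `M`, off-target log, event
#'   counts and the simulation settings.
#' @export
run_mapping_experiment <- function(network, M, schedule, noise_sigma,
                                   params = NULL,
                                   syn_fail_prob = 0, off_target_prob = 0,
                                   latency_mean = 1.0, latency_sd = 0.0,
                                   n_steps = NULL, record_voltages = TRUE) {
  if (syn_fail_prob < 0 || syn_fail_prob > 1)
    stop("`syn_fail_prob` must be in [0, 1].", call. = FALSE)
  if (off_target_prob < 0 || off_target_prob > 1)
    stop("`off_target_prob` must be in [0, 1].", call. = FALSE)
  if (ncol(M) != length(network$observed))
    stop("`M` must have one column per observed cell.", call. = FALSE)
  if (nrow(M) != length(schedule))
    stop("`schedule` must have one trial per row of `M`.", call. = FALSE)
  dt <- attr(schedule, "dt")
  if (is.null(n_steps))
    n_steps <- if (length(schedule)) max(schedule) + attr(schedule, "interval_steps")
               else as.integer(round(1000 / dt))
  if (length(schedule) && max(schedule) > n_steps)
    stop("Trial schedule does not fit in `n_steps`.", call. = FALSE)
  if (is.null(params)) params <- neuron_params(network$labels)

  W <- methods::as(network$weights, "CsparseMatrix")
  delays <- draw_latency_delays(length(W@x), latency_mean, latency_sd, dt)
  res <- run_experiment_cpp(
    W@p, W@i, W@x, delays,
    params$a, params$b, params$c, params$d,
    as.integer(network$observed), M, as.integer(schedule),
    as.integer(n_steps), dt, noise_sigma, syn_fail_prob, off_target_prob,
    record_voltages
  )
  structure(
    list(
      voltages = res$voltages,
      spikes = tibble::tibble(neuron = res$spike_neuron, step = res$spike_step),
      spike_counts = res$spike_counts,
      schedule = schedule,
      M = M,
      off_target_log = ifelse(res$off_target == 0L, NA_integer_, res$off_target),
      noise_sigma = noise_sigma,
      observed = network$observed,
      dt = dt,
      n_steps = as.integer(n_steps),
      latency_mean = latency_mean,
      latency_sd = latency_sd,
      syn_fail_prob = syn_fail_prob,
      off_target_prob = off_target_prob,
      n_transmission_events = res$n_transmission_events,
      n_failed_events = res$n_failed_events,
      params = params
    ),
    class = "experiment_recording"
  )
}

#' @export
print.experiment_recording <- function(x, ...) {
  cat(sprintf(
    "<experiment_recording> %d trials, %d steps (dt = %g ms), %d observed cells\n",
    nrow(x$M), x$n_steps, x$dt, length(x$observed)))
  cat(sprintf("  %d spikes; noise sigma %.3g; mean rate %.3g Hz\n",
              nrow(x$spikes), x$noise_sigma, mean_firing_rate(x)))
  invisible(x)
}

#' Network-mean firing rate of a recording
#'
#' Total spikes divided by (number of cells in the network x simulated
#' seconds).
#'
#' @param recording An `experiment_recording`.
#' @return Rate in Hz.
#' @export
mean_firing_rate <- function(recording) {
  seconds <- recording$n_steps * recording$dt / 1000
  sum(recording$spike_counts) / (length(recording$spike_counts) * seconds)
}

#' Calibrate the background current to a target spontaneous rate
#'
#' Bisects the per-step Gaussian current s.d. until a stimulation-free
#' simulation reproduces the target network-mean spontaneous firing rate
#' (0.2 Hz by default). The search brackets sigma in `bracket`, evaluates
#' each candidate on `sim_seconds` of spontaneous activity, and accepts a
#' candidate within `tolerance * target_rate` of the target.
#'
#' @param network A `ground_truth_network`.
#' @param target_rate Target network-mean rate, Hz. Default 0.2.
#' @param sim_seconds Evaluation run length per candidate, s. Default 30.
#' @param tolerance Relative tolerance on the achieved rate. Default 0.1.
#' @param params Neuron parameters; drawn if `NULL`.
#' @param dt Step size, ms.
#' @param bracket Search interval for sigma. Default `c(0, 20)`.
#' @param max_iter Bisection iterations before giving up. Default 20.
#' @return A `noise_calibration`: list with `sigma`, `achieved_rate`, and
#'   the search `trace` (tibble of sigma/rate pairs).
#' @export
calibrate_background_noise <- function(network, target_rate = 0.2,
                                       sim_seconds = 30, tolerance = 0.1,
                                       params = NULL, dt = 0.5,
                                       bracket = c(0, 20), max_iter = 20) {
  if (target_rate <= 0) stop("`target_rate` must be > 0.", call. = FALSE)
  if (is.null(params)) params <- neuron_params(network$labels)
  n_steps <- as.integer(round(sim_seconds * 1000 / dt))
  W <- methods::as(network$weights, "CsparseMatrix")
  delays <- rep(1L, length(W@x))
  n <- length(network$labels)
  no_trials <- matrix(0L, 0, length(network$observed))

  rate_at <- function(sigma) {
    res <- run_experiment_cpp(
      W@p, W@i, W@x, delays, params$a, params$b, params$c, params$d,
      as.integer(network$observed), no_trials, integer(0),
      n_steps, dt, sigma, 0, 0, FALSE)
    sum(res$spike_counts) / (n * sim_seconds)
  }

  lo <- bracket[1]; hi <- bracket[2]
  trace <- list()
  r_hi <- rate_at(hi)
  trace[[1]] <- c(sigma = hi, rate = r_hi)
  if (r_hi < target_rate * (1 - tolerance))
    stop(sprintf(
      "Calibration failed: rate %.4g Hz at the upper bracket sigma = %g.",
      r_hi, hi), call. = FALSE)
  best <- c(sigma = hi, rate = r_hi)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    trace[[length(trace) + 1]] <- c(sigma = mid, rate = r)
    if (abs(r - target_rate) < abs(best["rate"] - target_rate))
      best <- c(sigma = mid, rate = r)
    if (abs(r - target_rate) <= tolerance * target_rate) {
      best <- c(sigma = mid, rate = r)
      break
    }
    if (r < target_rate) lo <- mid else hi <- mid
  }
  if (abs(best["rate"] - target_rate) > tolerance * target_rate)
    stop(sprintf(
      "Calibration did not converge in %d iterations (best rate %.4g Hz at sigma = %.4g).",
      max_iter, best["rate"], best["sigma"]), call. = FALSE)
  structure(
    list(sigma = unname(best["sigma"]),
         achieved_rate = unname(best["rate"]),
         target_rate = target_rate,
         trace = dplyr::bind_rows(lapply(trace, \(x) tibble::as_tibble(as.list(x))))),
    class = "noise_calibration"
  )
}

#' @export
print.noise_calibration <- function(x, ...) {
  cat(sprintf(
    "<noise_calibration> sigma = %.4g (achieved %.4g Hz, target %g Hz, %d evaluations)\n",
    x$sigma, x$achieved_rate, x$target_rate, nrow(x$trace)))
  invisible(x)
}

#' Export an experiment recording as a directory bundle
#'
#' Writes the observed-voltage array as an RDS binary container
#' (`voltages.rds`), the spike raster and off-target log as CSV, the
#' stimulation matrix as CSV, the trial schedule as JSON, and the run
#' settings as JSON.
#'
#' @param recording An `experiment_recording`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(recording$voltages))
    saveRDS(recording$voltages, file.path(dir, "voltages.rds"))
  utils::write.csv(recording$spikes, file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(trial = seq_along(recording$off_target_log),
               off_target = recording$off_target_log),
    file.path(dir, "off_target_log.csv"), row.names = FALSE)
  utils::write.csv(recording$M, file.path(dir, "stimulation_matrix.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(trial_steps = as.integer(recording$schedule),
         dt = recording$dt,
         interval = attr(recording$schedule, "interval"),
         warmup = attr(recording$schedule, "warmup")),
    file.path(dir, "schedule.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(noise_sigma = recording$noise_sigma, dt = recording$dt,
         n_steps = recording$n_steps,
         latency_mean = recording$latency_mean,
         latency_sd = recording$latency_sd,
         synFailProb = recording$syn_fail_prob,
         offTargetProb = recording$off_target_prob,
         observed = recording$observed),
    file.path(dir, "settings.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
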