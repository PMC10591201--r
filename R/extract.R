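new_measurement_set <- function(y, excluded, offset = NULL, window = NULL,
                                decay = NULL) {
  structure(list(y = y, excluded = excluded, offset = offset,
                 window = window, decay = decay),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set> %d trials x %d cells (%s extraction), %d responses excluded\n",
              nrow(x$y), ncol(x$y),
              if (is.null(x$window)) "point" else "windowed",
              sum(x$excluded)))
  invisible(x)
}

self_trial_mask <- function(M, retain_self_trials) {
  if (retain_self_trials) matrix(FALSE, nrow(M), ncol(M)) else M == 1L
}

#' Extract single-step trial responses
#'
#' For fixed (zero-s.d.) latency, the response of observed cell n on trial t
#' is the one-step voltage change at the arrival of the stimulation-evoked
#' synaptic currents: `y[t, n] = v_n(s + k) - v_n(s + k - 1)` where `s` is
#' the trial step and the offset `k` defaults to the latency mean expressed
#' in steps, so the measurement lands on the post-synaptic potential.
#'
#' Trials in which the measured cell was itself stimulated are flagged in
#' the exclusion mask and (by default) dropped from that cell's own
#' decoding, since the forced supra-threshold spike and reset swamp the
#' sub-threshold measurement. Set `retain_self_trials = TRUE` to keep them.
#'
#' @param recording An `experiment_recording` with voltage traces.
#' @param offset_steps Measurement offset in steps after the trial step;
#'   default `round(latency_mean / dt)`.
#' @param retain_self_trials Keep trials where the measured cell was
#'   stimulated. Default `FALSE`.
#' @return A `measurement_set` with `y` and `excluded` (trials x cells).
#' @export
extract_point_responses <- function(recording, offset_steps = NULL,
                                    retain_self_trials = FALSE) {
  V <- recording$voltages
  if (is.null(V) || !length(V))
    stop("Recording has no voltage traces.", call. = FALSE)
  if (is.null(offset_steps))
    offset_steps <- max(1L, as.integer(round(recording$latency_mean / recording$dt)))
  steps <- as.integer(recording$schedule) + offset_steps
  if (any(steps > recording$n_steps))
    stop("Measurement window exceeds the end of the recording.", call. = FALSE)
  y <- t(V[, steps, drop = FALSE] - V[, steps - 1L, drop = FALSE])
  excluded <- self_trial_mask(recording$M, retain_self_trials)
  new_measurement_set(y, excluded, offset = offset_steps)
}

#' Estimate per-cell passive voltage decay
#'
#' Estimates the one-step decay ratio of each observed cell as the mean of
#' `v(t + 1) / v(t)` over all post-stimulation window steps, excluding
#' steps adjacent to a spike (the reset breaks the ratio) and steps where
#' `|v(t)|` is below 1e-6 mV. Cells with no valid step get ratio 1 with a
#' warning.
#'
#' @param recording An `experiment_recording`.
#' @param windows Integer matrix (trials x 2) of first/last step per
#'   post-stimulation interval, or `NULL` to use each trial's
#'   inter-trial window.
#' @return Numeric vector of decay ratios, one per observed cell.
#' @export
estimate_voltage_decay <- function(recording, windows = NULL) {
  V <- recording$voltages
  if (is.null(windows)) {
    s <- as.integer(recording$schedule)
    len <- attr(recording$schedule, "interval_steps") - 1L
    windows <- cbind(s + 1L, pmin(s + len, recording$n_steps - 1L))
  }
  if (!nrow(windows)) stop("`windows` must be non-empty.", call. = FALSE)
  steps <- unlist(lapply(seq_len(nrow(windows)),
                         function(i) seq.int(windows[i, 1], windows[i, 2])))
  steps <- steps[steps < recording$n_steps]
  v0 <- V[, steps, drop = FALSE]
  v1 <- V[, steps + 1L, drop = FALSE]
  valid <- abs(v0) >= 1e-6 & v0 != 30 & v1 != 30
  ratio <- v1 / v0
  ratio[!valid] <- NA_real_
  out <- rowMeans(ratio, na.rm = TRUE)
  none <- !is.finite(out) | rowSums(valid) == 0
  if (any(none)) {
    warning(sprintf("%d cell(s) had no valid decay steps; using ratio 1.",
                    sum(none)), call. = FALSE)
    out[none] <- 1
  }
  out
}

#' Extract decay-normalised windowed trial responses
#'
#' With random per-connection latency, evoked currents arrive spread over
#' several steps, so responses are summed over a window covering the mean
#' plus three standard deviations of the latency distribution. At each step
#' the decay-predicted voltage is subtracted before summing:
#' `y[t, n] = sum over the window of v_n(s' + 1) - decay_n * v_n(s')`,
#' which accumulates the stimulation-evoked increments while cancelling
#' passive relaxation regardless of where in the window each delayed input
#' lands.
#'
#' @inheritParams extract_point_responses
#' @param decay Per-cell decay ratios; estimated via
#'   [estimate_voltage_decay()] if `NULL`.
#' @param window_steps Window length in steps; default
#'   `ceiling((latency_mean + 3 * latency_sd) / dt)`, truncated (with a
#'   warning) if it would overlap the next trial.
#' @return A `measurement_set`.
#' @export
extract_windowed_responses <- function(recording, decay = NULL,
                                       window_steps = NULL,
                                       retain_self_trials = FALSE) {
  V <- recording$voltages
  if (is.null(window_steps))
    window_steps <- as.integer(ceiling(
      (recording$latency_mean + 3 * recording$latency_sd) / recording$dt))
  window_steps <- max(1L, window_steps)
  max_window <- attr(recording$schedule, "interval_steps")
  if (window_steps > max_window) {
    warning(sprintf(
      "Window of %d steps overlaps the next trial; truncated to %d.",
      window_steps, max_window), call. = FALSE)
    window_steps <- max_window
  }
  if (is.null(decay)) decay <- estimate_voltage_decay(recording)
  s <- as.integer(recording$schedule)
  if (any(s + window_steps > recording$n_steps))
    stop("Measurement window exceeds the end of the recording.", call. = FALSE)
  y <- matrix(0, length(s), nrow(V))
  for (k in seq_len(window_steps)) {
    y <- y + t(V[, s + k, drop = FALSE] - decay * V[, s + k - 1L, drop = FALSE])
  }
  excluded <- self_trial_mask(recording$M, retain_self_trials)
  new_measurement_set(y, excluded, window = window_steps, decay = decay)
}

#' Export a measurement set as CSV files
#'
#' Writes `responses.csv` (trials x cells) and `excluded.csv` (0/1 mask).
#'
#' @param measurements A `measurement_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_measurements <- function(measurements, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  y <- measurements$y
  colnames(y) <- paste0("cell", seq_len(ncol(y)))
  utils::write.csv(y, file.path(dir, "responses.csv"), row.names = FALSE)
  ex <- matrix(as.integer(measurements$excluded), nrow(y),
               dimnames = list(NULL, colnames(y)))
  utils::write.csv(ex, file.path(dir, "excluded.csv"), row.names = FALSE)
  invisible(dir)
}
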