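#' Generate a binary random stimulation matrix
#'
#' Rows are trials, columns are observed neurons; a 1 means the cell is
#' force-spiked on that trial. Entries are i.i.d. Bernoulli(`fraction_stim`),
#' so the number of cells stimulated per trial fluctuates binomially around
#' `fraction_stim * n_obs`. Set `exact_row_count = TRUE` to instead stimulate
#' exactly `round(fraction_stim * n_obs)` cells per trial (a fixed-count
#' variant for sensitivity checks).
#'
#' @param n_trials Number of trials T.
#' @param n_obs Number of observed neurons N.
#' @param fraction_stim Per-entry stimulation probability, in `(0, 1]`.
#' @param exact_row_count Use a fixed per-row count instead of i.i.d.
#'   entries. Default `FALSE`.
#' @return Integer 0/1 matrix of dimension `n_trials x n_obs` with attribute
#'   `fraction_stim`.
#' @examples
#' set.seed(1)
#' M <- generate_stimulation_matrix(5, 10, 0.3)
#' rowSums(M)
#' @export
generate_stimulation_matrix <- function(n_trials, n_obs, fraction_stim,
                                        exact_row_count = FALSE) {
  if (n_trials < 1 || n_obs < 1)
    stop("`n_trials` and `n_obs` must be >= 1.", call. = FALSE)
  if (fraction_stim <= 0 || fraction_stim > 1)
    stop("`fraction_stim` must be in (0, 1]: with 0 no cell would ever be stimulated.",
         call. = FALSE)
  n_trials <- as.integer(n_trials); n_obs <- as.integer(n_obs)
  if (exact_row_count) {
    per_row <- max(1L, as.integer(floor(fraction_stim * n_obs + 0.5)))
    M <- matrix(0L, n_trials, n_obs)
    for (t in seq_len(n_trials)) M[t, sample.int(n_obs, per_row)] <- 1L
  } else {
    M <- matrix(as.integer(stats::runif(n_trials * n_obs) < fraction_stim),
                n_trials, n_obs)
  }
  attr(M, "fraction_stim") <- fraction_stim
  M
}

#' Schedule stimulation trials on the simulation clock
#'
#' One trial is carried out every `interval` ms (default 50 ms), consuming
#' the rows of the stimulation matrix in order, each row exactly once. A
#' warm-up period precedes the first trial so the network settles into its
#' spontaneous regime. Trial `t` lands on step
#' `warmup/dt + t * interval/dt`.
#'
#' @param n_trials Number of trials (rows of M).
#' @param dt Simulation step, ms. Default 0.5.
#' @param interval Inter-trial interval, ms; must be a multiple of `dt`.
#'   Default 50.
#' @param warmup Settling time before the first trial, ms; must be a
#'   multiple of `dt`. Default 500.
#' @return Object of class `trial_schedule`: integer vector of trial steps
#'   with attributes `dt`, `interval`, `warmup`, `interval_steps`.
#' @examples
#' schedule_trials(3, dt = 0.5, interval = 50, warmup = 0)
#' @export
schedule_trials <- function(n_trials, dt = 0.5, interval = 50, warmup = 500) {
  if (abs(interval / dt - round(interval / dt)) > 1e-9)
    stop("`interval` must be a multiple of `dt`.", call. = FALSE)
  if (abs(warmup / dt - round(warmup / dt)) > 1e-9)
    stop("`warmup` must be a multiple of `dt`.", call. = FALSE)
  steps <- as.integer(round(warmup / dt) + seq_len(n_trials) * round(interval / dt))
  structure(steps, dt = dt, interval = interval, warmup = warmup,
            interval_steps = as.integer(round(interval / dt)),
            class = "trial_schedule")
}
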