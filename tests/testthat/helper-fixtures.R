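# Shared fixtures, all generated in code.

# A small network with a fixed seed.
small_net <- function(n = 60, p = 0.1, n_obs = n, seed = 101, ...) {
  set.seed(seed)
  build_network(n, p, n_observed = n_obs, ...)
}

# Minimal fake recording wrapping a given observed-voltage matrix, enough
# for the extraction functions.
fake_recording <- function(voltages, trial_steps, M,
                           dt = 0.5, interval = 50,
                           latency_mean = 1, latency_sd = 0) {
  schedule <- structure(as.integer(trial_steps), dt = dt,
                        interval = interval, warmup = 0,
                        interval_steps = as.integer(round(interval / dt)),
                        class = "trial_schedule")
  structure(
    list(voltages = voltages, schedule = schedule, M = M,
         observed = seq_len(nrow(voltages)), dt = dt,
         n_steps = ncol(voltages), latency_mean = latency_mean,
         latency_sd = latency_sd),
    class = "experiment_recording")
}

# Independent forward-Euler reference for the adopted neuron equations,
# written as a plain R loop (kept separate from the package's compiled
# path on purpose).
reference_izhikevich <- function(a, b, c, d, I, dt, v0, u0) {
  n <- length(I)
  v <- v0; u <- u0
  v_tr <- numeric(n); spikes <- integer(0)
  for (t in seq_len(n)) {
    vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I[t])
    un <- u + dt * a * (b * v - u)
    if (vn >= 30) {
      v_tr[t] <- 30
      spikes <- c(spikes, t)
      v <- c; u <- un + d
    } else {
      v_tr[t] <- vn
      v <- vn; u <- un
    }
  }
  list(v = v_tr, spikes = spikes)
}

# Exhaustive best-k-sparse support search by least squares over all
# candidate supports (the brute-force oracle for noiseless recovery).
best_sparse_support <- function(M, y, k) {
  combs <- utils::combn(ncol(M), k)
  best <- NULL; best_rss <- Inf
  for (i in seq_len(ncol(combs))) {
    S <- combs[, i]
    fit <- stats::lm.fit(M[, S, drop = FALSE], y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- S
    }
  }
  sort(best)
}
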