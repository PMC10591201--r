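#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler Izhikevich update at step size dt:
//   v' = 0.04 v^2 + 5 v + 140 - u + I
//   u' = a (b v - u)
// spike at v >= 30 mV, reset (v, u) <- (c, u + d).

// Single-neuron trace under a prescribed input current series. Returned
// voltage at a spike step is clamped to the 30 mV cutoff before reset, so
// traces look like recorded spikes. Used as the reference path for tests
// and for decay estimation checks.
// [[Rcpp::export]]
List izhikevich_trace_cpp(double a, double b, double c, double d,
                          NumericVector I, double dt,
                          double v0, double u0) {
  int n = I.size();
  NumericVector v_trace(n), u_trace(n);
  std::vector<int> spikes;
  double v = v0, u = u0;
  for (int t = 0; t < n; ++t) {
    double vn = v + dt * (0.04 * v * v + 5.0 * v + 140.0 - u + I[t]);
    double un = u + dt * a * (b * v - u);
    if (!R_finite(vn))
      stop("Non-finite membrane voltage at step %d.", t + 1);
    if (vn >= 30.0) {
      v_trace[t] = 30.0;
      spikes.push_back(t + 1);
      v = c;
      u = un + d;
    } else {
      v_trace[t] = vn;
      v = vn;
      u = un;
    }
    u_trace[t] = u;
  }
  return List::create(_["v"] = v_trace, _["u"] = u_trace,
                      _["spikes"] = wrap(spikes));
}

// Full network experiment. Connectivity is passed in compressed sparse
// column form (column j = outgoing connections of presynaptic cell j;
// Wi holds 0-based postsynaptic row indices). `delays` holds one integer
// step delay (>= 1) per stored weight: a spike of cell j at step t adds
// Wx[idx] to the input current its target integrates at step t + delay.
//
// Per step, in fixed order (so runs are reproducible given the R seed):
// 1. read and clear the delayed-delivery buffer, add N(0, sigma^2) noise;
// 2. on trial steps, force-spike the scheduled row of M (plus, with
//    probability off_target_prob, one uniformly drawn non-stimulated cell,
//    which is logged but never reflected in M);
// 3. Euler-update all non-forced cells; threshold crossings spike.
// Every presynaptic spike delivers its weight per connection unless the
// per-event synaptic failure draw (probability syn_fail_prob) zeroes it.
// [[Rcpp::export]]
List run_experiment_cpp(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                        IntegerVector delays,
                        NumericVector a, NumericVector b,
                        NumericVector c, NumericVector d,
                        IntegerVector observed, IntegerMatrix M,
                        IntegerVector trial_steps,
                        int n_steps, double dt, double noise_sigma,
                        double syn_fail_prob, double off_target_prob,
                        bool record_voltages) {
  const int n = a.size();
  const int n_obs = observed.size();
  const int n_trials = trial_steps.size();

  int max_delay = 1;
  for (int e = 0; e < delays.size(); ++e)
    if (delays[e] > max_delay) max_delay = delays[e];
  const int L = max_delay + 1;

  std::vector<double> inbox((size_t)L * n, 0.0);
  std::vector<double> v(n), u(n), I(n);
  std::vector<bool> forced(n, false);
  std::vector<int> obs_pos(n, -1);  // 0-based row in the voltage record
  for (int k = 0; k < n_obs; ++k) obs_pos[observed[k] - 1] = k;

  for (int i = 0; i < n; ++i) {
    v[i] = -65.0;
    u[i] = b[i] * v[i];
  }

  NumericMatrix voltages(record_voltages ? n_obs : 0,
                         record_voltages ? n_steps : 0);
  std::vector<int> spike_neuron, spike_step;
  IntegerVector off_target(n_trials);
  IntegerVector spike_counts(n);
  double n_events = 0.0, n_failed = 0.0;
  int next_trial = 0;

  // Deliver one spike of presynaptic cell `j` (0-based) fired at step t.
  auto deliver = [&](int j, int t) {
    for (int e = Wp[j]; e < Wp[j + 1]; ++e) {
      n_events += 1.0;
      if (syn_fail_prob > 0.0 && unif_rand() < syn_fail_prob) {
        n_failed += 1.0;
        continue;
      }
      int slot = (t + delays[e]) % L;
      inbox[(size_t)slot * n + Wi[e]] += Wx[e];
    }
  };

  for (int t = 1; t <= n_steps; ++t) {
    const int slot = t % L;
    double *in_row = &inbox[(size_t)slot * n];
    for (int i = 0; i < n; ++i) {
      I[i] = in_row[i];
      in_row[i] = 0.0;
      if (noise_sigma > 0.0) I[i] += noise_sigma * norm_rand();
    }

    bool is_trial = next_trial < n_trials && trial_steps[next_trial] == t;
    if (is_trial) {
      for (int k = 0; k < n_obs; ++k)
        if (M(next_trial, k) == 1) forced[observed[k] - 1] = true;
      if (off_target_prob > 0.0 && unif_rand() < off_target_prob) {
        int cand;
        do {
          cand = (int)std::floor(unif_rand() * n);
          if (cand >= n) cand = n - 1;
        } while (forced[cand]);
        forced[cand] = true;
        off_target[next_trial] = cand + 1;
      }
    }

    for (int i = 0; i < n; ++i) {
      if (is_trial && forced[i]) {
        // Forced to its firing threshold: spike at the trial step.
        spike_neuron.push_back(i + 1);
        spike_step.push_back(t);
        spike_counts[i]++;
        deliver(i, t);
        if (record_voltages && obs_pos[i] >= 0) voltages(obs_pos[i], t - 1) = 30.0;
        v[i] = c[i];
        u[i] += d[i];
        continue;
      }
      double vn = v[i] + dt * (0.04 * v[i] * v[i] + 5.0 * v[i] + 140.0 - u[i] + I[i]);
      double un = u[i] + dt * a[i] * (b[i] * v[i] - u[i]);
      if (!R_finite(vn))
        stop("Non-finite membrane voltage (neuron %d, step %d).", i + 1, t);
      if (vn >= 30.0) {
        spike_neuron.push_back(i + 1);
        spike_step.push_back(t);
        spike_counts[i]++;
        deliver(i, t);
        if (record_voltages && obs_pos[i] >= 0) voltages(obs_pos[i], t - 1) = 30.0;
        v[i] = c[i];
        u[i] = un + d[i];
      } else {
        if (record_voltages && obs_pos[i] >= 0) voltages(obs_pos[i], t - 1) = vn;
        v[i] = vn;
        u[i] = un;
      }
    }

    if (is_trial) {
      for (int k = 0; k < n_obs; ++k)
        if (M(next_trial, k) == 1) forced[observed[k] - 1] = false;
      if (off_target[next_trial] > 0) forced[off_target[next_trial] - 1] = false;
      ++next_trial;
    }
  }

  return List::create(
    _["voltages"] = voltages,
    _["spike_neuron"] = wrap(spike_neuron),
    _["spike_step"] = wrap(spike_step),
    _["spike_counts"] = spike_counts,
    _["off_target"] = off_target,
    _["n_transmission_events"] = n_events,
    _["n_failed_events"] = n_failed);
}
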