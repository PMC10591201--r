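# cocomap

Compressed connectivity mapping of spiking neuronal networks.

Pairwise sequential circuit mapping — stimulate one candidate presynaptic
neuron per trial, record one postsynaptic response — needs at least as many
trials as candidate neurons. Because cortical connectivity is sparse
(~10% of ordered pairs), the mapping problem is a textbook compressive
sensing instance: stimulate a random *subset* of the observed ensemble on
every trial, record all observed membrane voltages at once, and recover
each cell's presynaptic weight vector by L1-regularised regression from
far fewer trials than neurons.

`cocomap` is a simulation laboratory for that experiment, aimed at
computational neuroscientists and experiment planners who want to know
when compressed mapping works before committing rig time. It provides:

* **Ground-truth generators** — uniform-random and Watts–Strogatz
  small-world digraphs of 80/20 excitatory/inhibitory Izhikevich neurons
  with signed, type-consistent weights, plus import/export of external
  connectivity as plain CSV.
* **A biophysical simulator** (compiled core) — forward-Euler Izhikevich
  dynamics at 0.5 ms steps, emergent background noise calibrated to a
  0.2 Hz spontaneous rate, forced spiking of scheduled stimulation
  patterns every 50 ms, per-connection propagation latency, per-event
  synaptic failure, and off-target stimulation.
* **Response extraction** — single-step voltage changes at PSP arrival,
  or decay-normalised windowed sums under random latency.
* **Decoders** — lasso (`solve_lasso()`), noise-bounded basis pursuit
  (`solve_basis_pursuit()`), and cell-type sign-constrained variants
  (oracle or inferred types), all via an exact box-constrained coordinate
  descent; thresholding at 1% of the strongest reconstructed weight; a
  one-cell-per-trial sequential baseline (`siso_baseline()`).
* **Evaluation and orchestration** — confusion counts, recall
  `TP/(TP+FN)` and precision `TP/(TP+FP)` over observed ordered pairs,
  per-cell metrics, and parameter sweeps (`run_parameter_sweep()`) over
  the standard grid (network size, observability, sparsity, stimulated
  fraction, off-target and failure probabilities, latency, small-world
  beta) with tidy tibble results and `autoplot()`.

The model for observed neuron *n* is `y_n = M x_n + e_n`: `M` the binary
trials × neurons stimulation matrix, `x_n` the unknown presynaptic
weights, `e_n` the mechanistic noise from spontaneous firing and membrane
fluctuations. The decoder solves

```
min_x  lambda * ||x||_1 + 1/2 * ||y - M x||^2    (lambda = 0.25)
```

optionally subject to `x(E) >= 0`, `x(I) <= 0` for known cell types.

## Worked example

A scaled-down experiment (300-cell network, 100 observed, 50 trials —
half the sequential budget) runs in a few seconds:

```r
library(cocomap)
set.seed(1)
cfg <- cocomap_config(TotalCells = 300, N_obsCell = 100, n_trials = 50)
run <- map_connectivity(cfg, noise_sigma = 2)
run
#> <cocomap_run> 100/300 cells observed, T = 50 trials, mode unconstrained
#>   recall 0.733, precision 0.282 (tp 745, fp 1895, fn 272)
glance(run)
#> # A tibble: 1 × 10
#>   mode   n_trials recall precision    tp    fp    fn    tn mean_rate noise_sigma
#>   <chr>     <dbl>  <dbl>     <dbl> <int> <int> <int> <int>     <dbl>       <dbl>
#> 1 uncon…       50  0.733     0.282   745  1895   272  6988     0.917           2
```

Reading the numbers: of the 1,017 true connections among the 100 observed
cells, 745 were recovered from only 50 trials (recall 0.733); the small
relative threshold deliberately over-declares, so precision is lower —
false positives are cheap to check experimentally with targeted follow-up
stimulation, missed connections are not. `mean_rate` is the network-mean
firing rate during the run (Hz); `tidy(run)` returns the full estimated
vs. true edge table. At the full reference scale (1,000 cells, 200
observed, 100 trials) recall reaches ~0.83. Omitting `noise_sigma`
calibrates the background current to the 0.2 Hz spontaneous target first.

Sweeps follow the same pattern:

```r
sw <- run_parameter_sweep("sparsity", c(0.02, 0.1, 0.2), n_seeds = 5,
                          base = cfg)
autoplot(sw)
```

A thin command-line front end wraps the same functions
(`inst/cli/cocomap.R run|sweep|eval`), reading flat YAML/JSON configs
written in the standard parameter names (`TotalCells`, `N_obsCell`,
`sparsity`, `fractionStim`, `offTargetProb`, `synFailProb`,
`latency_mean`, `latency_sd`, `WSbeta`, `lambda`).

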