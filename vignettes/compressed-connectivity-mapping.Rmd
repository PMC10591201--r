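---
title: "Compressed connectivity mapping: model, decoder, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed connectivity mapping: model, decoder, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocomap)
```

## The problem

Mapping synaptic connectivity by stimulating one putative presynaptic
neuron per trial and measuring the postsynaptic response needs at least as
many trials as there are candidate neurons. Cortical connectivity is
sparse (on the order of 10% of ordered pairs are connected), which is
exactly the condition under which compressive sensing recovers a sparse
vector from far fewer linear measurements than unknowns. `cocomap`
simulates that experiment end to end: patterned stimulation of random
subsets of an observed ensemble in a recurrent spiking network, voltage
readout of every observed cell, and L1-regularised reconstruction of each
cell's presynaptic weight vector, scored against the ground truth the
simulator built.

The measurement model for observed cell $n$ is

$$ y_n = M x_n + e_n, \qquad e_n = e_n^{sf} + e_n^{v}, $$

where $M \in \{0,1\}^{T \times N}$ flags which of the $N$ observed cells
were force-spiked on each of $T$ trials, $x_n$ is the unknown vector of
presynaptic weights onto $n$, and the error term collects spontaneous
network firing ($e^{sf}$) and membrane noise ($e^{v}$). Neither error
component is drawn from a distribution: both arise mechanistically inside
the spiking-network simulation. The decoder solves

$$ \min_x \; \lambda \lVert x \rVert_1 + \tfrac12 \lVert y - M x \rVert_2^2 , $$

optionally subject to $x(E) \ge 0$, $x(I) \le 0$ when cell types are known
(or inferred from a first unconstrained pass). Entries larger in magnitude
than 1% of the largest reconstructed weight are declared connections, and
recall and precision are computed over all ordered pairs of observed
cells.

## The network model

Ground truth networks have 80% excitatory and 20% inhibitory Izhikevich
neurons, connected either uniformly at random with probability `sparsity`
or as a directed Watts–Strogatz small world whose per-node out-degree
matches the same expected density. Synapses are instantaneous current
increments: a presynaptic spike adds the connection weight to the
postsynaptic input current after a per-connection propagation delay
(a normal draw rounded to the time step, frozen for the run, minimum one
step). Neuron parameters are randomised per cell over the classical
heterogeneous-network recipe (regular-spiking to chattering excitatory
cells, fast-spiking to low-threshold inhibitory cells). Integration is
forward Euler at `dt = 0.5` ms, the spike cutoff is 30 mV, and every cell
receives an independent zero-mean Gaussian current each step.

Three experimental imperfections are modelled explicitly, each gated by a
probability parameter: per-(spike, connection) synaptic failure
(`synFailProb`), per-trial off-target stimulation of one uniformly chosen
cell outside the addressed pattern (`offTargetProb`, logged but never
reflected in `M`), and propagation latency (`latency_mean`,
`latency_sd`).

### Calibration and the weight scale

Two quantities of the underlying biophysical model are not identifiable
from the published description alone and are fixed by calibration:

* **Background noise.** The per-step current s.d. is bisected until a
  stimulation-free run of the network reproduces a 0.2 Hz network-mean
  spontaneous rate (`calibrate_background_noise()`; 30 s evaluation runs,
  ±10% tolerance, bracket [0, 20]). On the base 1,000-cell network this
  lands near $\sigma \approx 2$, i.e. a per-step voltage kick of
  $dt\,\sigma \approx 1$ mV.
* **Weight magnitudes.** Weight magnitudes are uniform on $(0, w_{max}]$
  with inhibitory synapses twice as strong as excitatory ones. The scale
  is anchored to the model's own detection-floor property: a weight at 1%
  of the strongest connection should move the membrane by about a tenth
  of the background noise level, i.e. the strongest (inhibitory) weight
  moves it by roughly ten times the per-step noise. With the calibrated
  noise this gives `inh_max = 20`, `exc_max = 10` current units
  (single-step deflections of at most 10 and 5 mV). Substantially larger
  scales were examined and destabilise the network: beyond roughly 1.4×
  the default, trial-evoked firing no longer dies out between trials
  (tens of Hz of reverberation), and the added activity noise cancels the
  SNR gain. The scale is exposed in the configuration (`exc_max`,
  `inh_max`) for sensitivity analyses.

### Response extraction

With fixed latency, the response of cell $n$ on a trial at step $s$ is the
one-step voltage change at PSP arrival,
$y = v(s + k) - v(s + k - 1)$ with $k = \mathrm{round}(\text{latency}/dt)$
— measuring at the arrival step keeps disynaptic contamination (which
arrives one further delay later) out of the measurement window. With
random latency, responses are summed over a window of
$\lceil(\mu_\ell + 3\sigma_\ell)/dt\rceil$ steps with the decay-predicted voltage
subtracted at each step: $\sum_s v(s+1) - \rho_n v(s)$, where $\rho_n$ is
each cell's mean $v(t{+}1)/v(t)$ ratio over post-stimulation intervals
(spike-adjacent steps and near-zero voltages excluded). The telescoping
structure makes the windowed sum insensitive to where inside the window a
delayed PSP lands.

Trials in which the measured cell was itself stimulated are excluded from
that cell's own linear system by default: the forced suprathreshold spike
and reset dominate the subthreshold measurement. The alternative
(`retain_self_trials = TRUE`) keeps them, at the cost of large reset
artefacts in $y$. With self-trials excluded the self-weight is dropped
from the unknowns and the diagonal of the estimate is fixed at zero.

## The decoder

`solve_lasso()` minimises the penalised squared-residual objective by
cyclic coordinate descent on the Gram system, with optional
per-coordinate bounds implementing the cell-type sign constraints (each
1-D subproblem is solved exactly by a soft-thresholded Newton step
projected onto the box). An active-set sweep strategy and an
objective-progress stopping rule keep it fast and stable even in the
underdetermined regime, where binary designs can make the minimiser
non-unique (coefficients can then drift along a flat valley; the solver
stops when the objective stops decreasing). The duality-gap-free
convergence measure is the largest scaled coordinate change per full
sweep (default tolerance `1e-7`).

`solve_basis_pursuit()` solves the constrained form (minimum L1 norm
subject to a residual bound $\varepsilon$) by descending a warm-started
penalty path and bisecting for the penalty whose residual matches the
bound; the two forms trace the same solution path, which the tests verify
in the noiseless limit against exhaustive support enumeration. The
printed objective in the reference description can be read with a squared
or unsquared residual norm; the squared (standard lasso) reading is the
default and the unsquared variant (`squared = FALSE`) is solved through a
fixed-point iteration on the effective penalty
$\lambda_{\mathrm{eff}} = 2\lambda\lVert r\rVert$.

$\lambda = 0.25$ (the reference default) is applied to the raw extracted
responses in mV with no rescaling of $M$ or $y$, the same value across
all conditions. The connection threshold is relative to the *global*
maximum of the reconstructed matrix by default (`per_neuron = TRUE`
switches to per-cell references). Cell types are classified from an
unconstrained reconstruction by the sign of each presynaptic column sum —
a magnitude-weighted vote; ties default to excitatory, the majority
class.

## What the synthetic generator does and does not emulate

The simulator reproduces the features that matter for the measurement
model: recurrent E/I dynamics with realistic spike mechanics, emergent
(not sampled) background noise, stimulation that actually forces spikes
whose currents propagate with delay and can fail, and partial
observability (unobserved cells spike and inject current but are never
stimulated or decoded). It does not model voltage-indicator kinetics or
photophysics, conductance-based (shunting) inhibition, laser-power
misestimation, or state-dependent changes in synaptic reliability — all
fixed per run. Passing tests therefore certify the inference machinery
under an idealised voltage readout, not performance on indicator
timeseries from real preparations.

## Numerical and design choices

* Forced spiking sets the cell's voltage to the 30 mV cutoff at the trial
  step (the stimulation current needed to reach threshold is assumed
  known), giving the reset dynamics of a genuine spike.
* Deliveries scheduled for step $t$ enter the input current integrated in
  the update that produces $v(t)$; a delay of one step is therefore "the
  following time step", and delays round to a minimum of one step.
* The Watts–Strogatz digraph rewires the *target* endpoint of each ring
  edge with probability beta, resampling to exclude self-loops and
  duplicates, so the total edge count and every out-degree are conserved.
  Whether the original construction rewired sources or targets (or used
  reciprocal edges) is not documented; this choice is recorded here.
* Cell-type counts use round-half-up on the excitatory fraction.
* Calibration reuses one sigma per network configuration across
  replicate experiments; the experiments themselves are independently
  seeded.
* The sweep driver holds all parameters at their base values, walks one
  parameter over its grid, and emits one tibble row per (value, seed);
  undefined metrics (zero denominators) are reported as missing rather
  than 0 or 1.
* Problem sizes in the test suite are scaled versions of the reference
  geometry (300-cell networks with 100 observed cells, and a
  200/60-cell variant for the synaptic-failure comparison), chosen to
  preserve the trials-to-unknowns ratios that drive decoder behaviour.

## Known limitations

* **The base-configuration recall ceiling.** At the reference operating
  point (0.2 Hz calibration, $\lambda = 0.25$, $T = 100$ trials for 200
  observed cells) the model reaches a mean recall of about 0.83, not the
  >0.90 headline of the original study. The limit is structural: with
  self-trials excluded the per-cell system has ~90 equations for 199
  unknowns, and the per-measurement noise floor equals the calibrated
  per-step voltage noise (~1 mV) against excitatory signal coefficients
  uniform on (0, 5] mV. A static linear instance with exactly these
  dimensions reproduces the same 0.83, and reaching 0.90 would need
  roughly threefold lower noise or ~150 trials. Because the noise is
  pinned by the published 0.2 Hz calibration and the weight scale by the
  published noise-to-threshold anchor — and because larger weight scales
  destabilise the recurrent network — we report this ceiling rather than
  tune the generator to the headline number. The unpublished
  supplementary model presumably differs in details (weight distribution,
  noise injection, parameter ranges) that the printed text does not
  constrain.
* **Large partially observed networks can ignite.** At 10% connection
  probability a 2,000-cell network carries twice the per-cell in-degree
  of the 1,000-cell base case, and roughly one simulated experiment in
  five ignites stimulation-evoked reverberation (sustained multi-Hz
  activity) whose extra firing degrades that run's measurements; the
  five-seed mean recall at 10% observability is therefore ~0.76 against
  the >0.80 headline, with non-igniting runs at 0.80–0.82. The onset is
  chaotic in the seed and is a property of keeping the weight scale
  size-independent, which is all the published description supports.
* **Sign constraints trade recall for precision.** Because connections
  are declared by estimate magnitude, an unconstrained decoder is
  credited for true connections recovered with the *wrong sign* (~14% of
  its true positives under 50% synaptic failure). Sign constraints zero
  those estimates: precision roughly doubles while recall drops a few
  points, so the constraint benefit shows in composite performance (F1),
  and that is what the corresponding test asserts.
* Purely spontaneous firing rates are nearly flat in connection density
  at the calibrated noise level (the doubled inhibitory weights offset
  denser excitation); the growth of background activity with connectivity
  appears in stimulation-evoked firing, which is how the test checks it.
* Coordinate-descent solutions in the underdetermined regime are one
  minimiser among possibly many; support sets are stable but individual
  coefficient values on duplicated design columns are not identifiable.
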