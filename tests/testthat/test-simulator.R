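rs <- list(a = 0.02, b = 0.2, c = -65, d = 8)

test_that("the resting state of a regular-spiking cell is a fixed point", {
  # v = -70, u = -14 is the root of 0.04 v^2 + 4.8 v + 140 = 0
  st <- list(v = -70, u = -14)
  for (i in 1:20) {
    st2 <- izhikevich_step(st, rs, input_current = 0)
    expect_lt(abs(st2$v - st$v), 1e-9)
    expect_lt(abs(st2$u - st$u), 1e-9)
    st <- st2
  }
})

test_that("a voltage at the cutoff resets to (c, u + d)", {
  st <- izhikevich_step(list(v = 29, u = -14), rs, input_current = 200)
  expect_true(st$spiked)
  expect_equal(st$v, rs$c)
})

test_that("the compiled neuron path matches an independent Euler loop exactly", {
  I <- rep(10, 2000)  # 1 s of constant drive
  ref <- reference_izhikevich(rs$a, rs$b, rs$c, rs$d, I, 0.5, -70, -14)
  got <- izhikevich_trace(rs, I, dt = 0.5, v0 = -70, u0 = -14)
  expect_gt(length(ref$spikes), 3)
  expect_identical(got$spikes, ref$spikes)
  expect_equal(got$v, ref$v, tolerance = 1e-12)
})

test_that("without noise or stimulation the network stays silent", {
  net <- small_net(n = 50, seed = 21)
  params <- neuron_params(net$labels)
  M <- matrix(0L, 0, 50)
  sched <- schedule_trials(0, warmup = 0)
  rec <- run_mapping_experiment(net, M, sched, noise_sigma = 0,
                                params = params, n_steps = 2000)
  expect_equal(nrow(rec$spikes), 0)
  expect_equal(mean_firing_rate(rec), 0)
})

test_that("a single connection delivers after exactly the latency delay", {
  # two cells, j = 1 -> i = 2 with weight w; stimulate 1; no noise
  set.seed(22)
  labels <- c("excitatory", "excitatory")
  W <- Matrix::sparseMatrix(i = 2, j = 1, x = 4, dims = c(2, 2))
  net <- structure(list(weights = W, labels = labels, observed = 1:2,
                        connect_prob = NA, topology = "manual"),
                   class = "ground_truth_network")
  params <- tibble::tibble(a = c(0.02, 0.02), b = c(0.2, 0.2),
                           c = c(-65, -65), d = c(8, 8))
  M <- matrix(c(1L, 0L), 1, 2)
  sched <- schedule_trials(1, warmup = 10)
  for (lat_ms in c(0.5, 1, 2)) {
    rec <- run_mapping_experiment(net, M, sched, noise_sigma = 0,
                                  params = params, latency_mean = lat_ms)
    s <- as.integer(sched)[1]
    d_steps <- round(lat_ms / 0.5)
    v2 <- rec$voltages[2, ]
    # against a reference trace with no delivery, the perturbation onset is
    # exactly the trial step plus the latency in steps
    ref0 <- reference_izhikevich(0.02, 0.2, -65, 8,
                                 rep(0, length(v2)), 0.5, -65, 0.2 * -65)
    onset <- which(abs(v2 - ref0$v) > 1e-9)[1]
    expect_equal(onset, s + d_steps)
    # and the perturbed trace matches hand-stepped Euler with the delivery
    ref1 <- reference_izhikevich(0.02, 0.2, -65, 8,
                                 replace(rep(0, length(v2)), s + d_steps, 4),
                                 0.5, -65, 0.2 * -65)
    expect_equal(v2, ref1$v, tolerance = 1e-10)
  }
})

test_that("every scheduled cell is forced to spike at the trial step", {
  set.seed(23)
  net <- small_net(n = 60, seed = 23)
  params <- neuron_params(net$labels)
  M <- generate_stimulation_matrix(5, 60, 0.2)
  sched <- schedule_trials(5, warmup = 100)
  rec <- run_mapping_experiment(net, M, sched, noise_sigma = 0.3,
                                params = params)
  for (t in 1:5) {
    stim <- which(M[t, ] == 1L)
    spiked <- rec$spikes$neuron[rec$spikes$step == as.integer(sched)[t]]
    extra <- rec$off_target_log[t]
    expect_true(all(stim %in% spiked))
    expect_true(all(setdiff(spiked, stim) %in% stats::na.omit(extra)))
  }
})

test_that("total synaptic failure suppresses all transmission", {
  set.seed(24)
  net <- small_net(n = 40, seed = 24, p = 0.3)
  params <- neuron_params(net$labels)
  M <- generate_stimulation_matrix(3, 40, 0.3)
  sched <- schedule_trials(3, warmup = 10)
  rec <- run_mapping_experiment(net, M, sched, noise_sigma = 0,
                                params = params, syn_fail_prob = 1)
  expect_equal(rec$n_failed_events, rec$n_transmission_events)
  # never-stimulated cells evolve exactly as isolated neurons: no synaptic
  # current ever reached them
  never_stim <- which(colSums(M) == 0)
  for (i in never_stim[1:5]) {
    p <- rec$params[i, ]
    ref <- reference_izhikevich(p$a, p$b, p$c, p$d,
                                rep(0, rec$n_steps), 0.5, -65, p$b * -65)
    expect_equal(rec$voltages[i, ], ref$v, tolerance = 1e-12)
  }
})

test_that("failure frequency matches its probability", {
  set.seed(25)
  net <- small_net(n = 80, seed = 25, p = 0.2)
  params <- neuron_params(net$labels)
  M <- generate_stimulation_matrix(40, 80, 0.2)
  sched <- schedule_trials(40, warmup = 10)
  rec <- run_mapping_experiment(net, M, sched, noise_sigma = 0,
                                params = params, syn_fail_prob = 0.5)
  n <- rec$n_transmission_events
  expect_gt(n, 1000)
  se <- sqrt(0.25 / n)
  expect_lt(abs(rec$n_failed_events / n - 0.5), 3 * se)
})

test_that("off-target spikes are logged and never in the stimulated set", {
  set.seed(26)
  net <- small_net(n = 60, seed = 26, n_obs = 30)
  params <- neuron_params(net$labels)
  M <- generate_stimulation_matrix(50, 30, 0.2)
  sched <- schedule_trials(50, warmup = 10)
  rec <- run_mapping_experiment(net, M, sched, noise_sigma = 0,
                                params = params, off_target_prob = 0.5)
  hits <- which(!is.na(rec$off_target_log))
  expect_gt(length(hits), 10)
  for (t in hits) {
    stim_cells <- net$observed[M[t, ] == 1L]
    expect_false(rec$off_target_log[t] %in% stim_cells)
  }
})

test_that("identical seeds give identical spike rasters", {
  run_once <- function() {
    set.seed(27)
    net <- small_net(n = 70, seed = 27)
    params <- neuron_params(net$labels)
    M <- generate_stimulation_matrix(5, 70, 0.15)
    sched <- schedule_trials(5)
    run_mapping_experiment(net, M, sched, noise_sigma = 2, params = params)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$voltages, b$voltages)
})

test_that("background activity during mapping grows with connectivity", {
  # denser networks turn the same stimulation into more evoked firing
  set.seed(28)
  rate_at <- function(p) {
    net <- build_network(300, p, n_observed = 100)
    params <- neuron_params(net$labels)
    M <- generate_stimulation_matrix(40, 100, 0.1)
    sched <- schedule_trials(40)
    rec <- run_mapping_experiment(net, M, sched, noise_sigma = 2,
                                  params = params, record_voltages = FALSE)
    mean_firing_rate(rec)
  }
  r <- vapply(c(0.02, 0.2), rate_at, numeric(1))
  expect_gt(r[2], r[1])
})

test_that("noise calibration reaches the target rate and is monotone", {
  set.seed(29)
  net <- build_network(300, 0.1)
  params <- neuron_params(net$labels)
  cal <- calibrate_background_noise(net, target_rate = 0.2, sim_seconds = 20,
                                    params = params)
  expect_lt(abs(cal$achieved_rate - 0.2), 0.1 * 0.2 + 1e-12)
  expect_gt(cal$sigma, 0)

  # the rate is non-decreasing over probe points spanning the bracket
  M <- matrix(0L, 0, 300)
  sched <- schedule_trials(0, warmup = 0)
  rates <- vapply(c(1, 2.5, 6), function(sig) {
    set.seed(30)
    rec <- run_mapping_experiment(net, M, sched, noise_sigma = sig,
                                  params = params, n_steps = 20000,
                                  record_voltages = FALSE)
    mean_firing_rate(rec)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("zero noise with no drive calibrates to zero rate at sigma 0", {
  set.seed(31)
  net <- small_net(n = 40, seed = 31)
  params <- neuron_params(net$labels)
  M <- matrix(0L, 0, 40)
  sched <- schedule_trials(0, warmup = 0)
  rec <- run_mapping_experiment(net, M, sched, noise_sigma = 0,
                                params = params, n_steps = 4000,
                                record_voltages = FALSE)
  expect_equal(mean_firing_rate(rec), 0)
})
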