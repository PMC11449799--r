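# Synthetic-data generators: analytic limits, ground-truth consistency,
# seeded determinism.

test_that("leak-only model relaxes to EL and obeys Ohm's law", {
  p <- neuron_params(C = 5, gL = 0.5, EL = -58, noise_sd = 0)
  proto <- step_protocol(holding_potential = -58, n_steps = 3,
                         first_step_offset = -12, step_increment = 12)
  cc <- simulate_current_clamp(p, proto)
  # holding at EL needs no bias
  expect_equal(cc$meta$holding_current, 0, tolerance = 1e-12)
  # equilibrium: after the step ends, V returns to EL
  sw <- cc$sweeps[[1]]
  expect_equal(tail(sw$y, 1), -58, tolerance = 1e-3)
  # baseline before the step sits exactly at EL
  expect_equal(sw$y[sw$t < sw$meta$onset_s][10], -58, tolerance = 1e-9)
  # Ohm: steady-state deflection at end of step = dI / gL
  for (k in 1:3) {
    sw <- cc$sweeps[[k]]
    v_end <- sw$y[max(which(sw$t <= sw$meta$offset_s))]
    expect_equal(v_end - (-58), sw$meta$step_offset_pA / 0.5, tolerance = 0.01)
  }
})

test_that("invalid model parameters are rejected", {
  expect_error(neuron_params(C = 0), class = "invalid_parameter_error")
  expect_error(neuron_params(gL = -1), class = "invalid_parameter_error")
  expect_error(step_protocol(sampling_interval = 0),
               class = "invalid_parameter_error")
  expect_error(epsc_gen_params(tau_rise = 5, tau_decay = 5),
               class = "invalid_parameter_error")
  expect_error(morph_gen_params(max_depth = 0),
               class = "invalid_parameter_error")
})

test_that("simulated spike trains match the refractory peak-finder oracle", {
  # the oracle counts overshooting (> 0 mV) peaks, so the detector is run
  # with the same height criterion; its default (-10 mV) additionally
  # accepts marginal late-train spikelets the simple oracle ignores
  cfg <- spike_config(min_peak = 0)
  for (seed in 1:5) {
    p <- neuron_presets("dg_excitable", noise_sd = 3)
    cc <- simulate_current_clamp(p, step_protocol(), seed = seed)
    counted <- count_total_evoked_aps(cc, config = cfg)
    oracle <- sum(vapply(cc$sweeps, function(sw) {
      win <- sw$t >= sw$meta$onset_s & sw$t <= sw$meta$offset_s
      oracle_spike_count(sw$t[win], sw$y[win])
    }, integer(1)))
    expect_equal(counted$total, oracle)
  }
})

test_that("voltage clamp: leak-only I(V) is linear with slope gL", {
  p <- neuron_params(C = 30, gL = 0.7, EL = -55, noise_sd = 0)
  vc <- simulate_voltage_clamp(p, steps = seq(-90, 80, by = 10))
  iv <- vapply(vc$sweeps, steady_state_current, numeric(1))
  v <- vapply(vc$sweeps, function(s) s$command_level, numeric(1))
  fit <- lm(iv ~ v)
  expect_lt(abs(unname(coef(fit)[2]) - 0.7), 1e-3)
  expect_lt(max(abs(residuals(fit))), 0.05)
})

test_that("voltage clamp: no inward transient without sodium conductance", {
  p <- neuron_params(C = 30, gL = 0.5, EL = -60, gK = 20, gKA = 5, gNa = 0)
  vc <- simulate_voltage_clamp(p, steps = c(-20, 20))
  for (sw in vc$sweeps) {
    leak_i <- 0.5 * (sw$command_level - (-60))
    step_idx <- sw$t >= sw$meta$onset_s & sw$t <= sw$meta$offset_s
    expect_true(min(sw$y[step_idx]) >= leak_i - 1e-9)
  }
})

test_that("voltage clamp matches the closed-form gating oracle", {
  p <- neuron_presets("dg_excitable")
  vc <- simulate_voltage_clamp(p, steps = -20)
  sw <- vc$sweeps[[1]]
  step_idx <- which(sw$t >= sw$meta$onset_s & sw$t <= sw$meta$offset_s)
  t_ms <- (sw$t[step_idx] - sw$meta$onset_s) * 1e3
  i_oracle <- oracle_vc_current(p, -20, t_ms)
  # peak inward current agrees with direct evaluation of the gating equations
  expect_equal(min(sw$y[step_idx]), min(i_oracle), tolerance = 1e-6)
  expect_equal(sw$y[step_idx[100]], i_oracle[100], tolerance = 1e-8)
})

test_that("EPSC generator: zero rate gives pure noise, kernels are unit-peak", {
  g0 <- generate_epsc_trace(epsc_gen_params(rate = 0, noise_sd = 2,
                                            duration = 2), seed = 1)
  expect_equal(nrow(g0$truth), 0L)
  expect_lt(abs(mean(g0$sweep$y)), 0.2)
  # noiseless isolated events: trace minimum equals -amplitude
  gp <- epsc_gen_params(rate = 0.2, amp_mean = 20, amp_sd = 0, noise_sd = 0,
                        duration = 20)
  g <- generate_epsc_trace(gp, seed = 4)
  expect_gte(nrow(g$truth), 1L)   # deterministic for this seed
  expect_equal(min(g$sweep$y), -20, tolerance = 0.01)
})

test_that("EPSC generator: realized event count within the Poisson 3-sigma band", {
  g <- generate_epsc_trace(epsc_gen_params(rate = 5, duration = 100,
                                           noise_sd = 0, sampling_interval = 0.2),
                           seed = 11)
  expect_lt(abs(nrow(g$truth) - 500), 3 * sqrt(500))
})

test_that("MEA generator: empty, exponential-ISI and ground-truth-duration limits", {
  g0 <- generate_mea_trains(mea_gen_params(background_rate = 0, burst_rate = 0,
                                           n_electrodes = 3, duration = 60),
                            seed = 1)
  expect_true(all(vapply(g0$trains$trains, length, integer(1)) == 0L))
  expect_equal(nrow(g0$truth), 0L)

  # pure background: ISIs pass an exponentiality KS test in >= 95% of runs
  pass <- vapply(1:40, function(s) {
    g <- generate_mea_trains(mea_gen_params(background_rate = 2, burst_rate = 0,
                                            n_electrodes = 1, duration = 300),
                             seed = s)
    isi <- diff(g$trains$trains[[1]])
    suppressWarnings(ks.test(isi, "pexp", rate = 1 / mean(isi))$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)

  # inserted bursts have the nominal duration
  g <- generate_mea_trains(mea_gen_params(background_rate = 0.1, burst_rate = 2,
                                          burst_len = 10, intra_burst_isi = 10,
                                          n_electrodes = 2, duration = 300),
                           seed = 3)
  expect_true(all(abs((g$truth$end - g$truth$start) - 0.09) < 1e-9))
})

test_that("morphology generator: deterministic topology limits and SWC round trip", {
  # unbranched path: 1 stem, no branching, max_depth 2 -> 3 segments
  m <- generate_morphology(morph_gen_params(n_stems = 1, branch_prob = 0,
                                            max_depth = 2), seed = 1)
  expect_equal(nrow(m), 4L)        # soma + 3 nodes
  bm <- branch_metrics(m)
  expect_equal(bm$n_branches, 1L)

  # full branching: complete binary tree, tips = n_stems * 2^max_depth
  m2 <- generate_morphology(morph_gen_params(n_stems = 2, branch_prob = 1,
                                             max_depth = 3), seed = 2)
  idx <- match(m2$parent, m2$id)
  n_children <- tabulate(idx[!is.na(idx)], nbins = nrow(m2))
  tips <- sum(n_children == 0 & m2$type != 1L)
  expect_equal(tips, 2L * 2^3)

  # write/read round trip is the identity on the node table
  f <- tempfile(fileext = ".swc")
  m3 <- generate_morphology(morph_gen_params(), seed = 3)
  write_swc(m3, f)
  m3r <- read_swc(f)
  expect_equal(as.data.frame(m3r), as.data.frame(m3), tolerance = 1e-7)
})

test_that("DEG generator: exact significant-row count and determinism", {
  d0 <- generate_deg_table(n_genes = 500, n_dys = 0, seed = 1)
  expect_equal(sum(d0$padj < 0.05), 0L)
  d <- generate_deg_table(n_genes = 2000, n_dys = 305, seed = 2)
  expect_equal(sum(d$padj < 0.05), 305L)
  d2 <- generate_deg_table(n_genes = 2000, n_dys = 305, seed = 2)
  expect_identical(d, d2)
})

test_that("every generator is a pure function of parameters + seed", {
  p <- neuron_presets("dg_excitable", noise_sd = 5)
  a <- simulate_current_clamp(p, step_protocol(n_steps = 2), seed = 7)
  b <- simulate_current_clamp(p, step_protocol(n_steps = 2), seed = 7)
  expect_identical(a, b)
  ea <- generate_epsc_trace(epsc_gen_params(duration = 2), seed = 7)
  eb <- generate_epsc_trace(epsc_gen_params(duration = 2), seed = 7)
  expect_identical(ea, eb)
  ma <- generate_mea_trains(mea_gen_params(duration = 30), seed = 7)
  mb <- generate_mea_trains(mea_gen_params(duration = 30), seed = 7)
  expect_identical(ma, mb)
  ga <- generate_morphology(morph_gen_params(), seed = 7)
  gb <- generate_morphology(morph_gen_params(), seed = 7)
  expect_identical(ga, gb)
  # and the caller's RNG stream is untouched
  set.seed(99)
  before <- .Random.seed
  invisible(generate_morphology(morph_gen_params(), seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("Poisson generators: empirical rate approaches nominal at 3 sigma", {
  g <- generate_mea_trains(mea_gen_params(background_rate = 3, burst_rate = 0,
                                          n_electrodes = 4, duration = 600),
                           seed = 5)
  n <- sum(vapply(g$trains$trains, length, integer(1)))
  expected <- 3 * 4 * 600
  expect_lt(abs(n - expected), 3 * sqrt(expected))
})
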