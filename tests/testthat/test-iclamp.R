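# Current-clamp feature extraction: detector behaviour, spike-shape closed
# forms, passive-property estimators.

make_flat_sweep <- function(v = -60, dur_s = 0.5, dt = 5e-5) {
  t <- seq(0, dur_s, by = dt)
  new_sweep(t, rep(v, length(t)), "current_clamp", command_level = 0)
}

# synthetic AP: Gaussian bump on a flat baseline
make_gauss_spike <- function(base = -60, amp = 70, sigma_ms = 0.5,
                             center_s = 0.05, dur_s = 0.1, dt = 5e-5) {
  t <- seq(0, dur_s, by = dt)
  v <- base + amp * exp(-(t - center_s)^2 / (2 * (sigma_ms * 1e-3)^2))
  new_sweep(t, v, "current_clamp", command_level = 10)
}

test_that("detect_spikes: trivial inputs and mode guard", {
  expect_identical(detect_spikes(make_flat_sweep()), integer(0))
  sw <- make_gauss_spike()
  idx <- detect_spikes(sw)
  expect_length(idx, 1L)
  expect_equal(idx, which.max(sw$y))
  vc <- new_sweep(sw$t, sw$y, "voltage_clamp")
  expect_error(detect_spikes(vc), class = "mode_error")
})

test_that("count_total_evoked_aps: subthreshold sets, exclusion, protocol mismatch", {
  p <- neuron_params(C = 30, gL = 0.5, EL = -60)   # passive: never spikes
  cc <- simulate_current_clamp(p, step_protocol())
  res <- count_total_evoked_aps(cc)
  expect_equal(res$total, 0L)
  expect_false(res$excluded)

  cc$meta$holding_current <- 60
  res <- count_total_evoked_aps(cc)
  expect_true(res$excluded)
  expect_equal(res$reason, "holding>50pA")
  expect_true(is.na(res$total))

  cc2 <- simulate_current_clamp(p, step_protocol(n_steps = 5))
  expect_error(count_total_evoked_aps(cc2, protocol = step_protocol()),
               class = "protocol_mismatch_error")
})

test_that("first_evoked_ap selects the minimal-current spiking sweep", {
  # hand-built set: spikes only in sweeps 5 and 9 (by command level)
  base <- make_flat_sweep(dur_s = 0.2)
  sweeps <- lapply(1:10, function(k) {
    sw <- if (k %in% c(5, 9)) make_gauss_spike(center_s = 0.1, dur_s = 0.2)
    else make_flat_sweep(dur_s = 0.2)
    sw$command_level <- k
    sw
  })
  ss <- new_sweep_set(sweeps)
  w <- first_evoked_ap(ss)
  expect_equal(w$meta$sweep_index, 5L)

  # synthetic set with known rheobase: generator preset, count per sweep
  cc <- simulate_current_clamp(neuron_presets("dg_excitable"), step_protocol(),
                               seed = 1)
  per <- count_total_evoked_aps(cc)$per_sweep
  rheo <- which(per > 0)[1]
  w2 <- first_evoked_ap(cc)
  expect_equal(w2$meta$sweep_index, rheo)

  # all-flat set errors
  flat <- new_sweep_set(lapply(1:3, function(k) make_flat_sweep()))
  expect_error(first_evoked_ap(flat), class = "no_spike_error")
})

# independently coded threshold estimator used as the dense-grid oracle:
# same definition (boxcar smoothing, first qualifying maximum of the second
# difference, parabolic refinement) evaluated on a 10x finer grid
thr_oracle <- function(w, dt_ms, smooth_ms = 0.25) {
  y0 <- w$y
  k <- max(1, round(smooth_ms / dt_ms))
  if (k %% 2 == 0) k <- k + 1
  y <- if (k > 1) {
    z <- stats::filter(y0, rep(1 / k, k), sides = 2)
    z[is.na(z)] <- y0[is.na(z)]
    as.numeric(z)
  } else y0
  d2 <- c(NA, diff(diff(y)), NA) / dt_ms^2
  pk <- which.max(y)
  win <- max(k + 2, pk - round(10 / dt_ms)):pk
  d2w <- d2[win]
  cand <- which(d2w > c(-Inf, head(d2w, -1)) & d2w >= c(tail(d2w, -1), -Inf) &
                  d2w >= 0.2 * max(d2w, na.rm = TRUE))
  i <- win[cand[1]]
  a <- d2[i - 1]; b <- d2[i]; cc <- d2[i + 1]
  delta <- if ((a - 2 * b + cc) != 0) 0.5 * (a - cc) / (a - 2 * b + cc) else 0
  approx(seq_along(y0), y0, xout = i + max(min(delta, 0.5), -0.5))$y
}

test_that("spike_threshold finds the onset of curvature", {
  # piecewise waveform: flat, then quadratic onset at k_on (slope-continuous
  # into a linear rise), then a capped peak: the unique first maximum of
  # d2V/dt2 sits at the quadratic onset
  dt <- 5e-5
  t <- seq(0, 0.05, by = dt)
  v <- rep(-60, length(t))
  k_on <- which(t >= 0.03)[1]
  quad <- t >= t[k_on] & t < t[k_on] + 2e-3
  v[quad] <- -60 + 4e6 * (t[quad] - t[k_on])^2          # quadratic onset
  lin <- t >= t[k_on] + 2e-3
  # value- and slope-matched linear continuation (slope 2 * 4e6 * 2e-3 mV/s)
  v[lin] <- (-60 + 4e6 * (2e-3)^2) + 1.6e4 * (t[lin] - t[k_on] - 2e-3)
  v <- pmin(v, 20)
  w <- new_sweep(t, v, "current_clamp")
  thr <- spike_threshold(w)
  expect_lt(abs(thr - (-60)), 1.5)    # V at curvature onset, within ~1 sample

  # pure linear ramp: second derivative identically zero
  ramp <- new_sweep(t, -60 + 1000 * t, "current_clamp")
  expect_error(spike_threshold(ramp), class = "undefined_threshold_error")

  # simulated AP: matches the dense-grid oracle within 1 mV
  cc <- simulate_current_clamp(neuron_presets("dg_excitable"), step_protocol(),
                               seed = 2)
  ccd <- simulate_current_clamp(neuron_presets("dg_excitable"),
                                step_protocol(sampling_interval = 0.005),
                                seed = 2)
  thr2 <- spike_threshold(first_evoked_ap(cc))
  dense <- thr_oracle(first_evoked_ap(ccd), 0.005)
  expect_lt(abs(thr2 - dense), 1)
})

test_that("spike_shape closed forms: Gaussian FWHM, triangular width, fAHP", {
  # Gaussian spike about the threshold baseline: FWHM = 2 sigma sqrt(2 ln 2)
  dt <- 1e-5
  t <- seq(0, 0.04, by = dt)
  sigma <- 0.5e-3
  thr <- -40
  v <- thr + 50 * exp(-(t - 0.02)^2 / (2 * sigma^2))
  v[t > 0.03] <- thr - 10                     # drop below threshold for fAHP
  w <- new_sweep(t, v, "current_clamp")
  sh <- spike_shape(w, threshold = thr)
  expect_equal(sh$width, 2 * sigma * sqrt(2 * log(2)) * 1e3, tolerance = 0.01)
  expect_equal(sh$amplitude, 50, tolerance = 1e-6)

  # triangular spike rising 1 ms, falling 2 ms: FWHM = 1.5 ms
  tt <- seq(0, 0.02, by = dt)
  peak_t <- 0.01
  vt <- ifelse(tt < peak_t, -60 + 40e3 * pmax(tt - (peak_t - 1e-3), 0),
               pmax(-70, -20 - 20e3 * (tt - peak_t)))
  wt <- new_sweep(tt, vt, "current_clamp")
  sht <- spike_shape(wt, threshold = -60)
  expect_equal(sht$width, 1.5, tolerance = 0.01)

  # constructed fAHP: V = threshold - 10 exactly 5 ms after the re-crossing
  t3 <- seq(0, 0.03, by = dt)
  thr3 <- -40
  v3 <- rep(thr3 - 10, length(t3))
  rise <- t3 >= 0.005 & t3 < 0.010
  v3[rise] <- thr3 - 10 + (t3[rise] - 0.005) / 0.005 * 60
  fall <- t3 >= 0.010 & t3 < 0.012
  v3[fall] <- (thr3 + 50) - (t3[fall] - 0.010) / 0.002 * 60
  w3 <- new_sweep(t3, v3, "current_clamp")
  sh3 <- spike_shape(w3, threshold = thr3)
  expect_equal(sh3$fahp, 10, tolerance = 0.05)

  # truncated window: no 5 ms left after the re-crossing
  short <- sweep_window(w3, 0, 0.013)
  expect_error(spike_shape(short, threshold = thr3),
               class = "truncated_window_error")
})

test_that("spike_shape is invariant to a constant voltage offset", {
  cc <- simulate_current_clamp(neuron_presets("dg_excitable"), step_protocol(),
                               seed = 3)
  w <- first_evoked_ap(cc)
  thr <- spike_threshold(w)
  sh <- spike_shape(w, thr)
  w2 <- w
  w2$y <- w$y + 13.7
  sh2 <- spike_shape(w2, thr + 13.7)
  expect_equal(sh2$amplitude, sh$amplitude, tolerance = 1e-10)
  expect_equal(sh2$width, sh$width, tolerance = 1e-10)
  expect_equal(sh2$fahp, sh$fahp, tolerance = 1e-10)
})

test_that("input_conductance: arithmetic, reciprocity and the leak-only limit", {
  g <- input_conductance(-10, 10)
  expect_equal(g$input_resistance, 1)
  expect_equal(g$input_conductance, 1)
  g2 <- input_conductance(0, 4.8)
  expect_equal(g2$input_conductance, 0.24)
  expect_equal(g2$input_conductance * g2$input_resistance, 1)
  expect_error(input_conductance(5, 5), class = "nonphysical_conductance_error")
  expect_error(input_conductance(10, 5), class = "nonphysical_conductance_error")

  # leak-only simulation recovers gL to < 0.1 %
  p <- neuron_params(C = 30, gL = 0.56, EL = -55, noise_sd = 0)
  vc <- simulate_voltage_clamp(p, steps = c(-70, -50), step_duration = 400,
                               baseline = 50, tail = 0)
  gin <- input_conductance(steady_state_current(vc$sweeps[[1]]),
                           steady_state_current(vc$sweeps[[2]]))$input_conductance
  expect_lt(abs(gin - 0.56) / 0.56, 0.001)
})

test_that("resting_potential: constant trace, noisy recovery, baseline guard", {
  sw <- make_flat_sweep(v = -52.8)
  sw$meta$zero_epoch_s <- c(0, 0.5)
  expect_equal(resting_potential(sw), -52.8)

  p <- neuron_params(C = 30, gL = 0.3, EL = -46.3, noise_sd = 5)
  est <- vapply(1:5, function(s) {
    resting_potential(simulate_resting(p, duration = 500, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(est) - (-46.3)), 0.5)

  injected <- make_flat_sweep(v = -30)
  injected$command_level <- 20
  expect_error(resting_potential(injected), class = "no_baseline_error")
})

test_that("capacitance: analytic RC transient, zero-transient trace, presets", {
  # ideal RC response built in closed form: C = 30 pF, R = 1 GOhm, dV = 5 mV
  dt <- 5e-5
  t <- seq(0, 0.2, by = dt)
  onset <- 0.05
  rs <- 0.01                      # GOhm
  C <- 30                         # pF
  rm <- 1                         # GOhm
  tau <- C * rs * rm / (rs + rm)  # pF * GOhm = ms
  dv <- 5
  i_ss <- dv / (rs + rm)
  i <- ifelse(t < onset, 0,
              i_ss + (dv / rs - i_ss) * exp(-(t - onset) * 1e3 / tau))
  sw <- new_sweep(t, i, "voltage_clamp", command_level = -55,
                  meta = list(onset_s = onset, offset_s = max(t)))
  expect_equal(capacitance(sw, dv), 30 * rm / (rm + rs), tolerance = 0.02)

  # zero transient -> 0 pF
  flat <- new_sweep(t, rep(2, length(t)), "voltage_clamp",
                    meta = list(onset_s = onset, offset_s = max(t)))
  expect_equal(capacitance(flat, 5), 0)

  # model neurons: recovered within 2 %
  for (Ctrue in c(30, 60)) {
    p <- neuron_params(C = Ctrue, gL = 0.3, EL = -55, noise_sd = 0)
    cs <- simulate_voltage_clamp(p, steps = -65, step_duration = 100,
                                 baseline = 20, tail = 0, rs = 0.01)
    expect_equal(capacitance(cs$sweeps[[1]], -5), Ctrue, tolerance = 0.02)
  }
})

test_that("passive panel: Gin * Rm = 1 and leak-only recovery under noise", {
  p <- neuron_params(C = 40, gL = 0.46, EL = -46.3, noise_sd = 5)
  gins <- vrests <- caps <- numeric(10)
  for (s in 1:10) {
    vc <- simulate_voltage_clamp(p, steps = c(-70, -50), step_duration = 200,
                                 baseline = 50, tail = 0, seed = s)
    rest <- simulate_resting(p, duration = 500, seed = s + 100)
    cap <- simulate_voltage_clamp(p, steps = -65, step_duration = 100,
                                  baseline = 20, tail = 0, rs = 0.01,
                                  seed = s + 200)
    pp <- passive_properties(steady_state_current(vc$sweeps[[1]]),
                             steady_state_current(vc$sweeps[[2]]),
                             rest_sweep = rest, cap_sweep = cap$sweeps[[1]],
                             cap_dv = -5, holding_current = 0)
    expect_equal(pp$input_conductance * pp$input_resistance, 1)
    gins[s] <- pp$input_conductance
    vrests[s] <- pp$resting_potential
    caps[s] <- pp$capacitance
  }
  expect_lt(abs(mean(gins) - 0.46) / 0.46, 0.05)
  expect_lt(abs(mean(vrests) - (-46.3)), 1)
  expect_lt(abs(mean(caps) - 40) / 40, 0.05)
})

test_that("evoked AP count is monotone non-decreasing in gNa", {
  counts <- vapply(c(80, 110, 140, 200), function(gna) {
    p <- neuron_presets("dg_excitable", gNa = gna, gK = gna / 5)
    count_total_evoked_aps(simulate_current_clamp(p, step_protocol(),
                                                  seed = 1))$total
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})
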