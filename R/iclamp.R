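# Current-clamp phenotyping: evoked spike counts, spike-shape features
# (threshold, amplitude, FWHM width, fast AHP) and passive membrane
# properties (input conductance/resistance, resting potential, capacitance).

#' Spike-detection configuration
#'
#' The source protocols never published a detector, so the criteria are
#' explicit and configurable: local voltage maxima above `min_peak` mV with
#' prominence at least `min_prominence` mV, separated by a refractory period
#' of `refractory_ms`. The defaults are chosen to be robust for the
#' small-amplitude spikes of immature neurons.
#'
#' @param min_peak Minimum peak voltage, mV.
#' @param min_prominence Minimum peak prominence, mV.
#' @param refractory_ms Minimum separation between spikes, ms.
#' @param min_upstroke Minimum rate of rise (mV/ms) in the millisecond
#'   before the peak; rejects slow passive depolarization humps that can
#'   satisfy the height and prominence criteria on large current steps.
#' @return A list of class `spike_config`.
#' @export
spike_config <- function(min_peak = -10, min_prominence = 20,
                         refractory_ms = 2, min_upstroke = 10) {
  structure(list(min_peak = min_peak, min_prominence = min_prominence,
                 refractory_ms = refractory_ms, min_upstroke = min_upstroke),
            class = "spike_config")
}

#' Detect action-potential peaks in a current-clamp sweep
#'
#' @param sweep A current-clamp [new_sweep()] (mV).
#' @param config A [spike_config()].
#' @param window Optional `c(from, to)` in seconds restricting detection to
#'   an epoch (e.g. the step window).
#' @return Integer indices of spike peaks into `sweep$t`.
#' @export
detect_spikes <- function(sweep, config = spike_config(), window = NULL) {
  assert_that(inherits(sweep, "sweep"), "input must be a sweep")
  if (sweep$mode != "current_clamp") {
    stop_twinephys("detect_spikes requires a current-clamp sweep", "mode_error")
  }
  dt_s <- sampling_interval_s(sweep$t)
  idx <- find_peaks(sweep$y, height = config$min_peak,
                    prominence = config$min_prominence,
                    min_distance = max(1L, round(config$refractory_ms * 1e-3 / dt_s)))
  if (length(idx) && config$min_upstroke > 0) {
    k1 <- max(1L, round(1e-3 / dt_s))
    dv <- c(0, diff(sweep$y)) / (dt_s * 1e3)       # mV/ms
    idx <- idx[vapply(idx, function(i) {
      max(dv[max(1L, i - k1):i]) >= config$min_upstroke
    }, logical(1))]
  }
  if (!is.null(window)) {
    idx <- idx[sweep$t[idx] >= window[1] & sweep$t[idx] <= window[2]]
  }
  idx
}

#' Total evoked action potentials over a step protocol
#'
#' Sums spikes over all depolarization steps (counted inside each sweep's
#' step epoch when annotated). Neurons whose holding current exceeds 50 pA
#' in magnitude are flagged excluded rather than counted.
#'
#' @param sweeps A [new_sweep_set()] from the 20-step protocol.
#' @param protocol The [step_protocol()] the set is expected to match.
#' @param config A [spike_config()].
#' @param max_holding_pA Exclusion bound on `|holding current|` (default 50).
#' @return A list with `total` (integer or `NA` when excluded), `excluded`
#'   (logical), `reason`, and `per_sweep` counts.
#' @export
count_total_evoked_aps <- function(sweeps, protocol = sweeps$protocol,
                                   config = spike_config(),
                                   max_holding_pA = 50) {
  assert_that(inherits(sweeps, "sweep_set"), "input must be a sweep_set")
  if (!is.null(protocol) && length(sweeps) != protocol$n_steps) {
    stop_twinephys(sprintf("sweep set has %d sweeps but protocol expects %d",
                           length(sweeps), protocol$n_steps),
                   "protocol_mismatch_error")
  }
  ihold <- sweeps$meta$holding_current
  if (!is.null(ihold) && is.finite(ihold) && abs(ihold) > max_holding_pA) {
    return(list(total = NA_integer_, excluded = TRUE,
                reason = sprintf("holding>%gpA", max_holding_pA),
                per_sweep = rep(NA_integer_, length(sweeps))))
  }
  per_sweep <- vapply(sweeps$sweeps, function(sw) {
    win <- if (!is.null(sw$meta$onset_s)) c(sw$meta$onset_s, sw$meta$offset_s)
    length(detect_spikes(sw, config, window = win))
  }, integer(1))
  list(total = sum(per_sweep), excluded = FALSE, reason = NA_character_,
       per_sweep = per_sweep)
}

#' Waveform of the first evoked action potential
#'
#' Selects the sweep with the minimal injected current containing at least
#' one spike (lowest sweep index on ties) and returns a window around its
#' first spike, for spike-shape analysis.
#'
#' @param sweeps A [new_sweep_set()].
#' @param config A [spike_config()].
#' @param pre_ms,post_ms Window extent around the peak, ms.
#' @return A `sweep` window whose `meta` records `peak_time_s`, the source
#'   `sweep_index` and its `command_level`.
#' @export
first_evoked_ap <- function(sweeps, config = spike_config(),
                            pre_ms = 10, post_ms = 30) {
  assert_that(inherits(sweeps, "sweep_set"), "input must be a sweep_set")
  lev <- vapply(sweeps$sweeps, function(s) as.numeric(s$command_level), numeric(1))
  has <- logical(length(sweeps$sweeps))
  first_peak <- rep(NA_real_, length(sweeps$sweeps))
  for (i in seq_along(sweeps$sweeps)) {
    sw <- sweeps$sweeps[[i]]
    win <- if (!is.null(sw$meta$onset_s)) c(sw$meta$onset_s, sw$meta$offset_s)
    idx <- detect_spikes(sw, config, window = win)
    has[i] <- length(idx) > 0
    if (has[i]) first_peak[i] <- sw$t[idx[1]]
  }
  if (!any(has)) stop_twinephys("no spikes in any sweep", "no_spike_error")
  cand <- which(has)
  sel <- cand[order(lev[cand], cand)][1]
  sw <- sweeps$sweeps[[sel]]
  pk <- first_peak[sel]
  w <- sweep_window(sw, max(min(sw$t), pk - pre_ms * 1e-3),
                    min(max(sw$t), pk + post_ms * 1e-3))
  w$meta$peak_time_s <- pk
  w$meta$sweep_index <- sel
  w$meta$command_level <- sw$command_level
  w
}

#' Spike threshold from the second derivative of the voltage
#'
#' The threshold is the membrane potential at the first maximum of
#' d2V/dt2 preceding the spike peak. Numerically: the voltage is smoothed
#' with a `smooth_ms` boxcar, differentiated twice by central differences,
#' and the first local maximum of d2V/dt2 within `[peak - search_ms, peak]`
#' that exceeds `rel_floor` of the window's global maximum is taken. This
#' guards against noise maxima that manual analysis implicitly skips.
#'
#' @param wave A `sweep` window containing one rising phase ending in a peak
#'   (see [first_evoked_ap()]).
#' @param smooth_ms Boxcar width, ms; forced to an odd number of samples so
#'   the smoothed trace is not phase-shifted.
#' @param search_ms Search window before the peak, ms.
#' @param rel_floor Fraction of the window's maximal d2V/dt2 a candidate must
#'   exceed.
#' @param abs_floor Absolute minimum d2V/dt2 (mV/ms^2) below which the
#'   threshold is declared undefined (flat or linear waveforms).
#' @return Threshold voltage, mV. The d2V/dt2 argmax is refined to
#'   sub-sample precision by a local parabolic fit before the voltage is
#'   read off by interpolation, so the estimate is stable across sampling
#'   rates (the upstroke can traverse > 1 mV per sample at 20 kHz).
#' @export
spike_threshold <- function(wave, smooth_ms = 0.25, search_ms = 10,
                            rel_floor = 0.2, abs_floor = 1e-3) {
  assert_that(inherits(wave, "sweep"), "input must be a sweep")
  dt_ms <- sampling_interval_s(wave$t) * 1e3
  y <- wave$y
  k <- max(1L, round(smooth_ms / dt_ms))
  if (k %% 2L == 0L) k <- k + 1L
  if (k > 1L) {
    ys <- stats::filter(y, rep(1 / k, k), sides = 2)
    ys[is.na(ys)] <- y[is.na(ys)]
    y_s <- as.numeric(ys)
  } else y_s <- y
  n <- length(y_s)
  d2 <- c(NA, diff(diff(y_s)), NA) / dt_ms^2
  peak <- which.max(y_s)
  # keep clear of the boxcar's partially-smoothed edges, where spurious
  # curvature appears on otherwise featureless (e.g. linear-ramp) traces
  lo <- max(k + 2L, peak - round(search_ms / dt_ms))
  hi <- min(max(lo + 1L, peak), n - k - 1L)
  if (hi <= lo) {
    stop_twinephys("no defined threshold: window too close to the trace edge",
                   "undefined_threshold_error")
  }
  win <- lo:hi
  d2w <- d2[win]
  d2w[is.na(d2w)] <- -Inf
  gmax <- max(d2w)
  if (!is.finite(gmax) || gmax < abs_floor) {
    stop_twinephys("no defined threshold: d2V/dt2 has no usable maximum",
                   "undefined_threshold_error")
  }
  m <- length(d2w)
  is_max <- which(d2w[2:(m - 1L)] > d2w[1:(m - 2L)] &
                    d2w[2:(m - 1L)] >= d2w[3:m]) + 1L
  is_max <- is_max[d2w[is_max] >= rel_floor * gmax & d2w[is_max] >= abs_floor]
  if (!length(is_max)) {
    stop_twinephys("no defined threshold: no local maximum of d2V/dt2",
                   "undefined_threshold_error")
  }
  i <- win[is_max[1]]
  # parabolic sub-sample refinement of the d2 maximum
  a <- d2[i - 1L]
  b <- d2[i]
  cc <- d2[i + 1L]
  delta <- 0
  if (is.finite(a) && is.finite(cc) && (a - 2 * b + cc) != 0) {
    delta <- max(min(0.5 * (a - cc) / (a - 2 * b + cc), 0.5), -0.5)
  }
  stats::approx(seq_along(y), y, xout = i + delta)$y
}

#' Spike-shape features of a single action-potential waveform
#'
#' Amplitude is peak voltage minus threshold; width is the full width at
#' half-maximum (time between the two crossings of threshold + amplitude/2,
#' linearly interpolated); the fast AHP is threshold minus the membrane
#' potential 5 ms after the downward threshold re-crossing.
#'
#' @param wave A `sweep` window extending at least `fahp_delay_ms` past the
#'   downward threshold re-crossing.
#' @param threshold Spike threshold, mV (see [spike_threshold()]).
#' @param fahp_delay_ms Delay after the threshold re-crossing at which the
#'   AHP is read, ms (default 5).
#' @return A one-row data.frame of class `spike_features` with columns
#'   `threshold`, `amplitude`, `width`, `fahp`, `peak_v`, `spike_time`.
#' @export
spike_shape <- function(wave, threshold, fahp_delay_ms = 5) {
  assert_that(inherits(wave, "sweep"), "input must be a sweep")
  t <- wave$t
  y <- wave$y
  peak <- which.max(y)
  peak_v <- y[peak]
  amplitude <- peak_v - threshold
  assert_that(amplitude >= 0, "peak must not be below threshold")
  half <- threshold + amplitude / 2
  # rising crossing: last upward crossing of the half level before the peak
  pre <- seq_len(peak - 1L)
  up <- pre[y[pre] < half & y[pre + 1L] >= half]
  assert_that(length(up) >= 1L, "no rising half-amplitude crossing in window")
  t_up <- crossing_time(t, y, up[length(up)], half)
  post <- peak:(length(y) - 1L)
  dn <- post[y[post] >= half & y[post + 1L] < half]
  assert_that(length(dn) >= 1L, "no falling half-amplitude crossing in window")
  t_dn <- crossing_time(t, y, dn[1L], half)
  width_ms <- (t_dn - t_up) * 1e3
  # downward threshold re-crossing after the peak
  re <- post[y[post] >= threshold & y[post + 1L] < threshold]
  if (!length(re)) {
    stop_twinephys("window ends before the spike re-crosses threshold",
                   "truncated_window_error")
  }
  t_re <- crossing_time(t, y, re[1L], threshold)
  t_fahp <- t_re + fahp_delay_ms * 1e-3
  if (t_fahp > max(t)) {
    stop_twinephys("window too short for the fast-AHP lookup",
                   "truncated_window_error")
  }
  v_fahp <- stats::approx(t, y, xout = t_fahp)$y
  structure(data.frame(threshold = threshold, amplitude = amplitude,
                       width = width_ms, fahp = threshold - v_fahp,
                       peak_v = peak_v, spike_time = t[peak]),
            class = c("spike_features", "data.frame"))
}

#' Input resistance and conductance from the two-point current measurement
#'
#' The membrane resistance around rest is 20 mV divided by the difference
#' between the holding currents measured at -50 and -70 mV; the input
#' conductance is its reciprocal.
#'
#' @param i_at_minus70,i_at_minus50 Steady-state currents (pA) with the cell
#'   clamped at -70 and -50 mV.
#' @return A list with `input_resistance` (GOhm) and `input_conductance`
#'   (nS); `input_conductance * input_resistance == 1` exactly.
#' @export
input_conductance <- function(i_at_minus70, i_at_minus50) {
  di <- i_at_minus50 - i_at_minus70
  if (!is.finite(di) || di <= 0) {
    stop_twinephys("non-physical conductance: current at -50 mV must exceed current at -70 mV",
                   "nonphysical_conductance_error")
  }
  gin <- di / 20                       # pA / mV = nS
  list(input_resistance = 1 / gin, input_conductance = gin)
}

#' Steady-state current of a voltage-clamp sweep
#'
#' Mean current over the last `window_ms` of the step epoch (or of the whole
#' sweep when no epoch is annotated).
#'
#' @param sweep A voltage-clamp [new_sweep()].
#' @param window_ms Averaging window, ms.
#' @return Mean current, pA.
#' @export
steady_state_current <- function(sweep, window_ms = 50) {
  assert_that(inherits(sweep, "sweep"), "input must be a sweep")
  t_end <- sweep$meta$offset_s %||% max(sweep$t)
  idx <- sweep$t > (t_end - window_ms * 1e-3) & sweep$t <= t_end
  mean(sweep$y[idx])
}

#' Resting membrane potential
#'
#' Median voltage over an injection-free epoch; the median is robust to
#' spontaneous synaptic events. The sweep must carry a `meta$zero_epoch_s`
#' annotation or have `command_level == 0`.
#'
#' @param sweep A current-clamp [new_sweep()].
#' @param epoch Optional `c(from, to)` seconds overriding the annotation.
#' @return Resting potential, mV.
#' @export
resting_potential <- function(sweep, epoch = NULL) {
  assert_that(inherits(sweep, "sweep"), "input must be a sweep")
  if (sweep$mode != "current_clamp") {
    stop_twinephys("resting potential requires a current-clamp sweep", "mode_error")
  }
  epoch <- epoch %||% sweep$meta$zero_epoch_s
  if (is.null(epoch)) {
    if (is.finite(sweep$command_level) && sweep$command_level == 0) {
      epoch <- range(sweep$t)
    } else {
      stop_twinephys("sweep has current injected throughout; no zero-injection baseline",
                     "no_baseline_error")
    }
  }
  idx <- sweep$t >= epoch[1] & sweep$t <= epoch[2]
  assert_that(any(idx), "empty baseline epoch")
  stats::median(sweep$y[idx])
}

#' Membrane capacitance by charge integration
#'
#' Integrates the capacitive transient of a small voltage-clamp test step
#' above the post-step steady current: `C = Q / dV`, with Q in pA*ms and dV
#' in mV giving pF. Charge integration is amplifier-convention-free.
#'
#' @param sweep A voltage-clamp [new_sweep()] of a test step, with
#'   `meta$onset_s` annotated.
#' @param dv Test-step size, mV (sign irrelevant).
#' @param integrate_ms Integration window after the onset, ms; must be long
#'   relative to the clamp time constant.
#' @param steady_window_ms Window at the end of the step over which the
#'   steady current is measured, ms.
#' @return Capacitance, pF.
#' @export
capacitance <- function(sweep, dv, integrate_ms = 50, steady_window_ms = 50) {
  assert_that(inherits(sweep, "sweep"), "input must be a sweep")
  assert_that(is.finite(dv) && dv != 0, "dv must be nonzero")
  onset <- sweep$meta$onset_s
  assert_that(!is.null(onset), "sweep must carry a step-onset annotation")
  i_ss <- steady_state_current(sweep, steady_window_ms)
  idx <- which(sweep$t >= onset & sweep$t <= onset + integrate_ms * 1e-3)
  q <- trapz(sweep$t[idx] * 1e3, sweep$y[idx] - i_ss)   # pA * ms
  abs(q / dv)
}

#' Passive-property panel for one simulated or recorded neuron
#'
#' Convenience wrapper bundling the two-point conductance, resting potential
#' and charge-integration capacitance into the per-neuron passive panel.
#'
#' @param i_at_minus70,i_at_minus50 Steady currents (pA) at -70/-50 mV.
#' @param rest_sweep Injection-free current-clamp sweep for
#'   [resting_potential()], or `NULL`.
#' @param cap_sweep,cap_dv Test-step sweep and step size for
#'   [capacitance()], or `NULL`.
#' @param holding_current Holding current, pA (used for the exclusion flag).
#' @param max_holding_pA Exclusion bound (default 50 pA).
#' @return A one-row data.frame of class `passive_properties`.
#' @export
passive_properties <- function(i_at_minus70, i_at_minus50, rest_sweep = NULL,
                               cap_sweep = NULL, cap_dv = NULL,
                               holding_current = NA_real_,
                               max_holding_pA = 50) {
  g <- input_conductance(i_at_minus70, i_at_minus50)
  excluded <- is.finite(holding_current) && abs(holding_current) > max_holding_pA
  structure(data.frame(
    input_resistance = g$input_resistance,
    input_conductance = g$input_conductance,
    capacitance = if (!is.null(cap_sweep)) capacitance(cap_sweep, cap_dv) else NA_real_,
    resting_potential = if (!is.null(rest_sweep)) resting_potential(rest_sweep) else NA_real_,
    holding_current = holding_current,
    excluded = excluded,
    reason = if (excluded) sprintf("holding>%gpA", max_holding_pA) else NA_character_),
    class = c("passive_properties", "data.frame"))
}
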