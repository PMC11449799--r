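#' Clamped time-series sweep
#'
#' The basic container for one electrophysiology trace: a uniformly sampled
#' time vector (seconds) plus a signal vector (mV in current clamp, pA in
#' voltage clamp) and protocol annotations.
#'
#' @param t Time vector in seconds, strictly increasing and uniformly spaced.
#' @param y Signal vector, same length as `t`; mV for current clamp, pA for
#'   voltage clamp.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param command_level Command level of the sweep: injected current (pA) in
#'   current clamp, command voltage (mV) in voltage clamp.
#' @param meta Named list of extra annotations (e.g. `onset_s`, `offset_s`
#'   marking the stimulus epoch, `zero_epoch_s` marking an injection-free
#'   epoch).
#' @return An object of class `sweep`.
#' @export
new_sweep <- function(t, y, mode = c("current_clamp", "voltage_clamp"),
                      command_level = NA_real_, meta = list()) {
  mode <- match.arg(mode)
  assert_that(length(t) == length(y), "t and y must have equal length")
  sampling_interval_s(t)
  structure(list(t = t, y = y, mode = mode,
                 command_level = command_level, meta = meta),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %s, %d samples @ %.4g kHz, command %.3g, %.3g s\n",
              x$mode, length(x$t), 1e-3 / sampling_interval_s(x$t),
              x$command_level, diff(range(x$t))))
  invisible(x)
}

#' Set of sweeps acquired under one protocol
#'
#' @param sweeps List of [new_sweep()] objects.
#' @param protocol Optional [step_protocol()] describing the acquisition.
#' @param meta Named list; conventional entries include `holding_current`
#'   (pA) and `holding_potential` (mV).
#' @return An object of class `sweep_set`.
#' @export
new_sweep_set <- function(sweeps, protocol = NULL, meta = list()) {
  assert_that(all(vapply(sweeps, inherits, logical(1), "sweep")),
              "all elements must be sweeps")
  structure(list(sweeps = sweeps, protocol = protocol, meta = meta),
            class = "sweep_set")
}

#' @export
length.sweep_set <- function(x) length(x$sweeps)

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps (%s)\n", length(x$sweeps),
              if (length(x$sweeps)) x$sweeps[[1]]$mode else "empty"))
  invisible(x)
}

#' Current-step protocol
#'
#' Defaults mirror the standard evoked-firing protocol used for immature
#' human neurons: hold at -60 mV, inject 20 current steps of 400 ms starting
#' 12 pA below the holding current and incrementing by 3 pA.
#'
#' @param holding_potential Target holding potential, mV.
#' @param n_steps Number of current steps.
#' @param step_increment Step-to-step current increment, pA.
#' @param first_step_offset Offset of the first step relative to the holding
#'   current, pA.
#' @param step_duration Step duration, ms.
#' @param sampling_interval Sampling interval, ms.
#' @param baseline Pre-step epoch at the holding current, ms.
#' @param tail Post-step epoch at the holding current, ms.
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(holding_potential = -60, n_steps = 20L,
                          step_increment = 3, first_step_offset = -12,
                          step_duration = 400, sampling_interval = 0.05,
                          baseline = 100, tail = 100) {
  assert_that(n_steps >= 1L, "n_steps must be >= 1")
  assert_that(step_duration > 0, "step_duration must be > 0")
  assert_that(sampling_interval > 0, "sampling_interval must be > 0")
  structure(list(holding_potential = holding_potential,
                 n_steps = as.integer(n_steps),
                 step_increment = step_increment,
                 first_step_offset = first_step_offset,
                 step_duration = step_duration,
                 sampling_interval = sampling_interval,
                 baseline = baseline, tail = tail),
            class = "step_protocol")
}

#' Extract the samples of a sweep inside a time window
#'
#' @param sweep A [new_sweep()] object.
#' @param from,to Window bounds in seconds (inclusive).
#' @return A `sweep` restricted to the window; `meta` is preserved.
#' @export
sweep_window <- function(sweep, from, to) {
  idx <- which(sweep$t >= from & sweep$t <= to)
  assert_that(length(idx) >= 2L, "window contains fewer than 2 samples")
  new_sweep(sweep$t[idx], sweep$y[idx], sweep$mode, sweep$command_level,
            sweep$meta)
}
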