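# Voltage-clamp current extraction: sodium transient, fast and slow
# potassium currents per step, assembled into I-V curves.

#' Extraction windows for voltage-clamp currents
#'
#' The source analysis specifies only "after stabilizing" and "within a few
#' milliseconds"; the operational windows are explicit here and configurable.
#'
#' @param transient_ms `c(from, to)` window (ms after onset) in which the
#'   inward sodium transient minimum is sought.
#' @param stabilized_ms Window (ms after onset) whose mean defines the
#'   post-transient stabilized current.
#' @param w_fast_ms Width of the "few milliseconds" window for the fast
#'   potassium maximum.
#' @param slow_ms Width of the end-of-step window for the slow potassium
#'   current.
#' @return A list of class `vclamp_config`.
#' @export
vclamp_config <- function(transient_ms = c(0, 10), stabilized_ms = c(20, 40),
                          w_fast_ms = 10, slow_ms = 10) {
  structure(list(transient_ms = transient_ms, stabilized_ms = stabilized_ms,
                 w_fast_ms = w_fast_ms, slow_ms = slow_ms),
            class = "vclamp_config")
}

vc_onset <- function(sweep) {
  onset <- sweep$meta$onset_s
  if (is.null(onset)) {
    stop_twinephys("sweep lacks a step-onset annotation", "protocol_error")
  }
  onset
}

#' Sodium current amplitude of one voltage-clamp sweep
#'
#' Subtracts the sweep minimum within the transient window (the inward
#' sodium transient) from the mean current after stabilization. The leak
#' contribution cancels in the subtraction. Inward amplitude is reported as
#' a positive number; values are floored at 0. The subtraction is only
#' applied when the trace actually undershoots its onset-instantaneous
#' current by more than `undershoot_floor` -- without an inward transient
#' (e.g. a sodium-free cell whose outward potassium current simply rises)
#' the stated formula would otherwise report the potassium activation
#' amplitude as sodium current.
#'
#' @param sweep A voltage-clamp [new_sweep()] (pA) with `meta$onset_s`.
#' @param config A [vclamp_config()].
#' @param undershoot_floor Minimal dip (pA) below the onset-instantaneous
#'   current for a transient to count.
#' @return Sodium current amplitude, pA (>= 0).
#' @export
sodium_current <- function(sweep, config = vclamp_config(),
                           undershoot_floor = 2) {
  assert_that(inherits(sweep, "sweep"), "input must be a sweep")
  onset <- vc_onset(sweep)
  tr <- sweep$t >= onset + config$transient_ms[1] * 1e-3 &
    sweep$t <= onset + config$transient_ms[2] * 1e-3
  st <- sweep$t >= onset + config$stabilized_ms[1] * 1e-3 &
    sweep$t <= onset + config$stabilized_ms[2] * 1e-3
  assert_that(any(tr) && any(st), "extraction windows fall outside the sweep")
  i_onset <- sweep$y[which(tr)[1]]
  i_min <- min(sweep$y[tr])
  if (i_min >= i_onset - undershoot_floor) return(0)
  max(0, mean(sweep$y[st]) - i_min)
}

#' Fast potassium current of one voltage-clamp sweep
#'
#' Maximal current within `w_fast_ms` after the depolarization onset, minus
#' the `leak` current expected at the step voltage.
#'
#' @param sweep A voltage-clamp [new_sweep()] with `meta$onset_s`.
#' @param config A [vclamp_config()].
#' @param leak Leak current at the step voltage, pA (0 disables subtraction).
#' @return Fast potassium current, pA.
#' @export
fast_potassium_current <- function(sweep, config = vclamp_config(), leak = 0) {
  assert_that(inherits(sweep, "sweep"), "input must be a sweep")
  onset <- vc_onset(sweep)
  w <- sweep$t > onset & sweep$t <= onset + config$w_fast_ms * 1e-3
  assert_that(any(w), "fast window falls outside the sweep")
  max(sweep$y[w]) - leak
}

#' Slow potassium current of one voltage-clamp sweep
#'
#' Mean current over the final `slow_ms` of the step, minus the leak current
#' expected at the step voltage.
#'
#' @inheritParams fast_potassium_current
#' @return Slow potassium current, pA.
#' @export
slow_potassium_current <- function(sweep, config = vclamp_config(), leak = 0) {
  assert_that(inherits(sweep, "sweep"), "input must be a sweep")
  offset <- sweep$meta$offset_s %||% max(sweep$t)
  w <- sweep$t >= offset - config$slow_ms * 1e-3 & sweep$t <= offset
  assert_that(any(w), "slow window falls outside the sweep")
  mean(sweep$y[w]) - leak
}

#' Assemble the sodium/potassium I-V curve from a voltage-clamp sweep set
#'
#' Applies the three per-sweep extractors across the command-voltage family
#' (step order preserved). When `leak_subtract` is on, a line is fitted to
#' the steady current over the hyperpolarized steps (command voltage within
#' `leak_range`) and extrapolated to every step; the potassium measures are
#' reported relative to that leak line. The sodium measure needs no leak
#' correction (it is a within-sweep difference). Turning leak subtraction
#' off reproduces the literal extraction text.
#'
#' @param sweepset A [new_sweep_set()] of voltage-clamp sweeps.
#' @param config A [vclamp_config()].
#' @param leak_subtract Fit-and-subtract the passive leak line (default TRUE).
#' @param leak_range Command-voltage range (mV) defining the leak-fit steps.
#' @return A data.frame of class `iv_curve` with columns `step_v`, `i_na`,
#'   `i_k_fast`, `i_k_slow` (pA).
#' @export
build_iv <- function(sweepset, config = vclamp_config(), leak_subtract = TRUE,
                     leak_range = c(-90, -70)) {
  assert_that(inherits(sweepset, "sweep_set"), "input must be a sweep_set")
  v <- vapply(sweepset$sweeps, function(s) as.numeric(s$command_level), numeric(1))
  steady <- vapply(sweepset$sweeps, slow_potassium_current, numeric(1),
                   config = config, leak = 0)
  leak_at <- function(vq) rep(0, length(vq))
  if (leak_subtract) {
    sel <- v >= leak_range[1] & v <= leak_range[2]
    if (sum(sel) >= 2L) {
      fit <- stats::lm(steady[sel] ~ v[sel])
      leak_at <- function(vq) unname(stats::coef(fit)[1] + stats::coef(fit)[2] * vq)
    }
  }
  ina <- vapply(sweepset$sweeps, sodium_current, numeric(1), config = config)
  ikf <- mapply(function(s, lk) fast_potassium_current(s, config, leak = lk),
                sweepset$sweeps, leak_at(v))
  iks <- steady - leak_at(v)
  structure(data.frame(step_v = v, i_na = ina, i_k_fast = as.numeric(ikf),
                       i_k_slow = iks),
            class = c("iv_curve", "data.frame"))
}
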