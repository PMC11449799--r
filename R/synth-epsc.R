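#' EPSC trace generator parameters
#'
#' @param rate Event rate, events/s (homogeneous Poisson).
#' @param amp_mean,amp_sd Mean and SD of the (lognormal) peak amplitude
#'   distribution, pA.
#' @param tau_rise,tau_decay Bi-exponential kernel time constants, ms; must
#'   satisfy `tau_decay > tau_rise > 0`.
#' @param noise_sd Additive Gaussian noise SD, pA per sample.
#' @param duration Trace duration, s.
#' @param sampling_interval Sampling interval, ms.
#' @param seed RNG seed.
#' @return An object of class `epsc_gen_params`.
#' @export
epsc_gen_params <- function(rate = 1, amp_mean = 20, amp_sd = 5,
                            tau_rise = 1, tau_decay = 5, noise_sd = 2,
                            duration = 60, sampling_interval = 0.05,
                            seed = NULL) {
  assert_that(rate >= 0, "rate must be >= 0")
  assert_that(tau_rise > 0 && tau_decay > tau_rise,
              "must have tau_decay > tau_rise > 0")
  assert_that(duration > 0, "duration must be > 0")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(rate = rate, amp_mean = amp_mean, amp_sd = amp_sd,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 noise_sd = noise_sd, duration = duration,
                 sampling_interval = sampling_interval, seed = seed),
            class = "epsc_gen_params")
}

# Bi-exponential kernel normalized to unit peak; t in ms.
epsc_kernel <- function(t, tau_rise, tau_decay) {
  tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  norm <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)) / norm
  out
}

#' Generate a synthetic spontaneous-EPSC voltage-clamp trace
#'
#' Events occur at homogeneous Poisson times; each contributes an inward
#' (negative) bi-exponential current scaled to a lognormal peak amplitude.
#' The ground-truth event list is returned alongside the trace so detector
#' recall/precision can be scored. Ground-truth event times mark the kernel
#' onset; the kernel peak lags them by the bi-exponential peak time.
#'
#' @param params An [epsc_gen_params()] object.
#' @param seed RNG seed; defaults to `params$seed`.
#' @return A list with elements `sweep` (a voltage-clamp [new_sweep()], pA)
#'   and `truth` (an [event_train()] of onset times and peak amplitudes).
#' @export
generate_epsc_trace <- function(params, seed = params$seed) {
  assert_that(inherits(params, "epsc_gen_params"), "params must be epsc_gen_params")
  dt_ms <- params$sampling_interval
  n <- round(params$duration * 1000 / dt_ms)
  t_s <- (seq_len(n) - 1L) * dt_ms * 1e-3
  with_seed(seed, {
    n_ev <- stats::rpois(1L, params$rate * params$duration)
    times <- sort(stats::runif(n_ev, 0, params$duration))
    if (params$amp_sd > 0) {
      sdlog <- sqrt(log(1 + (params$amp_sd / params$amp_mean)^2))
      meanlog <- log(params$amp_mean) - sdlog^2 / 2
      amps <- stats::rlnorm(n_ev, meanlog, sdlog)
    } else {
      amps <- rep(params$amp_mean, n_ev)
    }
    y <- numeric(n)
    # each kernel is truncated at 8 decay constants
    n_k <- round(8 * params$tau_decay / dt_ms)
    kern <- epsc_kernel((0:(n_k - 1L)) * dt_ms, params$tau_rise, params$tau_decay)
    for (i in seq_len(n_ev)) {
      i0 <- floor(times[i] * 1000 / dt_ms) + 1L
      idx <- i0:min(n, i0 + n_k - 1L)
      if (i0 <= n) y[idx] <- y[idx] - amps[i] * kern[seq_along(idx)]
    }
    if (params$noise_sd > 0) y <- y + stats::rnorm(n, 0, params$noise_sd)
    list(sweep = new_sweep(t_s, y, "voltage_clamp", command_level = -60,
                           meta = list(units = "pA")),
         truth = event_train(times, amps, params$duration))
  })
}
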