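#' MEA spike-train generator parameters
#'
#' @param n_electrodes Number of electrodes in the well (>= 1).
#' @param background_rate Background Poisson firing rate per electrode, Hz.
#' @param burst_rate Inserted-burst rate per electrode, bursts/min.
#' @param burst_len Spikes per inserted burst.
#' @param intra_burst_isi Interval between spikes inside a burst, ms.
#' @param duration Recording duration, s (default 600, i.e. 10 min).
#' @param seed RNG seed.
#' @return An object of class `mea_gen_params`.
#' @export
mea_gen_params <- function(n_electrodes = 8L, background_rate = 1,
                           burst_rate = 2, burst_len = 10L,
                           intra_burst_isi = 10, duration = 600,
                           seed = NULL) {
  assert_that(n_electrodes >= 1L, "n_electrodes must be >= 1")
  assert_that(background_rate >= 0 && burst_rate >= 0, "rates must be >= 0")
  assert_that(burst_len >= 2L, "burst_len must be >= 2")
  assert_that(duration > 0, "duration must be > 0")
  structure(list(n_electrodes = as.integer(n_electrodes),
                 background_rate = background_rate, burst_rate = burst_rate,
                 burst_len = as.integer(burst_len),
                 intra_burst_isi = intra_burst_isi, duration = duration,
                 seed = seed),
            class = "mea_gen_params")
}

#' Spike-train set for one MEA well
#'
#' @param trains Named list mapping electrode id to a sorted numeric vector
#'   of spike times (s).
#' @param duration Recording duration, s.
#' @param well_id Well identifier.
#' @param recording_day Day index of the recording.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, duration, well_id = "W1",
                            recording_day = NA_integer_) {
  assert_that(duration > 0, "duration must be > 0")
  trains <- lapply(trains, function(tt) {
    tt <- sort(as.numeric(tt))
    assert_that(!length(tt) || (min(tt) >= 0 && max(tt) <= duration),
                "spike times must lie within [0, duration]")
    tt
  })
  structure(list(trains = trains, duration = duration, well_id = well_id,
                 recording_day = recording_day),
            class = "spike_train_set")
}

#' Generate bursty MEA spike trains with ground truth
#'
#' Background spikes are homogeneous Poisson per electrode; bursts are
#' inserted as dense regular runs (`burst_len` spikes at `intra_burst_isi`)
#' at Poisson burst times. The inserted bursts are returned as ground truth.
#'
#' @param params An [mea_gen_params()] object.
#' @param seed RNG seed; defaults to `params$seed`.
#' @param well_id,recording_day Passed through to the train set.
#' @return A list with `trains` (a [spike_train_set()]) and `truth` (a
#'   data.frame of inserted bursts: electrode_id, start, end, n_spikes).
#' @export
generate_mea_trains <- function(params, seed = params$seed, well_id = "W1",
                                recording_day = NA_integer_) {
  assert_that(inherits(params, "mea_gen_params"), "params must be mea_gen_params")
  dur <- params$duration
  burst_span <- (params$burst_len - 1L) * params$intra_burst_isi / 1000
  with_seed(seed, {
    truth <- list()
    trains <- list()
    for (e in seq_len(params$n_electrodes)) {
      eid <- sprintf("E%02d", e)
      n_bg <- stats::rpois(1L, params$background_rate * dur)
      spikes <- stats::runif(n_bg, 0, dur)
      n_b <- stats::rpois(1L, params$burst_rate / 60 * dur)
      starts <- sort(stats::runif(n_b, 0, max(dur - burst_span, 0)))
      for (s0 in starts) {
        bt <- s0 + (0:(params$burst_len - 1L)) * params$intra_burst_isi / 1000
        spikes <- c(spikes, bt)
        truth[[length(truth) + 1L]] <-
          data.frame(electrode_id = eid, start = s0, end = s0 + burst_span,
                     n_spikes = params$burst_len)
      }
      trains[[eid]] <- sort(pmin(spikes, dur))
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(electrode_id = character(0), start = numeric(0),
                 end = numeric(0), n_spikes = integer(0))
    list(trains = spike_train_set(trains, dur, well_id, recording_day),
         truth = truth)
  })
}

#' Synthesize a raw extracellular voltage trace with inserted spikes
#'
#' Utility for exercising the threshold spike detector: Gaussian noise at the
#' MEA sampling rate with biphasic spike waveforms added at given times.
#'
#' @param spike_times Spike times, s.
#' @param duration Trace duration, s.
#' @param fs Sampling rate, Hz (default 12500).
#' @param noise_sd Noise SD, uV.
#' @param spike_amp Peak amplitude of the negative spike phase, uV.
#' @param seed RNG seed.
#' @return A [new_sweep()] (voltage_clamp mode is not meaningful here; the
#'   sweep is tagged `current_clamp` with `meta$units = "uV"`).
#' @export
generate_mea_raw <- function(spike_times, duration, fs = 12500,
                             noise_sd = 3, spike_amp = 30, seed = NULL) {
  n <- round(duration * fs)
  t_s <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    y <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    # biphasic waveform: 0.4 ms negative lobe then 0.6 ms positive lobe
    tw <- seq(0, 1e-3, by = 1 / fs)
    w <- -sin(pi * tw / 0.4e-3) * (tw <= 0.4e-3) +
      0.4 * sin(pi * (tw - 0.4e-3) / 0.6e-3) * (tw > 0.4e-3)
    for (ts in spike_times) {
      i0 <- round(ts * fs) + 1L
      idx <- i0:min(n, i0 + length(w) - 1L)
      if (i0 <= n) y[idx] <- y[idx] + spike_amp * w[seq_along(idx)]
    }
    new_sweep(t_s, y, "current_clamp", command_level = 0,
              meta = list(units = "uV", fs = fs))
  })
}
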