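# MEA analysis: threshold spike detection on raw traces, Poisson-surprise
# burst detection, network-burst detection and per-well summaries.

#' MEA analysis configuration
#'
#' Detection mirrors the acquisition description of multiwell MEA systems:
#' band-pass 10 Hz - 2.5 kHz, adaptive threshold at 5.5 SD of each
#' electrode's activity, and a dead time after each crossing. The burst
#' detector is the classic Poisson-surprise formulation (the commercial
#' "adaptive Poisson" algorithm is proprietary; numeric parity with it is
#' not claimed). Negative-going crossings are primary, per extracellular
#' convention.
#'
#' @param band Band-pass corner frequencies, Hz.
#' @param threshold_sd Detection threshold in SDs around the mean.
#' @param dead_time_ms Dead time after each detected crossing, ms.
#' @param polarity `"negative"` or `"both"`.
#' @param filter Apply the band-pass before thresholding (default TRUE).
#' @param min_spikes Minimum spikes per burst.
#' @param s_min Minimum Poisson surprise (-log10 tail probability).
#' @param isi_factor Burst-seed ISI threshold as a fraction of the train's
#'   mean ISI.
#' @param network_fraction Fraction of active electrodes that must burst
#'   simultaneously for a network burst.
#' @param network_gap_ms Network-burst intervals closer than this are merged.
#' @return A list of class `mea_config`.
#' @export
mea_config <- function(band = c(10, 2500), threshold_sd = 5.5,
                       dead_time_ms = 1, polarity = c("negative", "both"),
                       filter = TRUE, min_spikes = 5L, s_min = 10,
                       isi_factor = 0.5, network_fraction = 0.25,
                       network_gap_ms = 100) {
  structure(list(band = band, threshold_sd = threshold_sd,
                 dead_time_ms = dead_time_ms, polarity = match.arg(polarity),
                 filter = filter, min_spikes = as.integer(min_spikes),
                 s_min = s_min, isi_factor = isi_factor,
                 network_fraction = network_fraction,
                 network_gap_ms = network_gap_ms),
            class = "mea_config")
}

# Zero-phase FFT brick-wall band-pass.
fft_bandpass <- function(y, fs, band) {
  n <- length(y)
  freq <- (seq_len(n) - 1L) * fs / n
  freq <- pmin(freq, fs - freq)                  # two-sided
  mask <- freq >= band[1] & freq <= band[2]
  Re(stats::fft(stats::fft(y) * mask, inverse = TRUE)) / n
}

#' Threshold spike detection on one raw MEA electrode trace
#'
#' Band-pass filters the trace, then reports threshold crossings at
#' `mean +/- threshold_sd * SD` with the configured polarity and dead time.
#'
#' @param raw A [new_sweep()] holding the raw electrode voltage.
#' @param config An [mea_config()].
#' @return Numeric vector of spike times, s.
#' @export
mea_spike_detect <- function(raw, config = mea_config()) {
  assert_that(inherits(raw, "sweep"), "input must be a sweep")
  dt_s <- sampling_interval_s(raw$t)
  fs <- 1 / dt_s
  if (fs < 2 * config$band[2]) {
    stop_twinephys(sprintf("sampling rate %.4g Hz below 2x the %.4g Hz high cutoff",
                           fs, config$band[2]), "nyquist_error")
  }
  y <- if (config$filter) fft_bandpass(raw$y, fs, config$band) else raw$y
  mu <- mean(y)
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) return(numeric(0))
  lo <- mu - config$threshold_sd * s
  hi <- mu + config$threshold_sd * s
  n <- length(y)
  idx <- which(y[-1] < lo & y[-n] >= lo) + 1L
  if (config$polarity == "both") {
    idx <- sort(c(idx, which(y[-1] > hi & y[-n] <= hi) + 1L))
  }
  if (!length(idx)) return(numeric(0))
  dead <- max(1L, round(config$dead_time_ms * 1e-3 * fs))
  keep <- idx[1]
  for (i in idx[-1]) if (i - keep[length(keep)] >= dead) keep <- c(keep, i)
  raw$t[keep]
}

#' Poisson surprise of a spike run
#'
#' `-log10 P(N >= n)` for a Poisson count with mean `lambda * t_window`.
#'
#' @param n Number of spikes in the window.
#' @param lambda Baseline rate, Hz.
#' @param t_window Window length, s.
#' @return Surprise value (>= 0).
#' @export
poisson_surprise <- function(n, lambda, t_window) {
  -stats::ppois(n - 1L, lambda * t_window, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Detect bursts in one spike train by Poisson-surprise maximization
#'
#' Runs of at least `min_spikes` spikes with inter-spike intervals below
#' `isi_factor` times the train's mean ISI seed candidate bursts, which are
#' greedily extended (and trimmed) at both ends while the surprise
#' increases. Non-overlapping candidates with surprise >= `s_min` are
#' reported. The baseline rate lambda is the whole-train mean rate, per the
#' classic formulation.
#'
#' @param times Sorted spike times, s.
#' @param duration Recording duration, s.
#' @param config An [mea_config()].
#' @param electrode_id Identifier copied into the output.
#' @return A data.frame of class `burst_set` with columns `electrode_id`,
#'   `start`, `end`, `n_spikes`, `surprise`.
#' @export
detect_bursts <- function(times, duration, config = mea_config(),
                          electrode_id = NA_character_) {
  empty <- structure(data.frame(electrode_id = character(0), start = numeric(0),
                                end = numeric(0), n_spikes = integer(0),
                                surprise = numeric(0)),
                     class = c("burst_set", "data.frame"))
  n <- length(times)
  if (n < config$min_spikes) return(empty)
  assert_that(!is.unsorted(times), "spike times must be sorted")
  lambda <- n / duration
  s_of <- function(i, j) {
    tw <- max(times[j] - times[i], 1e-9)
    poisson_surprise(j - i + 1L, lambda, tw)
  }
  isi <- diff(times)
  thr <- config$isi_factor / lambda
  dense <- isi < thr
  # runs of consecutive dense ISIs
  r <- rle(dense)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= config$min_spikes - 1L)
  bursts <- list()
  for (ci in cand) {
    i <- starts[ci]            # first spike index of run
    j <- ends[ci] + 1L         # last spike index of run
    s <- s_of(i, j)
    repeat {                   # grow right
      if (j < n && s_of(i, j + 1L) > s) { j <- j + 1L; s <- s_of(i, j) } else break
    }
    repeat {                   # grow left
      if (i > 1L && s_of(i - 1L, j) > s) { i <- i - 1L; s <- s_of(i, j) } else break
    }
    repeat {                   # trim left
      if (j - i + 1L > config$min_spikes && s_of(i + 1L, j) > s) {
        i <- i + 1L; s <- s_of(i, j)
      } else break
    }
    repeat {                   # trim right
      if (j - i + 1L > config$min_spikes && s_of(i, j - 1L) > s) {
        j <- j - 1L; s <- s_of(i, j)
      } else break
    }
    bursts[[length(bursts) + 1L]] <- c(i = i, j = j, s = s)
  }
  if (!length(bursts)) return(empty)
  b <- unique(do.call(rbind, bursts))
  b <- b[order(b[, "i"]), , drop = FALSE]
  # resolve overlaps: keep the higher-surprise burst
  keep <- rep(TRUE, nrow(b))
  for (k in seq_len(nrow(b))[-1]) {
    prev <- max(which(keep[seq_len(k - 1L)]))
    if (b[k, "i"] <= b[prev, "j"]) {
      if (b[k, "s"] > b[prev, "s"]) keep[prev] <- FALSE else keep[k] <- FALSE
    }
  }
  b <- b[keep & b[, "s"] >= config$s_min, , drop = FALSE]
  if (!nrow(b)) return(empty)
  structure(data.frame(electrode_id = electrode_id,
                       start = times[b[, "i"]], end = times[b[, "j"]],
                       n_spikes = as.integer(b[, "j"] - b[, "i"] + 1L),
                       surprise = b[, "s"]),
            class = c("burst_set", "data.frame"))
}

#' Detect bursts on every electrode of a well
#'
#' @param trainset A [spike_train_set()].
#' @param config An [mea_config()].
#' @return A combined `burst_set` across electrodes.
#' @export
detect_bursts_well <- function(trainset, config = mea_config()) {
  assert_that(inherits(trainset, "spike_train_set"), "input must be a spike_train_set")
  out <- lapply(names(trainset$trains), function(eid) {
    detect_bursts(trainset$trains[[eid]], trainset$duration, config, eid)
  })
  res <- do.call(rbind, out)
  structure(res, class = c("burst_set", "data.frame"))
}

#' Detect network bursts from per-electrode bursts
#'
#' Intervals during which single-electrode bursts overlap on at least
#' `network_fraction * n_active` electrodes (at least 2), merged when gaps
#' are shorter than `network_gap_ms`.
#'
#' @param bursts A `burst_set` (e.g. from [detect_bursts_well()]).
#' @param n_active Number of active electrodes in the well.
#' @param config An [mea_config()].
#' @return A data.frame with columns `start`, `end`; zero rows when no
#'   interval reaches the electrode quorum.
#' @export
detect_network_bursts <- function(bursts, n_active, config = mea_config()) {
  empty <- data.frame(start = numeric(0), end = numeric(0))
  if (!nrow(bursts) || n_active < 2L) return(empty)
  quorum <- max(2L, ceiling(config$network_fraction * n_active))
  # sweep over burst edges counting distinct bursting electrodes
  ev <- rbind(data.frame(t = bursts$start, d = 1L),
              data.frame(t = bursts$end, d = -1L))
  ev <- ev[order(ev$t, -ev$d), ]
  active <- cumsum(ev$d)
  on <- active >= quorum
  if (!any(on)) return(empty)
  starts <- ev$t[which(on & !c(FALSE, on[-length(on)]))]
  ends <- ev$t[which(!on & c(FALSE, on[-length(on)]))]
  if (length(ends) < length(starts)) ends <- c(ends, max(bursts$end))
  iv <- data.frame(start = starts, end = ends)
  # merge close intervals
  gap <- config$network_gap_ms * 1e-3
  if (nrow(iv) > 1L) {
    merged <- iv[1, ]
    for (k in 2:nrow(iv)) {
      if (iv$start[k] - merged$end[nrow(merged)] < gap) {
        merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], iv$end[k])
      } else merged <- rbind(merged, iv[k, ])
    }
    iv <- merged
  }
  iv
}

#' Per-well activity summary
#'
#' @param trainset A [spike_train_set()].
#' @param config An [mea_config()].
#' @return A one-row data.frame of class `well_summary`: `well_id`, `day`,
#'   `n_spikes`, `n_bursts`, `n_network_bursts`, `mean_firing_rate` (Hz per
#'   electrode).
#' @export
summarize_well <- function(trainset, config = mea_config()) {
  assert_that(inherits(trainset, "spike_train_set"), "input must be a spike_train_set")
  n_spikes <- sum(vapply(trainset$trains, length, integer(1)))
  bursts <- detect_bursts_well(trainset, config)
  n_active <- sum(vapply(trainset$trains, length, integer(1)) > 0)
  nb <- detect_network_bursts(bursts, n_active, config)
  n_el <- max(1L, length(trainset$trains))
  structure(data.frame(well_id = trainset$well_id, day = trainset$recording_day,
                       n_spikes = n_spikes, n_bursts = nrow(bursts),
                       n_network_bursts = nrow(nb),
                       mean_firing_rate = n_spikes / (n_el * trainset$duration)),
            class = c("well_summary", "data.frame"))
}

#' Longitudinal group table from well summaries
#'
#' Averages each variable across a subject's replicate wells and returns a
#' long table keyed by (group, subject, day), the shape consumed by the
#' two-way ANOVA layer.
#'
#' @param summaries A data.frame of well summaries carrying `group`,
#'   `subject_id`, `day` columns plus the well variables.
#' @param variables Variables to carry (default: the standard counts/rate).
#' @return A long data.frame with columns `group`, `subject_id`, `day`,
#'   `variable`, `value`.
#' @export
longitudinal_table <- function(summaries,
                               variables = c("n_spikes", "n_bursts",
                                             "n_network_bursts",
                                             "mean_firing_rate")) {
  assert_that(all(c("group", "subject_id", "day") %in% names(summaries)),
              "summaries must carry group, subject_id, day")
  out <- list()
  for (v in variables) {
    agg <- stats::aggregate(summaries[[v]],
                            by = list(group = summaries$group,
                                      subject_id = summaries$subject_id,
                                      day = summaries$day),
                            FUN = mean)
    out[[v]] <- data.frame(group = agg$group, subject_id = agg$subject_id,
                           day = agg$day, variable = v, value = agg$x)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
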