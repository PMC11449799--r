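# MEA spike detection, Poisson-surprise bursts, network bursts, summaries.

test_that("mea_spike_detect: silence, Nyquist guard, level-crossing statistics", {
  sw0 <- generate_mea_raw(numeric(0), duration = 5, noise_sd = 0, seed = 1)
  expect_length(mea_spike_detect(sw0), 0L)

  low_fs <- generate_mea_raw(numeric(0), duration = 2, fs = 4000, seed = 1)
  expect_error(mea_spike_detect(low_fs), class = "nyquist_error")

  # iid Gaussian noise, filter off: detected crossing count matches the
  # analytic downward-level-crossing expectation N * P(x_t >= u) * P(x < u)
  # within 3 sigma (Poisson-scale dispersion)
  cfg <- mea_config(threshold_sd = 4, filter = FALSE, dead_time_ms = 0)
  n_det <- vapply(1:4, function(s) {
    raw <- generate_mea_raw(numeric(0), duration = 120, noise_sd = 3, seed = s)
    length(mea_spike_detect(raw, cfg))
  }, numeric(1))
  n_samp <- 120 * 12500
  p_cross <- pnorm(-4) * (1 - pnorm(-4))
  expected <- n_samp * p_cross
  expect_lt(abs(mean(n_det) - expected), 3 * sqrt(expected / 4))

  # inserted large spikes recovered within +/- 1 ms
  times <- seq(0.5, 59.5, by = 0.5)
  raw <- generate_mea_raw(times, duration = 60, noise_sd = 3, spike_amp = 30,
                          seed = 9)
  det <- mea_spike_detect(raw)
  m <- match_events(times, det, tol_s = 1e-3)
  expect_equal(m$fn, 0L)
  expect_lte(m$fp, 1L)
})

test_that("poisson_surprise matches the brute-force tail sum", {
  for (i in 1:50) {
    n <- sample(5:50, 1)
    lambda <- runif(1, 0.5, 20)
    tw <- runif(1, 0.01, 2)
    expect_equal(poisson_surprise(n, lambda, tw),
                 oracle_surprise(n, lambda, tw), tolerance = 1e-8)
  }
})

test_that("detect_bursts: empty train, single embedded burst, oracle surprise", {
  expect_equal(nrow(detect_bursts(numeric(0), 600)), 0L)

  # 10 spikes at 100 Hz embedded in a sparse regular background
  bg <- seq(0.5, 599.5, by = 1)
  burst <- 300.05 + (0:9) * 0.01
  train <- sort(c(bg, burst))
  b <- detect_bursts(train, 600)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_spikes, 10L)
  expect_equal(b$start, 300.05)
  expect_equal(b$end, 300.14, tolerance = 1e-9)
  lambda <- length(train) / 600
  expect_equal(b$surprise, oracle_surprise(10, lambda, 300.14 - 300.05),
               tolerance = 1e-8)
})

test_that("every reported surprise equals the exact Poisson tail computation", {
  set.seed(42)
  n_checked <- 0L
  for (i in 1:40) {
    g <- generate_mea_trains(
      mea_gen_params(background_rate = runif(1, 0.5, 3),
                     burst_rate = runif(1, 1, 6), burst_len = sample(5:15, 1),
                     intra_burst_isi = runif(1, 5, 20), n_electrodes = 1,
                     duration = 120), seed = 1000 + i)
    train <- g$trains$trains[[1]]
    b <- detect_bursts(train, 120)
    if (!nrow(b)) next
    lambda <- length(train) / 120
    for (k in seq_len(nrow(b))) {
      expect_equal(b$surprise[k],
                   oracle_surprise(b$n_spikes[k], lambda,
                                   max(b$end[k] - b$start[k], 1e-9)),
                   tolerance = 1e-8)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 50L)
})

test_that("false-burst rate on homogeneous Poisson trains is <= 0.5 per train", {
  n_false <- vapply(1:50, function(s) {
    g <- generate_mea_trains(mea_gen_params(background_rate = 5,
                                            burst_rate = 0, n_electrodes = 1,
                                            duration = 600), seed = 2000 + s)
    nrow(detect_bursts(g$trains$trains[[1]], 600))
  }, numeric(1))
  expect_lte(mean(n_false), 0.5)
})

test_that("burst count is monotone non-increasing in the surprise cutoff", {
  g <- generate_mea_trains(mea_gen_params(background_rate = 2, burst_rate = 6,
                                          n_electrodes = 1, duration = 300),
                           seed = 77)
  train <- g$trains$trains[[1]]
  counts <- vapply(c(3, 6, 10, 20, 40), function(smin) {
    nrow(detect_bursts(train, 300, mea_config(s_min = smin)))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  # burst spikes are a subset of the train and inside the recording
  b <- detect_bursts(train, 300)
  if (nrow(b)) {
    expect_true(all(b$start >= 0 & b$end <= 300 & b$end > b$start))
    expect_true(all(b$start %in% train & b$end %in% train))
  }
})

test_that("network bursts: quorum, synchrony limits, interval bounds", {
  cfg <- mea_config()
  # bursts on 1 of 8 electrodes: no network burst
  one <- data.frame(electrode_id = "E01", start = c(1, 5), end = c(1.2, 5.3),
                    n_spikes = 10L, surprise = 20)
  expect_equal(nrow(detect_network_bursts(one, 8, cfg)), 0L)

  # identical trains on every electrode: network bursts == per-electrode bursts
  g <- generate_mea_trains(mea_gen_params(background_rate = 1, burst_rate = 3,
                                          burst_len = 12, n_electrodes = 1,
                                          duration = 300), seed = 5)
  train <- g$trains$trains[[1]]
  per <- detect_bursts(train, 300)
  expect_gte(nrow(per), 2L)   # deterministic for this seed
  dup <- do.call(rbind, lapply(sprintf("E%02d", 1:8), function(e) {
    b <- per
    b$electrode_id <- e
    b
  }))
  nb <- detect_network_bursts(dup, 8, cfg)
  expect_equal(nrow(nb), nrow(per))
  expect_true(all(nb$start >= 0 & nb$end <= 300))

  # synchronous inserted bursts across all electrodes are each recovered
  starts <- c(30, 90, 150, 210, 270)
  trains <- lapply(1:6, function(e) {
    sort(c(runif(30, 0, 300), rep(starts, each = 10) + rep((0:9) * 0.01, 5)))
  })
  names(trains) <- sprintf("E%02d", 1:6)
  ts <- spike_train_set(trains, 300)
  bs <- detect_bursts_well(ts)
  nb2 <- detect_network_bursts(bs, 6, cfg)
  expect_equal(nrow(nb2), length(starts))
})

test_that("well summary counts and longitudinal aggregation", {
  trains <- list(E01 = seq(0.1, 99.9, length.out = 100))
  ts <- spike_train_set(trains, 100, well_id = "W7", recording_day = 37L)
  ws <- summarize_well(ts)
  expect_equal(ws$n_spikes, 100L)
  expect_equal(ws$well_id, "W7")
  expect_equal(ws$mean_firing_rate, 1)

  # six replicate wells with counts 10..60 -> subject mean 35
  summaries <- data.frame(group = "control", subject_id = "s1", day = 37,
                          n_spikes = seq(10, 60, by = 10), n_bursts = 0,
                          n_network_bursts = 0, mean_firing_rate = 0)
  lt <- longitudinal_table(summaries)
  expect_equal(lt$value[lt$variable == "n_spikes"], 35)
})

test_that("group ordering of firing rates survives the pipeline summaries", {
  rates <- c(control = 1.5, cotwin = 2.2, affected = 0.7)
  ok <- vapply(1:10, function(s) {
    mfr <- vapply(names(rates), function(g) {
      gen <- generate_mea_trains(
        mea_gen_params(background_rate = rates[[g]], burst_rate = 2,
                       n_electrodes = 8, duration = 60),
        seed = s * 17 + match(g, names(rates)))
      summarize_well(gen$trains)$mean_firing_rate
    }, numeric(1))
    mfr["affected"] < mfr["control"] && mfr["control"] < mfr["cotwin"]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
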