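# Internal helpers: unit notes, seeding, peak finding, numerics.
#
# Unit conventions used throughout the package:
#   voltage mV, current pA, conductance nS, resistance GOhm, capacitance pF,
#   time ms inside the integrator and feature code, seconds at the Sweep
#   interface. These are mutually consistent: nS * mV = pA, mV / GOhm = pA,
#   pA * ms / mV = pF.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1L)
  old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_twinephys <- function(msg, class) {
  stop(structure(class = c(class, "twinephys_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "invalid_parameter_error") {
  if (!isTRUE(ok)) stop_twinephys(msg, class)
  invisible(TRUE)
}

# Trapezoidal integral of y over x (same length).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Local-maximum finder with height, prominence and minimum-distance filters.
# Returns sorted indices. Peaks are strict against the left neighbour and
# >= the right neighbour, so the first sample of a plateau qualifies.
find_peaks <- function(y, height = -Inf, prominence = 0, min_distance = 1L) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  cand <- cand[y[cand] >= height]
  if (!length(cand)) return(integer(0))
  if (prominence > 0) {
    keep <- vapply(cand, function(i) {
      higher_l <- which(y[seq_len(i - 1L)] > y[i])
      lo <- if (length(higher_l)) max(higher_l) + 1L else 1L
      higher_r <- which(y[(i + 1L):n] > y[i]) + i
      hi <- if (length(higher_r)) min(higher_r) - 1L else n
      base <- max(min(y[lo:i]), min(y[i:hi]))
      (y[i] - base) >= prominence
    }, logical(1))
    cand <- cand[keep]
  }
  if (min_distance > 1L && length(cand) > 1L) {
    ord <- cand[order(y[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(kept - i) >= min_distance)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  cand
}

# Linear interpolation of the time at which y crosses `level` between
# samples i and i+1.
crossing_time <- function(t, y, i, level) {
  if (y[i + 1L] == y[i]) return(t[i])
  t[i] + (level - y[i]) / (y[i + 1L] - y[i]) * (t[i + 1L] - t[i])
}

sampling_interval_s <- function(t) {
  dt <- diff(t)
  assert_that(length(dt) >= 1L && all(dt > 0), "time vector must be strictly increasing")
  m <- stats::median(dt)
  assert_that(max(abs(dt - m)) < 1e-6 * m + 1e-12, "time vector must be uniformly spaced")
  m
}

# MD5 of an R object via its canonical JSON rendering (used to stamp outputs).
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}
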