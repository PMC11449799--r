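# Plain-text I/O: per-sweep CSV + JSON manifest for sweep sets, long CSV
# for spike trains, TSV for tables.

#' Write a sweep set as per-sweep CSVs plus a JSON manifest
#'
#' Each sweep becomes a two-column CSV (`time_s`, `value`); the manifest
#' records clamp mode, units, per-sweep command levels and annotations.
#'
#' @param sweepset A [new_sweep_set()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Path of the manifest JSON, invisibly.
#' @export
write_sweep_set <- function(sweepset, dir, prefix = "sweep") {
  assert_that(inherits(sweepset, "sweep_set"), "input must be a sweep_set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(sweepset$sweeps), function(i) {
    sw <- sweepset$sweeps[[i]]
    fn <- sprintf("%s_%03d.csv", prefix, i)
    utils::write.csv(data.frame(time_s = sw$t, value = sw$y),
                     file.path(dir, fn), row.names = FALSE)
    list(file = fn, mode = sw$mode, command_level = sw$command_level,
         units = if (sw$mode == "current_clamp") "mV" else "pA",
         meta = sw$meta)
  })
  manifest <- list(sweeps = entries, meta = sweepset$meta,
                   protocol = sweepset$protocol)
  mf <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(mf)
}

#' Read a sweep set from a manifest written by [write_sweep_set()]
#'
#' @param manifest Path to the manifest JSON.
#' @return A [new_sweep_set()].
#' @export
read_sweep_set <- function(manifest) {
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  dir <- dirname(manifest)
  sweeps <- lapply(m$sweeps, function(e) {
    d <- utils::read.csv(file.path(dir, e$file))
    meta <- lapply(e$meta, function(x) if (is.list(x)) unlist(x) else x)
    new_sweep(d$time_s, d$value, e$mode,
              command_level = e$command_level %||% NA_real_, meta = meta)
  })
  proto <- if (!is.null(m$protocol)) do.call(step_protocol, m$protocol)
  new_sweep_set(sweeps, proto, meta = m$meta %||% list())
}

#' Write spike trains as a long CSV (electrode_id, spike_time_s)
#'
#' @param trainset A [spike_train_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(trainset, path) {
  assert_that(inherits(trainset, "spike_train_set"), "input must be a spike_train_set")
  rows <- do.call(rbind, lapply(names(trainset$trains), function(eid) {
    tt <- trainset$trains[[eid]]
    if (!length(tt)) return(NULL)
    data.frame(electrode_id = eid, spike_time_s = tt)
  }))
  if (is.null(rows)) rows <- data.frame(electrode_id = character(0),
                                        spike_time_s = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from a long CSV
#'
#' @param path CSV with columns `electrode_id`, `spike_time_s`.
#' @param duration Recording duration, s (defaults to the last spike time).
#' @param well_id,recording_day Passed to [spike_train_set()].
#' @return A [spike_train_set()].
#' @export
read_spike_csv <- function(path, duration = NULL, well_id = "W1",
                           recording_day = NA_integer_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  trains <- split(d$spike_time_s, d$electrode_id)
  duration <- duration %||% if (nrow(d)) max(d$spike_time_s) else 1
  spike_train_set(trains, duration, well_id, recording_day)
}

# TSV with a provenance header comment (config hash + seed).
write_tsv_stamped <- function(df, path, hash = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) {
    writeLines(sprintf("# twinephys config_hash=%s seed=%s", hash,
                       seed %||% "NA"), con)
  }
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
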