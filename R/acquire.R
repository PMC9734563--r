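reading_to_row <- function(r) {
  bins <- as.list(r$bins_per_L)
  names(bins) <- sprintf("bin_%03d", seq_along(bins) - 1L)
  c(list(time_s = r$time_s, device_id = r$device_id,
         `repeat` = r$repeat_index, phase = r$phase),
    bins,
    list(total_per_L = r$total_per_L, pm2_5_ugm3 = r$pm2_5_ugm3,
         pm10_ugm3 = r$pm10_ugm3))
}

#' Run the sampling loop over a schedule
#'
#' Drives a backend through every segment of a schedule: device-state
#' changes are applied at each segment boundary before the segment's first
#' tick, the backend is stepped to each tick time, and one reading per
#' sensor is taken at every tick and appended to the log. Ticks fall at
#' exact multiples of `tick_s` starting at `t = tick_s`. If the backend
#' fails mid-run, the partial log is flushed and the manifest is flagged
#' incomplete before the error is re-raised.
#'
#' @param schedule A [expand_schedule()] result.
#' @param backend Object implementing the backend protocol (see
#'   [backend-protocol]).
#' @param log_path CSV file to write (created/overwritten).
#' @param manifest_path Optional JSON manifest path (default: alongside the
#'   log with extension .json).
#' @return A `run_artifacts` object: list with `log_path`, `manifest_path`
#'   and the manifest contents (config id, seed, tick_s, n_sensors,
#'   n_ticks, rows, start stamp, `complete` flag).
#' @export
acquire <- function(schedule, backend, log_path,
                    manifest_path = sub("\\.csv$", ".json", log_path)) {
  stopifnot(inherits(schedule, "schedule"))
  sensors <- backend_sensors(backend)
  tick <- schedule$tick_s
  rows <- vector("list", schedule$n_ticks * length(sensors))
  n_rows <- 0L
  start_stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  complete <- FALSE
  ticks_done <- 0L

  flush <- function() {
    dt <- if (n_rows)
      data.table::rbindlist(rows[seq_len(n_rows)])
    else empty_log_table(backend)
    data.table::fwrite(dt, log_path)
    manifest <- list(
      schema_version = 1L,
      config_id = schedule$config_id,
      seed = schedule$seed,
      tick_s = tick,
      n_sensors = length(sensors),
      sensors = as.list(sensors),
      n_ticks_scheduled = schedule$n_ticks,
      n_ticks_done = ticks_done,
      rows = n_rows,
      start = start_stamp,
      software = as.character(utils::packageVersion("aerotest")),
      complete = complete)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
    manifest
  }

  manifest <- tryCatch({
    t_cur <- 0
    for (k in seq_len(nrow(schedule$segments))) {
      seg <- schedule$segments[k, ]
      backend_apply(backend, c(generator = seg$generator,
                               purifier = seg$purifier, fan = seg$fan))
      first <- floor(seg$t_start_s / tick) + 1L
      last <- floor(seg$t_end_s / tick)
      if (last >= first) {
        for (j in first:last) {
          t_tick <- j * tick
          backend_step(backend, t_tick - t_cur)
          t_cur <- t_tick
          for (r in backend_read(backend, phase = seg$phase,
                                 repeat_index = seg$repeat_index)) {
            n_rows <- n_rows + 1L
            rows[[n_rows]] <- reading_to_row(r)
          }
          ticks_done <- ticks_done + 1L
        }
      }
      if (seg$t_end_s > t_cur) { # advance physics through the tickless tail
        backend_step(backend, seg$t_end_s - t_cur)
        t_cur <- seg$t_end_s
      }
    }
    complete <- TRUE
    flush()
  }, error = function(e) {
    flush()
    stop("acquisition aborted (partial log flagged incomplete): ",
         conditionMessage(e), call. = FALSE)
  })

  structure(list(log_path = log_path, manifest_path = manifest_path,
                 manifest = manifest),
            class = "run_artifacts")
}

empty_log_table <- function(backend) {
  n_bins <- backend$grid$n_bins
  cols <- c("time_s", "device_id", "repeat", "phase",
            sprintf("bin_%03d", seq_len(n_bins) - 1L),
            "total_per_L", "pm2_5_ugm3", "pm10_ugm3")
  dt <- data.table::as.data.table(
    stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  dt[, c("device_id", "phase") := list(character(0), character(0))]
  dt
}

#' Run a configured experiment end to end
#'
#' Expands the configuration into a schedule, builds the simulated backend
#' from its `sim:` section (or uses the supplied backend), runs the
#' sampling loop and writes one CSV log plus a JSON manifest into
#' `out_dir`.
#'
#' @param cfg An [experiment_config()] (or a path/string accepted by
#'   [parse_config()]).
#' @param out_dir Output directory, created if missing.
#' @param backend Optional backend; default builds one with
#'   [sim_backend_from_config()].
#' @param grid Size grid for the default backend.
#' @return [acquire()]'s `run_artifacts`.
#' @export
run_experiment <- function(cfg, out_dir, backend = NULL,
                           grid = default_bin_grid()) {
  if (is.character(cfg))
    cfg <- parse_config(cfg, is_file = file.exists(cfg))
  stopifnot(inherits(cfg, "experiment_config"))
  schedule <- expand_schedule(cfg)
  if (is.null(backend)) backend <- sim_backend_from_config(cfg, grid)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  acquire(schedule, backend, file.path(out_dir, paste0(cfg$id, ".csv")))
}

#' Read a run log
#'
#' Reads a CSV log written by [acquire()] and validates its schema: the
#' fixed metadata columns, a contiguous `bin_000..bin_NNN` block, and the
#' derived columns must all be present. A grid may be supplied to assert
#' the expected bin count; a mismatch is an error, never a silent
#' truncation.
#'
#' @param path CSV log path.
#' @param grid Optional [size_bin_grid()] the log must match.
#' @return A `data.table` of readings in file order, with attribute
#'   `n_bins`.
#' @export
read_log <- function(path, grid = NULL) {
  dt <- data.table::fread(path, colClasses = list(character = c("device_id", "phase")))
  fixed <- c("time_s", "device_id", "repeat", "phase")
  derived <- c("total_per_L", "pm2_5_ugm3", "pm10_ugm3")
  missing <- setdiff(c(fixed, derived), names(dt))
  if (length(missing))
    stop("log schema mismatch, missing column(s): ",
         paste(missing, collapse = ", "))
  bins <- grep("^bin_[0-9]{3}$", names(dt), value = TRUE)
  if (!length(bins)) stop("log schema mismatch, missing column(s): bin_000 ...")
  expect <- sprintf("bin_%03d", seq_along(bins) - 1L)
  if (!identical(sort(bins), sort(expect)))
    stop("log schema mismatch: non-contiguous bin columns")
  if (!is.null(grid) && length(bins) != grid$n_bins)
    stop(sprintf("log has %d bins but grid has %d; refusing to coerce",
                 length(bins), grid$n_bins))
  data.table::setattr(dt, "n_bins", length(bins))
  dt
}

#' Replay a log as an ordered sequence of readings
#'
#' Reconstructs `spectrometer_reading` objects from a CSV log, validating
#' that timestamps are non-decreasing overall and strictly increasing per
#' device.
#'
#' @param path CSV log path.
#' @param grid Optional grid to validate bin count against.
#' @return List of `spectrometer_reading` objects in time order.
#' @export
replay_reader <- function(path, grid = NULL) {
  dt <- read_log(path, grid)
  if (nrow(dt) == 0L) return(list())
  if (is.unsorted(dt$time_s))
    stop("replay_reader: non-monotone timestamps in ", path)
  for (dev in unique(dt$device_id)) {
    tt <- dt$time_s[dt$device_id == dev]
    if (any(diff(tt) <= 0))
      stop(sprintf("replay_reader: non-increasing timestamps for device '%s'",
                   dev))
  }
  bins <- grep("^bin_[0-9]{3}$", names(dt), value = TRUE)
  lapply(seq_len(nrow(dt)), function(i) {
    structure(list(
      time_s = dt$time_s[i],
      device_id = dt$device_id[i],
      bins_per_L = as.numeric(dt[i, bins, with = FALSE]),
      total_per_L = dt$total_per_L[i],
      pm2_5_ugm3 = dt$pm2_5_ugm3[i],
      pm10_ugm3 = dt$pm10_ugm3[i],
      phase = dt$phase[i],
      repeat_index = as.integer(dt$`repeat`[i])
    ), class = "spectrometer_reading")
  })
}

#' Per-phase, per-repeat, per-sensor summary statistics
#'
#' Computes mean and standard deviation of PM2.5 and total particle counts
#' for every (phase, repeat, device) group of a run log, the statistics
#' routinely exported after an experiment for downstream analysis.
#'
#' @param x A `run_artifacts` object, a log path, or an in-memory log
#'   table (e.g. after [apply_calibration()]).
#' @param allow_partial Summarize an incomplete (aborted) run (default
#'   FALSE: refused).
#' @param report_path Optional path; if given, the summary is also written
#'   as a JSON report with an embedded schema version.
#' @return A `data.table` with one row per (phase, repeat, device):
#'   `n`, `pm2_5_mean`, `pm2_5_sd`, `total_mean`, `total_sd`.
#' @export
summarize_run <- function(x, allow_partial = FALSE, report_path = NULL) {
  if (inherits(x, "run_artifacts")) {
    if (!isTRUE(x$manifest$complete) && !allow_partial)
      stop("summarize_run: run is incomplete; pass allow_partial = TRUE ",
           "to summarize anyway")
    dt <- read_log(x$log_path)
  } else if (is.data.frame(x)) {
    dt <- data.table::as.data.table(x)
  } else {
    dt <- read_log(x)
  }
  pm2_5_ugm3 <- total_per_L <- phase <- device_id <- NULL # R CMD check NSE
  smry <- dt[, list(
    n = .N,
    pm2_5_mean = mean(pm2_5_ugm3), pm2_5_sd = stats::sd(pm2_5_ugm3),
    total_mean = mean(total_per_L), total_sd = stats::sd(total_per_L)),
    by = c("phase", "repeat", "device_id")]
  data.table::setorderv(smry, c("phase", "repeat", "device_id"))
  if (!is.null(report_path)) {
    jsonlite::write_json(list(schema_version = 1L, summary = smry),
                         report_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  smry[]
}
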