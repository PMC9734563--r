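#' Mask efficacy from paired concentrations
#'
#' The fraction of aerosol removed by a mask during inhalation, in percent:
#' \deqn{e = (1 - c_i / c_o) \times 100\%}
#' with \eqn{c_i} the concentration behind (inside) the mask and \eqn{c_o}
#' the ambient concentration outside it. Values above measurement (masked
#' exceeding ambient) give negative efficacies, which are reported, not
#' clamped: they signal a setup problem worth seeing.
#'
#' @param c_i Concentration inside/behind the mask.
#' @param c_o Ambient concentration outside the mask; must be > 0.
#' @return Efficacy in percent (vectorized).
#' @examples
#' efficacy(9.5, 100) # 90.5
#' @export
efficacy <- function(c_i, c_o) {
  if (any(c_o <= 0))
    stop("efficacy: undefined for c_o <= 0 (no ambient aerosol)")
  (1 - c_i / c_o) * 100
}

boot_indices <- function(n, n_boot, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
}

#' Windowed mask efficacy with bootstrap confidence interval
#'
#' Computes the efficacy from the windowed mean concentrations of two
#' time-aligned series (same ticks, calibration already applied) and a 95%
#' percentile-bootstrap confidence interval over paired ticks.
#'
#' @param masked,ambient Numeric vectors of aligned per-tick concentrations
#'   (PM2.5 or total counts); at least 10 paired ticks.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @param metric Label recorded in the result ("pm2_5" or "total").
#' @return An `efficacy_result`: list with `e_pct`, `ci` (low, high), `n`,
#'   `metric`.
#' @export
efficacy_series <- function(masked, ambient, n_boot = 2000, conf = 0.95,
                            seed = NULL, metric = "pm2_5") {
  if (length(masked) != length(ambient))
    stop("efficacy_series: series must be time-aligned (equal length)")
  n <- length(masked)
  if (n < 10L) stop("efficacy_series: need at least 10 paired ticks, got ", n)
  if (mean(ambient) <= 0) stop("efficacy: undefined for c_o <= 0 (no ambient aerosol)")
  e <- efficacy(mean(masked), mean(ambient))
  idx <- boot_indices(n, n_boot, seed)
  eb <- vapply(seq_len(n_boot), function(j) {
    i <- idx[, j]
    (1 - mean(masked[i]) / mean(ambient[i])) * 100
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(eb, c(alpha, 1 - alpha), names = FALSE))
  structure(list(e_pct = e, ci = ci, n = n, conf = conf, metric = metric),
            class = "efficacy_result")
}

#' @export
print.efficacy_result <- function(x, ...) {
  cat(sprintf("efficacy: %.2f%% (%.0f%% CI %.2f-%.2f, n = %d, %s)\n",
              x$e_pct, 100 * x$conf, x$ci[1], x$ci[2], x$n, x$metric))
  invisible(x)
}

#' Extract two aligned per-tick series from a run log
#'
#' Joins the rows of two devices on identical tick times, optionally
#' restricted to a phase comment and/or a time range, and returns the
#' chosen metric for each.
#'
#' @param log A `data.table` from [read_log()].
#' @param device_a,device_b Device ids.
#' @param metric "pm2_5" or "total".
#' @param phase Optional phase comment filter.
#' @param t_range Optional `c(t_min, t_max)` in seconds (inclusive).
#' @return A `data.table` with columns `time_s`, `a`, `b`.
#' @export
aligned_series <- function(log, device_a, device_b,
                           metric = c("pm2_5", "total"),
                           phase = NULL, t_range = NULL) {
  metric <- match.arg(metric)
  col <- if (metric == "pm2_5") "pm2_5_ugm3" else "total_per_L"
  sel <- data.table::as.data.table(log)
  keep <- rep(TRUE, nrow(sel))
  if (!is.null(phase)) keep <- keep & (sel$phase == phase)
  if (!is.null(t_range))
    keep <- keep & sel$time_s >= t_range[1] & sel$time_s <= t_range[2]
  ia <- which(keep & sel$device_id == device_a)
  ib <- which(keep & sel$device_id == device_b)
  a <- sel[ia, c("time_s", col), with = FALSE]
  b <- sel[ib, c("time_s", col), with = FALSE]
  data.table::setnames(a, col, "a")
  data.table::setnames(b, col, "b")
  merge(a, b, by = "time_s")
}

#' Median-ratio cross-calibration factors
#'
#' Real co-located instruments never read identically; before an
#' experiment, calibration factors are computed so that multiplying each
#' device's readings by its factor equalizes them with a chosen reference.
#' For device `d`, the factor is `median(reference) / median(d)` over the
#' first `n` time-aligned samples, with a paired-bootstrap confidence
#' interval. The reference's factor is exactly 1.
#'
#' @param series Named list of numeric vectors, one per device, aligned
#'   sample-by-sample (all unmasked and co-located), or a log `data.table`
#'   (then the chosen `metric` column is used per device).
#' @param reference Name/id of the reference device.
#' @param n Number of leading aligned samples to use (default 450).
#' @param metric For log input: "pm2_5" or "total".
#' @param n_boot,conf,seed Bootstrap parameters.
#' @return A `calibration_set`: data frame with `device`, `factor`,
#'   `ci_low`, `ci_high`, `n`; attribute `reference`.
#' @export
calibration_factors <- function(series, reference, n = 450,
                                metric = c("pm2_5", "total"),
                                n_boot = 2000, conf = 0.95, seed = NULL) {
  metric <- match.arg(metric)
  if (data.table::is.data.table(series) || is.data.frame(series)) {
    col <- if (metric == "pm2_5") "pm2_5_ugm3" else "total_per_L"
    dt <- data.table::as.data.table(series)
    devs <- unique(dt$device_id)
    series <- lapply(devs, function(d) dt[[col]][dt$device_id == d])
    names(series) <- devs
  }
  if (!(reference %in% names(series)))
    stop("calibration_factors: reference device '", reference, "' not present")
  len <- vapply(series, length, integer(1))
  if (any(len < n))
    stop(sprintf("calibration_factors: need >= %d samples per device (min %d)",
                 n, min(len)))
  series <- lapply(series, function(x) x[seq_len(n)])
  ref <- series[[reference]]
  m_ref <- stats::median(ref)
  if (m_ref == 0) stop("calibration_factors: reference median is zero")
  idx <- boot_indices(n, n_boot, seed)
  rows <- lapply(names(series), function(d) {
    x <- series[[d]]
    m <- stats::median(x)
    if (m == 0) stop("calibration_factors: median of device '", d, "' is zero")
    if (d == reference)
      return(data.frame(device = d, factor = 1, ci_low = 1, ci_high = 1, n = n))
    fb <- vapply(seq_len(n_boot), function(j) {
      i <- idx[, j]
      stats::median(ref[i]) / stats::median(x[i])
    }, numeric(1))
    alpha <- (1 - conf) / 2
    q <- stats::quantile(fb, c(alpha, 1 - alpha), names = FALSE)
    data.frame(device = d, factor = m_ref / m, ci_low = q[1], ci_high = q[2],
               n = n)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  class(out) <- c("calibration_set", class(out))
  out
}

#' Apply calibration factors to a run log
#'
#' Multiplies every count and PM field of each device's rows by that
#' device's factor. Factors are only ever applied to unmasked (ambient)
#' devices in practice, but the function applies whatever it is given.
#' A provenance attribute guards against double application.
#'
#' @param log A `data.table` from [read_log()].
#' @param cal A `calibration_set`; must cover every device in the log.
#' @return A calibrated copy of the log (attribute `calibrated = TRUE`).
#' @export
apply_calibration <- function(log, cal) {
  stopifnot(inherits(cal, "calibration_set"))
  if (isTRUE(attr(log, "calibrated")))
    stop("apply_calibration: log is already calibrated")
  out <- data.table::copy(data.table::as.data.table(log))
  devs <- unique(out$device_id)
  missing <- setdiff(devs, cal$device)
  if (length(missing))
    stop("apply_calibration: no factor for device(s): ",
         paste(missing, collapse = ", "))
  numcols <- c(grep("^bin_[0-9]{3}$", names(out), value = TRUE),
               "total_per_L", "pm2_5_ugm3", "pm10_ugm3")
  numcols <- intersect(numcols, names(out))
  for (d in devs) {
    f <- cal$factor[cal$device == d]
    if (f != 1) {
      i <- which(out$device_id == d)
      for (cc in numcols)
        data.table::set(out, i, cc, out[[cc]][i] * f)
    }
  }
  data.table::setattr(out, "calibrated", TRUE)
  out
}
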