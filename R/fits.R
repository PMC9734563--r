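#' Purifier decay model
#'
#' The aerosol mass concentration during air-purifier operation follows
#' \deqn{C(t) = a \cdot 10^{-b t} + c}
#' where `a + c` is the starting concentration, `1/b` (seconds) is the time
#' to reduce the removable component tenfold, and `c` is the lowest
#' concentration the room can reach. The laboratory reference fit is
#' `a = 100`, `b = 0.0035` (so `1/b` is about 286 s) and `c = 0.04` ug/m3.
#'
#' @param t Time in seconds since the purifier turned on.
#' @param a Removable concentration amplitude in ug/m3.
#' @param b Decadic decay rate per second.
#' @param c Background floor in ug/m3.
#' @return Concentration in ug/m3.
#' @examples
#' decay_model(1200) # ~0.046
#' @export
decay_model <- function(t, a = 100, b = 0.0035, c = 0.04) {
  a * 10^(-b * t) + c
}

#' Background rise model
#'
#' With the purifier (and everything else) off, the background mass
#' concentration rises approximately linearly for about half an hour:
#' `C(t) = intercept + slope * t`. The laboratory reference fit is
#' intercept 0.04 ug/m3 and slope 0.00015 ug/m3 per second.
#'
#' @param t Time in seconds since the purifier turned off.
#' @param intercept,slope Linear coefficients.
#' @return Concentration in ug/m3.
#' @export
rise_model <- function(t, intercept = 0.04, slope = 0.00015) {
  intercept + slope * t
}

#' Fit the exponential purifier-decay model
#'
#' Least-squares fit of `C(t) = a*10^(-b t) + c` on linear concentration.
#' Starting values follow a self-starting strategy: `c0` is the minimum
#' over the trailing `floor_window` seconds, `b0` comes from a log-linear
#' regression of `log10(C - c0)` against time, and `a0 = C(0) - c0`. The
#' decay rate is bounded below zero and the floor at zero; fitting is by
#' Levenberg-Marquardt. Non-convergence and non-identifiable (flat) input
#' are flagged on the result, never raised.
#'
#' @param time_s Sample times in seconds.
#' @param conc Concentrations (same length, >= 10 samples).
#' @param floor_window Trailing window in seconds used for `c0`
#'   (default 120).
#' @return A `decay_fit`: list with `a`, `b`, `c`, `t90` (= 1/b seconds),
#'   `residual_rms`, `converged`, and `fitted`.
#' @examples
#' t <- seq(6, 1200, by = 6)
#' f <- fit_decay(t, decay_model(t))
#' f$t90 # ~285.7
#' @export
fit_decay <- function(time_s, conc, floor_window = 120) {
  if (length(time_s) != length(conc)) stop("fit_decay: length mismatch")
  if (length(conc) < 10L) stop("fit_decay: need >= 10 samples of active decay")
  o <- order(time_s)
  time_s <- time_s[o]; conc <- conc[o]
  flag <- function(a, b, c) {
    structure(list(a = a, b = b, c = c,
                   t90 = if (is.finite(b) && b > 0) 1 / b else NA_real_,
                   residual_rms = NA_real_, converged = FALSE,
                   fitted = rep(NA_real_, length(conc))),
              class = "decay_fit")
  }
  if (stats::sd(conc) == 0 || diff(range(conc)) < 1e-12 * max(abs(conc), 1))
    return(flag(0, NA_real_, mean(conc))) # non-identifiable: no decay signal

  tail_i <- time_s >= max(time_s) - floor_window
  c0 <- min(conc[tail_i])
  excess <- conc - c0
  pos <- excess > 0
  b0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log10(excess[pos]) ~ time_s[pos]))[[2]]
    max(-sl, 1e-6)
  } else 1e-3
  a0 <- max(conc[1] - c0, 1e-12)

  fit <- tryCatch(
    minpack.lm::nlsLM(conc ~ a * 10^(-b * time_s) + c,
                      start = list(a = a0, b = b0, c = c0),
                      lower = c(a = 0, b = 1e-12, c = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(flag(a0, b0, c0))
  p <- stats::coef(fit)
  structure(list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
                 t90 = 1 / unname(p["b"]),
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 converged = TRUE,
                 fitted = stats::fitted(fit)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "decay_fit: C(t) = %.4g * 10^(-%.4g t) + %.4g  (1/b = %.1f s, rms %.3g)\n",
      x$a, x$b, x$c, x$t90, x$residual_rms))
  else
    cat("decay_fit: did not converge / non-identifiable\n")
  invisible(x)
}

#' Fit the linear background-rise model
#'
#' Ordinary least squares of concentration against time for a purifier-off,
#' source-off window. The linear approximation is only trusted for about
#' half an hour; a longer window is fitted anyway but noted on the result.
#'
#' @param time_s Sample times in seconds.
#' @param conc Concentrations.
#' @param max_window Longest window in seconds for which the linear model is
#'   considered valid (default 1800).
#' @return A `rise_fit`: list with `intercept`, `slope`, `residual_rms`,
#'   `window_s`, `warning` (NULL or text).
#' @export
fit_rise <- function(time_s, conc, max_window = 1800) {
  if (length(time_s) != length(conc)) stop("fit_rise: length mismatch")
  if (length(conc) < 2L) stop("fit_rise: need >= 2 samples")
  window <- diff(range(time_s))
  warn <- if (window > max_window)
    sprintf("window %.0f s exceeds the %.0f s linear-validity limit",
            window, max_window) else NULL
  fit <- stats::lm(conc ~ time_s)
  p <- stats::coef(fit)
  structure(list(intercept = unname(p[1]), slope = unname(p[2]),
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 window_s = window, warning = warn),
            class = "rise_fit")
}

#' @export
print.rise_fit <- function(x, ...) {
  cat(sprintf("rise_fit: C(t) = %.4g + %.4g t  (window %.0f s%s)\n",
              x$intercept, x$slope, x$window_s,
              if (is.null(x$warning)) "" else paste0("; ", x$warning)))
  invisible(x)
}
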