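#' Repetition statistics
#'
#' An experiment is repeated many times (typically at least 20) and the
#' mean concentration of each repetition is treated as one observation;
#' those per-repetition means are usually close to normally distributed.
#' This computes the per-repetition means, their grand mean, SD, a 95%
#' t-interval, and a Shapiro-Wilk normality statistic. Normality is
#' reported for information only and never gates the analysis.
#'
#' @param x Either a log `data.table` (from [read_log()]) or a numeric
#'   vector of per-repetition means.
#' @param phase,device For log input: phase comment and device id selecting
#'   the rows; every repetition present in the log must contain the phase.
#' @param metric For log input: "pm2_5" or "total".
#' @param conf Confidence level (default 0.95).
#' @return A `repetition_summary`: list with `rep_means`, `grand_mean`,
#'   `sd`, `ci`, `n`, `shapiro_W`, `shapiro_p`.
#' @export
summarize_repetitions <- function(x, phase = NULL, device = NULL,
                                  metric = c("pm2_5", "total"), conf = 0.95) {
  metric <- match.arg(metric)
  if (is.data.frame(x)) {
    if (is.null(phase) || is.null(device))
      stop("summarize_repetitions: phase and device are required for log input")
    col <- if (metric == "pm2_5") "pm2_5_ugm3" else "total_per_L"
    dt <- data.table::as.data.table(x)
    dt <- dt[dt$device_id == device & dt$`repeat` > 0L, ]
    reps <- sort(unique(dt$`repeat`))
    means <- vapply(reps, function(r) {
      v <- dt[[col]][dt$`repeat` == r & dt$phase == phase]
      if (!length(v))
        stop(sprintf("summarize_repetitions: repetition %d has no phase '%s'",
                     r, phase))
      mean(v)
    }, numeric(1))
  } else {
    means <- as.numeric(x)
  }
  n <- length(means)
  if (n < 2L) stop("summarize_repetitions: need >= 2 repetitions")
  gm <- mean(means)
  s <- stats::sd(means)
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
  sw <- if (s > 0) tryCatch(stats::shapiro.test(means),
                            error = function(e) NULL) else NULL
  structure(list(rep_means = means, grand_mean = gm, sd = s,
                 ci = c(gm - half, gm + half), n = n, conf = conf,
                 shapiro_W = if (is.null(sw)) NA_real_ else unname(sw$statistic),
                 shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value),
            class = "repetition_summary")
}

#' @export
print.repetition_summary <- function(x, ...) {
  cat(sprintf("repetitions: n = %d, mean %.4g (SD %.3g, %.0f%% CI %.4g-%.4g)\n",
              x$n, x$grand_mean, x$sd, 100 * x$conf, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Concentration-stratified mask efficacy
#'
#' Bins the paired ticks by ambient concentration and estimates the
#' efficacy (with bootstrap CI) separately within each bin — the check that
#' a mask's measured efficacy does not depend on the surrounding aerosol
#' concentration, which justifies measuring at high concentrations for
#' signal-to-noise. Bins with fewer than `min_n` paired ticks are omitted
#' from the output (absent, not zero).
#'
#' @param masked,ambient Aligned per-tick concentration vectors.
#' @param bin_edges Increasing vector of ambient-concentration bin edges.
#' @param min_n Minimum paired ticks per reported bin (default 100).
#' @param n_boot,conf,seed Bootstrap parameters per bin.
#' @return A data frame with one row per populated bin: `bin_low`,
#'   `bin_high`, `n`, `e_pct`, `ci_low`, `ci_high`.
#' @export
efficacy_by_concentration <- function(masked, ambient, bin_edges,
                                      min_n = 100, n_boot = 2000,
                                      conf = 0.95, seed = NULL) {
  if (length(masked) != length(ambient))
    stop("efficacy_by_concentration: series must be aligned")
  if (any(diff(bin_edges) <= 0))
    stop("efficacy_by_concentration: bin_edges must be increasing")
  if (!is.null(seed)) set.seed(as.integer(seed))
  bin <- cut(ambient, bin_edges, include.lowest = TRUE)
  rows <- lapply(which(tabulate(bin, nbins = nlevels(bin)) >= max(min_n, 10L)),
                 function(k) {
    i <- which(as.integer(bin) == k)
    er <- efficacy_series(masked[i], ambient[i], n_boot = n_boot, conf = conf)
    data.frame(bin_low = bin_edges[k], bin_high = bin_edges[k + 1],
               n = length(i), e_pct = er$e_pct,
               ci_low = er$ci[1], ci_high = er$ci[2])
  })
  if (!length(rows))
    return(data.frame(bin_low = numeric(0), bin_high = numeric(0),
                      n = integer(0), e_pct = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0)))
  do.call(rbind, rows)
}

# Wilcoxon signed-rank with the Pratt convention for zero differences:
# zeros are included when ranking |d| but their ranks are dropped from the
# statistic; mean and variance are adjusted accordingly (normal
# approximation with tie correction).
wilcoxon_pratt <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  z0 <- sum(d == 0)
  w_plus <- sum(r[d > 0])
  mu <- (n * (n + 1) - z0 * (z0 + 1)) / 4
  ties <- table(r[d != 0]) # zero group handled by the z0 terms
  v <- (n * (n + 1) * (2 * n + 1) - z0 * (z0 + 1) * (2 * z0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (v <= 0) return(list(statistic = w_plus, z = 0, p_value = 1))
  z <- (w_plus - mu) / sqrt(v)
  list(statistic = w_plus, z = z, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Compare two measurement conditions
#'
#' Nonparametric comparison of per-repetition means measured under two
#' conditions (for example fan on vs fan off): a Wilcoxon signed-rank test
#' on the paired differences (Pratt convention — zero differences are
#' ranked but excluded from the statistic) and a Kruskal-Wallis test on the
#' pooled groups. Both p-values are reported without any significance
#' gating; the decision is the user's.
#'
#' @param a,b Numeric vectors of per-repetition means (>= 5 each; equal
#'   length when `paired`).
#' @param paired Treat the arms as paired (default TRUE).
#' @return A `condition_comparison`: list with `wilcoxon`
#'   (statistic, z, p_value; NULL when unpaired), `kruskal` (statistic, df,
#'   p_value), `n`.
#' @export
compare_conditions <- function(a, b, paired = TRUE) {
  if (length(a) < 5L || length(b) < 5L)
    stop("compare_conditions: need at least 5 repetitions per arm")
  if (paired && length(a) != length(b))
    stop("compare_conditions: paired arms must have equal length")
  wil <- if (paired) wilcoxon_pratt(a - b) else NULL
  kw <- stats::kruskal.test(list(a, b))
  structure(list(
    wilcoxon = wil,
    kruskal = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p_value = kw$p.value),
    n = c(length(a), length(b))),
    class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  if (!is.null(x$wilcoxon))
    cat(sprintf("Wilcoxon signed-rank (Pratt): V = %g, p = %.4g\n",
                x$wilcoxon$statistic, x$wilcoxon$p_value))
  cat(sprintf("Kruskal-Wallis: chi2 = %.4g (df %g), p = %.4g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p_value))
  invisible(x)
}

#' Aerosol-intake reduction between two distances
#'
#' Quantifies how much less aerosol a receiver inhales farther from the
#' emitter under the same mask condition: the percentage reduction
#' `(1 - mean_far / mean_near) * 100`, with a t-interval over the
#' per-repetition reductions (the repetitions are paired).
#'
#' @param near,far Numeric vectors of per-repetition mean concentrations at
#'   the near and far position (equal length, paired by repetition).
#' @param conf Confidence level (default 0.95).
#' @return A list with `reduction_pct`, `ci`, `n`.
#' @export
distance_reduction <- function(near, far, conf = 0.95) {
  if (length(near) != length(far))
    stop("distance_reduction: repetitions must be paired")
  if (mean(near) <= 0) stop("distance_reduction: mean near concentration <= 0")
  if (any(near <= 0)) stop("distance_reduction: non-positive near repetition mean")
  point <- (1 - mean(far) / mean(near)) * 100
  per_rep <- (1 - far / near) * 100
  n <- length(per_rep)
  s <- stats::sd(per_rep)
  half <- if (n >= 2 && s > 0) stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
          else 0
  m <- mean(per_rep)
  list(reduction_pct = point, ci = c(m - half, m + half), n = n)
}
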