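test_that("efficacy follows (1 - c_i/c_o) * 100 and is scale invariant", {
  expect_equal(efficacy(100, 100), 0)
  expect_equal(efficacy(0, 100), 100)
  expect_equal(efficacy(9.5, 100), 90.5)
  expect_equal(efficacy(150, 100), -50) # negative values surfaced, not clamped
  expect_error(efficacy(1, 0), "c_o")
  set.seed(2)
  for (i in 1:20) {
    ci <- stats::runif(1, 0, 200); co <- stats::runif(1, 1, 200)
    k <- stats::runif(1, 0.01, 100)
    expect_equal(efficacy(k * ci, k * co), efficacy(ci, co))
  }
})

test_that("efficacy_series is exact on constant ratios with zero CI width", {
  ambient <- stats::runif(50, 50, 150)
  r <- efficacy_series(0.3 * ambient, ambient, seed = 1)
  expect_equal(r$e_pct, 70)
  expect_equal(r$ci, c(70, 70))
  expect_equal(r$n, 50L)

  r0 <- efficacy_series(ambient, ambient, seed = 1)
  expect_equal(r0$e_pct, 0)

  expect_error(efficacy_series(1:5, 1:5), "10 paired ticks")
  expect_error(efficacy_series(1:10, 1:9), "aligned")
})

test_that("a simulated 90% mask is recovered within one point", {
  g <- default_bin_grid()
  bk <- static_backend(ids = c("masked", "bare"),
                       mixed_per_L = sample_size_fractions(aerosol_source(), g) * 1e6,
                       masks = list(masked = mask_model(90, spread_sd_pct = 0)),
                       noise = TRUE, seed = 7)
  s <- sample_readings(bk, 1000)
  r <- efficacy_series(s$masked, s$bare, seed = 7, metric = "total")
  expect_lt(abs(r$e_pct - 90), 1)
  expect_true(r$ci[1] <= r$e_pct && r$e_pct <= r$ci[2])
})

test_that("calibration factors are median ratios with exact reference unity", {
  s <- list(ref = rep(12, 500), dev = rep(10, 500))
  cal <- calibration_factors(s, "ref", n = 450, seed = 1)
  expect_equal(cal$factor[cal$device == "dev"], 1.2)
  expect_equal(cal$factor[cal$device == "ref"], 1)
  expect_identical(attr(cal, "reference"), "ref")

  self <- calibration_factors(list(a = rnorm(500, 10)), "a", n = 450, seed = 1)
  expect_identical(self$factor, 1)

  expect_error(calibration_factors(list(a = rep(0, 500), b = rep(1, 500)),
                                   "b", n = 450, seed = 1), "median")
  expect_error(calibration_factors(s, "other", n = 450), "reference")
  expect_error(calibration_factors(list(a = 1:10, b = 1:10), "a", n = 450),
               "samples")
})

test_that("calibration closure: factors invert and equalize medians", {
  set.seed(3)
  g <- default_bin_grid()
  bk <- static_backend(ids = c("LAS-1", "LAS-2"),
                       mixed_per_L = sample_size_fractions(aerosol_source(), g) * 1e6,
                       biases = c(`LAS-1` = 0.94, `LAS-2` = 1.00),
                       noise = TRUE, seed = 3)
  s <- sample_readings(bk, 450)
  f12 <- calibration_factors(s, "LAS-1", n = 450, seed = 3)
  f21 <- calibration_factors(s, "LAS-2", n = 450, seed = 3)
  fAB <- f12$factor[f12$device == "LAS-2"]
  fBA <- f21$factor[f21$device == "LAS-1"]
  expect_equal(fAB * fBA, 1, tolerance = 1e-12)

  # recover the simulated bias ratio ~1/0.94 within about 1%
  expect_equal(fBA, 1 / 0.94, tolerance = 0.015)

  # applying the factors equalizes co-located medians to < 0.1%
  corrected <- s$`LAS-1` * fBA
  expect_lt(abs(median(corrected) / median(s$`LAS-2`) - 1), 1e-3)
})

test_that("apply_calibration scales all count fields once and only once", {
  dir <- withr::local_tempdir()
  bk <- static_backend(ids = c("A", "B"), noise = FALSE)
  cfg <- experiment_config("cal", protocol = list(protocol_step(1, "PAUSE")))
  art <- acquire(expand_schedule(cfg), bk, file.path(dir, "cal.csv"))
  log <- read_log(art$log_path)

  cal <- calibration_factors(list(A = rep(10, 450), B = rep(12, 450)), "B",
                             n = 450, seed = 1)
  out <- apply_calibration(log, cal)
  iA <- out$device_id == "A"
  expect_equal(out$pm2_5_ugm3[iA], log$pm2_5_ugm3[iA] * 1.2)
  expect_equal(out$total_per_L[iA], log$total_per_L[iA] * 1.2)
  expect_equal(out$bin_000[iA], log$bin_000[iA] * 1.2)
  expect_equal(out$total_per_L[!iA], log$total_per_L[!iA]) # reference untouched
  expect_error(apply_calibration(out, cal), "already calibrated")

  unity <- calibration_factors(list(A = rep(5, 450), B = rep(5, 450)), "B",
                               n = 450, seed = 1)
  same <- apply_calibration(log, unity)
  expect_equal(same$total_per_L, log$total_per_L)

  log2 <- data.table::copy(log)
  log2$device_id[1] <- "C"
  expect_error(apply_calibration(log2, cal), "C")
})

test_that("fit_decay inverts the decay model exactly on noise-free data", {
  tt <- seq(6, 1200, by = 6)
  f <- fit_decay(tt, decay_model(tt, a = 100, b = 0.0035, c = 0.04))
  expect_true(f$converged)
  expect_equal(f$a, 100, tolerance = 1e-6)
  expect_equal(f$b, 0.0035, tolerance = 1e-6)
  expect_equal(f$c, 0.04, tolerance = 1e-6)
  expect_equal(f$t90, 1 / 0.0035, tolerance = 1e-6)
  expect_equal(f$t90, f$b^-1)

  flat <- fit_decay(tt, rep(5, length(tt)))
  expect_false(flat$converged)
  expect_equal(flat$a, 0)
})

test_that("fit_decay recovers the rate from 1% multiplicative noise", {
  set.seed(11)
  tt <- seq(6, 1200, by = 6)
  y <- decay_model(tt) * (1 + rnorm(length(tt), 0, 0.01))
  f <- fit_decay(tt, y)
  expect_true(f$converged)
  expect_lt(abs(f$b - 0.0035) / 0.0035, 0.05)
})

test_that("fit_rise recovers the linear background model", {
  tt <- seq(0, 1800, by = 6)
  f <- fit_rise(tt, rise_model(tt))
  expect_equal(f$intercept, 0.04, tolerance = 1e-10)
  expect_equal(f$slope, 0.00015, tolerance = 1e-10)
  expect_null(f$warning)

  const <- fit_rise(tt, rep(2, length(tt)))
  expect_equal(const$slope, 0)

  set.seed(5)
  y <- rise_model(tt) * (1 + rnorm(length(tt), 0, 0.01))
  fn <- fit_rise(tt, y)
  expect_lt(abs(fn$slope - 0.00015) / 0.00015, 0.05)

  long <- fit_rise(seq(0, 3600, 6), rise_model(seq(0, 3600, 6)))
  expect_match(long$warning, "exceeds")
})

test_that("repetition summaries match hand arithmetic", {
  s <- summarize_repetitions(c(1, 2, 3))
  expect_equal(s$grand_mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)
  expect_equal(mean(s$ci), 2)

  same <- summarize_repetitions(rep(5, 20))
  expect_equal(same$sd, 0)
  expect_equal(same$ci, c(5, 5))

  expect_error(summarize_repetitions(1), "2 repetitions")

  set.seed(17)
  s20 <- summarize_repetitions(rnorm(20, 10))
  expect_true(is.finite(s20$shapiro_W))
  expect_true(is.finite(s20$shapiro_p)) # reported, never gating
})

test_that("repetition summaries from a log demand every phase per repeat", {
  dir <- withr::local_tempdir()
  bk <- static_backend(ids = "LAS-0", noise = TRUE, seed = 4)
  cfg <- experiment_config("reps", repeats = 3L, seed = 4,
                           protocol = list(protocol_step(1, "AEROSOL", "during"),
                                           protocol_step(1, "PAUSE", "pause")))
  art <- acquire(expand_schedule(cfg), bk, file.path(dir, "reps.csv"))
  log <- read_log(art$log_path)
  s <- summarize_repetitions(log, phase = "during", device = "LAS-0",
                             metric = "total")
  expect_equal(s$n, 3L)
  expect_error(summarize_repetitions(log, phase = "missing", device = "LAS-0"),
               "repetition 1")
})

test_that("stratified efficacy is flat for concentration-independent masks", {
  ambient <- stats::runif(400, 10, 1000)
  masked <- 0.25 * ambient
  out <- efficacy_by_concentration(masked, ambient, c(0, 100, 500, 1000),
                                   min_n = 50, seed = 1)
  expect_equal(out$e_pct, rep(75, nrow(out)))
  expect_gt(nrow(out), 1)

  # under-populated bins are absent, not zero
  out2 <- efficacy_by_concentration(masked, ambient, c(0, 100, 500, 1000, 1e6),
                                    min_n = 50, seed = 1)
  expect_false(any(out2$bin_low == 1000))
})

test_that("stratified efficacy of a simulated mask varies < 2 points", {
  # ambient sweeps 1e3..1e6 /L; Poisson counting noise in a 0.12 L sample
  set.seed(21)
  vol <- 0.12
  ambient_true <- 10^seq(3, 6, length.out = 600)
  ambient <- rpois(600, ambient_true * vol) / vol
  masked <- rpois(600, 0.10 * ambient_true * vol) / vol
  keep <- ambient > 0
  out <- efficacy_by_concentration(masked[keep], ambient[keep],
                                   bin_edges = 10^seq(3, 6, by = 1),
                                   min_n = 100, seed = 21)
  expect_gte(nrow(out), 2)
  expect_lt(max(out$e_pct) - min(out$e_pct), 2)
})

test_that("condition comparison handles ties per Pratt and matches the
           library normal approximation on zero-free data", {
  a <- c(5, 6, 7, 8, 9, 10)
  same <- compare_conditions(a, a)
  expect_equal(same$wilcoxon$p_value, 1)
  expect_gt(same$kruskal$p_value, 0.9)

  set.seed(9)
  x <- rnorm(22); y <- x + rnorm(22, 0, 1e-3) + 5
  cc <- compare_conditions(x, y)
  expect_lt(cc$wilcoxon$p_value, 1e-3)
  oracle <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                               correct = FALSE)
  expect_equal(cc$wilcoxon$p_value, oracle$p.value, tolerance = 1e-10)

  expect_error(compare_conditions(1:3, 1:3), "5 repetitions")
  expect_error(compare_conditions(1:6, 1:5), "equal length")
})

test_that("same-distribution arms rarely reject at the 5% level", {
  rejections <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    a <- rnorm(22, 10); b <- rnorm(22, 10)
    if (compare_conditions(a, b)$wilcoxon$p_value <= 0.05)
      rejections <- rejections + 1L
  }
  expect_lte(rejections, 10L)
})

test_that("distance reduction reproduces the paired-ratio definition", {
  near <- c(10, 12, 11, 9, 10.5)
  expect_equal(distance_reduction(near, near)$reduction_pct, 0)
  r <- distance_reduction(near, 0.766 * near)
  expect_equal(r$reduction_pct, 23.4)
  expect_equal(r$ci, c(23.4, 23.4))
  expect_error(distance_reduction(c(0, 0, 0, 0, 0), near), "near")
  expect_error(distance_reduction(near, near[-1]), "paired")
})

test_that("uncorrected ambient bias vanishes as efficacy approaches 100%", {
  # ambient instrument reads beta * c_o; the efficacy error is
  # (1 - e/100) * (1/beta - 1) * 100, shrinking to 0 as e -> 100
  beta <- 0.94
  g <- default_bin_grid()
  errs <- vapply(c(0, 50, 90, 99), function(e) {
    bk <- static_backend(ids = c("masked", "bare"),
                         mixed_per_L = sample_size_fractions(aerosol_source(), g) * 1e6,
                         masks = list(masked = mask_model(e, spread_sd_pct = 0)),
                         biases = c(masked = 1, bare = beta),
                         noise = TRUE, seed = 31)
    s <- sample_readings(bk, 300)
    abs(efficacy(mean(s$masked), mean(s$bare)) - e)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  analytic <- (1 - c(0, 50, 90, 99) / 100) * (1 / beta - 1) * 100
  expect_lt(max(abs(errs - analytic)), 0.2)
  expect_lt(errs[4], 0.2)
})
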