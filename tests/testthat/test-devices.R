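test_that("default grid spans 0.25-35 um with an edge at the 2.53 cutoff", {
  g <- default_bin_grid()
  expect_length(g$edges, 31L)
  expect_equal(g$edges[1], 0.25)
  expect_equal(g$edges[31], 35)
  expect_true(2.53 %in% g$edges)
  expect_true(all(diff(g$edges) > 0))
  expect_equal(g$d_rep, sqrt(g$lower * g$upper))
})

test_that("size fractions peak at the mode bin and honour truncation", {
  g <- default_bin_grid()
  src <- aerosol_source()
  f <- sample_size_fractions(src, g)
  expect_equal(sum(f), 1)
  expect_true(all(f >= 0))
  # number-distribution peak in the bin containing the 0.25 um mode
  expect_equal(which.max(f), 1L)
  # bins entirely above the truncation diameter carry exactly zero
  expect_true(all(f[g$lower >= src$truncation_um] == 0))

  single <- size_bin_grid(c(0.25, 35))
  expect_equal(sample_size_fractions(src, single), 1)

  off_grid <- size_bin_grid(c(1, 2, 35))
  expect_error(sample_size_fractions(src, off_grid), "mode")
})

test_that("pm_from_bins matches the spherical-mass hand calculation", {
  # independent oracle: N/L * 1000/m3 * (pi/6) d^3 [m^3] * rho [kg/m3] in ug
  d_m <- 1e-6; rho <- 914
  expected <- 1000 * 1000 * (pi / 6) * d_m^3 * rho * 1e9
  g1 <- size_bin_grid(c(0.9, 1 / 0.9)) # geometric mean exactly 1.0 um
  expect_equal(pm_from_bins(1000, g1, density = 0.914), expected,
               tolerance = 1e-12)
  expect_equal(pm_from_bins(0, g1), 0)
  expect_error(pm_from_bins(c(1, 2), g1), "bins")
})

test_that("PM cutoff semantics: coarse-only aerosol has PM2.5 = 0 < PM10", {
  g <- default_bin_grid()
  counts <- numeric(g$n_bins)
  counts[g$d_rep > 2.53 & g$d_rep <= 10] <- 100
  expect_equal(pm_from_bins(counts, g, cutoff = 2.53), 0)
  expect_gt(pm_from_bins(counts, g, cutoff = 10), 0)
})

test_that("PM is monotone in counts and PM2.5 <= PM10 always", {
  g <- default_bin_grid()
  set.seed(7)
  for (i in 1:25) {
    counts <- stats::rpois(g$n_bins, 50)
    pm25 <- pm_from_bins(counts, g, cutoff = 2.53)
    pm10 <- pm_from_bins(counts, g, cutoff = 10)
    expect_lte(pm25, pm10)
    bump <- counts
    j <- sample.int(g$n_bins, 1)
    bump[j] <- bump[j] + 10
    expect_gte(pm_from_bins(bump, g, cutoff = 2.53), pm25)
    expect_gte(pm_from_bins(bump, g, cutoff = 10), pm10)
  }
})

test_that("idle room only accumulates linear background rise", {
  g <- default_bin_grid(); src <- aerosol_source(); room <- tiny_room()
  st <- room_state(room, src, g, mixed_per_L = sample_size_fractions(src, g) * 1e4)
  before <- st
  off <- c(generator = FALSE, purifier = FALSE, fan = FALSE)
  st2 <- step_room(st, off, 60, room, src, g)
  expect_equal(st2$mixed, before$mixed)
  expect_equal(st2$sensor, before$sensor)
  expect_equal(st2$background_ugm3,
               before$background_ugm3 + room$rise_slope * 60)
  # conservation: total particle count constant with sources and purifier off
  expect_equal(sum(st2$mixed), sum(before$mixed))
})

test_that("purifier decay reproduces the closed form to 1e-9 relative", {
  g <- default_bin_grid(); src <- aerosol_source(); room <- tiny_room()
  st <- room_state(room, src, g, background_ugm3 = 100.04)
  on <- c(generator = FALSE, purifier = TRUE, fan = FALSE)
  ticks <- seq(6, 1200, by = 6)
  got <- numeric(length(ticks))
  for (k in seq_along(ticks)) {
    st <- step_room(st, on, 6, room, src, g)
    got[k] <- st$background_ugm3
  }
  want <- 100 * 10^(-room$decay_b * ticks) + room$floor_ugm3
  expect_lt(max(abs(got - want) / want), 1e-9)
  # spot value from direct evaluation near the tenfold-reduction time
  expect_equal(got[ticks == 282], 100 * 10^(-0.0035 * 282) + 0.04)
})

test_that("plume onset at 1 m is delayed about three minutes, halved by fan", {
  g <- default_bin_grid(); src <- aerosol_source()
  for (fan in c(FALSE, TRUE)) {
    room <- tiny_room(ids = "LAS-0", distance_m = 1)
    st <- room_state(room, src, g)
    dev <- c(generator = TRUE, purifier = FALSE, fan = fan)
    onset <- NA
    for (k in 1:100) {
      st <- step_room(st, dev, 6, room, src, g)
      if (is.na(onset) && sum(st$sensor[1, ]) > 1e-6 * sum(st$mixed)) {
        onset <- st$time_s; break
      }
    }
    expected_delay <- 180 * (if (fan) room$fan_delay_factor else 1)
    expect_gte(onset, expected_delay)
    expect_lte(onset, expected_delay + 18)
  }
})

test_that("after the generator stops the sensor peaks and then holds", {
  g <- default_bin_grid(); src <- aerosol_source()
  room <- tiny_room(ids = "LAS-0", distance_m = 1)
  st <- room_state(room, src, g)
  gen <- c(generator = TRUE, purifier = FALSE, fan = FALSE)
  off <- c(generator = FALSE, purifier = FALSE, fan = FALSE)
  for (k in 1:100) st <- step_room(st, gen, 6, room, src, g)   # 600 s on
  at_stop <- sum(st$sensor[1, ])
  for (k in 1:100) st <- step_room(st, off, 6, room, src, g)   # 600 s off
  after <- sum(st$sensor[1, ])
  expect_gt(after, at_stop) # keeps rising toward the delayed peak
  st2 <- step_room(st, off, 600, room, src, g)
  expect_equal(sum(st2$sensor[1, ]), after, tolerance = 1e-3) # then holds
})

test_that("spectrometer readings apply mask, bias and noise as specified", {
  g <- default_bin_grid(); src <- aerosol_source()
  room <- tiny_room(ids = "LAS-0")
  ambient <- sample_size_fractions(src, g) * 1e6
  st <- room_state(room, src, g, background_ugm3 = 0, mixed_per_L = ambient)

  # full attenuation: realized efficacy 100 zeroes every channel
  perfect <- mask_model(100, spread_sd_pct = 0)
  m <- spectrometer_model("LAS-0", bias = 1, mask = perfect)
  r <- read_spectrometer(m, st, g, noise = FALSE)
  expect_equal(r$total_per_L, 0)
  expect_equal(r$pm2_5_ugm3, 0)

  # identity: no mask, unit bias, noise off
  m0 <- spectrometer_model("LAS-0", bias = 1)
  r0 <- read_spectrometer(m0, st, g, noise = FALSE)
  expect_equal(r0$bins_per_L, unname(ambient))
  expect_equal(r0$total_per_L, sum(ambient))
  expect_equal(r0$total_per_L, 1e6, tolerance = 1e-12)

  # a 6% low-reading instrument reports 940,000 of 1,000,000 per litre
  m94 <- spectrometer_model("LAS-0", bias = 0.94)
  r94 <- read_spectrometer(m94, st, g, noise = FALSE)
  expect_equal(r94$total_per_L, 940000, tolerance = 1e-12)

  expect_error(read_spectrometer(spectrometer_model("nope"), st, g),
               "unknown device")

  # reading invariants
  set.seed(5)
  rn <- read_spectrometer(m0, st, g, noise = TRUE)
  expect_true(all(rn$bins_per_L >= 0))
  expect_equal(rn$total_per_L, sum(rn$bins_per_L))
  expect_lte(rn$pm2_5_ugm3, rn$pm10_ugm3)
})

test_that("donning variation spans about +/-10 points at the default spread", {
  m <- mask_model(90, spread_sd_pct = 0)
  expect_equal(realized_efficacy(don_mask(m)), 90)

  m95 <- mask_model(95, spread_sd_pct = 5)
  m95$donned_offset_pct <- 50
  expect_equal(realized_efficacy(m95), 100) # clamped

  set.seed(123)
  m90 <- mask_model(90, spread_sd_pct = 5)
  realized <- replicate(20, realized_efficacy(don_mask(m90)))
  spread <- max(abs(realized - 90))
  expect_gte(spread, 5)   # 20 draws from N(0, 5) reach well past 1 SD
  expect_lte(spread, 16)  # ... but stay within ~3 SD
})

test_that("co-located biased sensors produce the bias ratio of medians", {
  g <- default_bin_grid()
  bk <- static_backend(ids = c("A", "B"), biases = c(A = 0.94, B = 1.02),
                       noise = FALSE)
  r <- backend_read(bk)
  expect_equal(r[["B"]]$total_per_L / r[["A"]]$total_per_L, 1.02 / 0.94,
               tolerance = 1e-12)
})

test_that("stochastic backends demand a seed", {
  room <- tiny_room(); src <- aerosol_source(); g <- default_bin_grid()
  expect_error(sim_backend(room, src, g, noise = TRUE, seed = NULL), "seed")
  expect_error(sim_backend(room, src, g, noise = FALSE, biases = "random"),
               "seed")
  expect_silent(sim_backend(room, src, g, noise = FALSE,
                            biases = unit_biases(room$sensors$id)))
})
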