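#' Room specification for the virtual aerosol laboratory
#'
#' Parameterizes the well-mixed room model: volume, purifier decay rate,
#' background behaviour, sensor placement and plume transport delays.
#'
#' The purifier removes the above-background aerosol exponentially with
#' decadic rate `decay_b` (concentration component multiplied by
#' `10^(-decay_b * t)`), so `1/decay_b` seconds reduce it tenfold. With the
#' purifier off the background mass concentration rises linearly at
#' `rise_slope` from the achievable floor. Freshly emitted aerosol reaches a
#' sensor at distance `d` only after a transport delay
#' `tau(d) = delay_s_per_m * d`, halved (by default) when the fan blows the
#' plume across the room; after onset the sensor concentration relaxes
#' toward the well-mixed level with time constant `mixing_tau_s`.
#'
#' @param volume_m3 Room volume in cubic metres (default 27, a 3x3x3 m lab).
#' @param decay_b Decadic purifier decay rate per second (default 0.0035).
#' @param floor_ugm3 Lowest achievable background PM2.5 in ug/m3
#'   (default 0.04).
#' @param rise_slope Background PM2.5 rise in ug/m3 per second with the
#'   purifier off (default 0.00015).
#' @param sensors Data frame with columns `id` (character) and `distance_m`
#'   (> 0), one row per spectrometer position.
#' @param delay_s_per_m Plume onset delay per metre of sensor distance
#'   (default 180 s/m, i.e. about three minutes at one metre).
#' @param fan_delay_factor Multiplier applied to the delay while the fan is
#'   on (default 0.5).
#' @param mixing_tau_s Relaxation time constant toward the well-mixed level
#'   in seconds (default 60).
#' @return An object of class `room_spec`.
#' @export
room_spec <- function(volume_m3 = 27, decay_b = 0.0035, floor_ugm3 = 0.04,
                      rise_slope = 0.00015,
                      sensors = data.frame(id = "LAS-0", distance_m = 1),
                      delay_s_per_m = 180, fan_delay_factor = 0.5,
                      mixing_tau_s = 60) {
  volume_m3 <- as.numeric(volume_m3); decay_b <- as.numeric(decay_b)
  floor_ugm3 <- as.numeric(floor_ugm3); rise_slope <- as.numeric(rise_slope)
  delay_s_per_m <- as.numeric(delay_s_per_m)
  fan_delay_factor <- as.numeric(fan_delay_factor)
  mixing_tau_s <- as.numeric(mixing_tau_s)
  if (volume_m3 <= 0) stop("room_spec: volume_m3 must be > 0")
  if (decay_b <= 0) stop("room_spec: decay_b must be > 0")
  if (floor_ugm3 < 0) stop("room_spec: floor_ugm3 must be >= 0")
  if (rise_slope < 0) stop("room_spec: rise_slope must be >= 0")
  sensors <- as.data.frame(sensors)
  if (!all(c("id", "distance_m") %in% names(sensors)))
    stop("room_spec: sensors needs columns id, distance_m")
  if (anyDuplicated(sensors$id)) stop("room_spec: duplicate sensor ids")
  if (any(sensors$distance_m <= 0)) stop("room_spec: distances must be > 0")
  sensors$id <- as.character(sensors$id)
  structure(list(volume_m3 = volume_m3, decay_b = decay_b,
                 floor_ugm3 = floor_ugm3, rise_slope = rise_slope,
                 sensors = sensors, delay_s_per_m = delay_s_per_m,
                 fan_delay_factor = fan_delay_factor,
                 mixing_tau_s = mixing_tau_s),
            class = "room_spec")
}

#' Initial state of the virtual room
#'
#' Creates the mutable state advanced by [step_room()]: the well-mixed
#' per-bin plume concentration, per-sensor plume concentrations, the scalar
#' background mass concentration, and a short history of the well-mixed
#' level used for transport-delay lookups.
#'
#' @param room A [room_spec()].
#' @param source An [aerosol_source()] (fixes the background size spectrum).
#' @param grid A [size_bin_grid()].
#' @param background_ugm3 Initial background PM2.5 (default: the room floor).
#' @param mixed_per_L Optional initial well-mixed per-bin plume counts/L
#'   (default all zero); sensors start equilibrated at this level.
#' @param density Particle density g/cm3 for mass conversions.
#' @param cutoff PM2.5-style cutoff diameter in um.
#' @return An object of class `room_state`.
#' @export
room_state <- function(room, source, grid, background_ugm3 = room$floor_ugm3,
                       mixed_per_L = NULL, density = 0.914, cutoff = 2.53) {
  stopifnot(inherits(room, "room_spec"), inherits(source, "aerosol_source"),
            inherits(grid, "size_bin_grid"))
  frac <- sample_size_fractions(source, grid)
  unit_pm <- pm_from_bins(frac, grid, density = density, cutoff = cutoff)
  if (is.null(mixed_per_L)) mixed_per_L <- numeric(grid$n_bins)
  if (length(mixed_per_L) != grid$n_bins)
    stop("room_state: mixed_per_L length must match grid")
  n_s <- nrow(room$sensors)
  sensor <- matrix(rep(mixed_per_L, each = n_s), nrow = n_s,
                   dimnames = list(room$sensors$id, NULL))
  structure(list(
    time_s = 0,
    background_ugm3 = background_ugm3,
    mixed = mixed_per_L,
    sensor = sensor,
    frac = frac,
    bg_unit = frac / unit_pm,    # counts/L per ug/m3 of background
    density = density, cutoff = cutoff,
    last_gen_on_s = -Inf,
    hist_t = 0,
    hist_m = matrix(mixed_per_L, nrow = 1)
  ), class = "room_state")
}

delayed_mixed <- function(state, t_query) {
  i <- findInterval(t_query, state$hist_t)
  if (i < 1L) return(state$hist_m[1L, ])
  state$hist_m[i, ]
}

#' Advance the virtual room by one time step
#'
#' Applies, in order: purifier decay (or background rise), aerosol emission
#' into the well-mixed reservoir, and per-sensor plume transport. Purifier
#' decay is exactly multiplicative, so repeated noise-free steps reproduce
#' the closed form `a*10^(-b t) + c` to machine precision. Sensors relax
#' toward the well-mixed level as it stood one transport delay ago, but only
#' while the generator is running or within one delay of it stopping; after
#' that the plume is frozen apart from purifier losses.
#'
#' @param state A [room_state()].
#' @param devices Named logical vector or list with elements `generator`,
#'   `purifier`, `fan`.
#' @param dt Time step in seconds (> 0).
#' @param room A [room_spec()].
#' @param source An [aerosol_source()].
#' @param grid A [size_bin_grid()].
#' @return The advanced `room_state`.
#' @export
step_room <- function(state, devices, dt, room, source, grid) {
  stopifnot(inherits(state, "room_state"))
  if (dt <= 0) stop("step_room: dt must be > 0")
  gen <- isTRUE(as.logical(devices[["generator"]]))
  pur <- isTRUE(as.logical(devices[["purifier"]]))
  fan <- isTRUE(as.logical(devices[["fan"]]))

  if (pur) {
    f <- 10^(-room$decay_b * dt)
    state$mixed <- state$mixed * f
    state$sensor <- state$sensor * f
    state$background_ugm3 <- room$floor_ugm3 +
      max(state$background_ugm3 - room$floor_ugm3, 0) * f
  } else {
    state$background_ugm3 <- state$background_ugm3 + room$rise_slope * dt
  }

  t_new <- state$time_s + dt
  if (gen) {
    state$mixed <- state$mixed +
      state$frac * source$rate_per_s * dt / (1000 * room$volume_m3)
    state$last_gen_on_s <- t_new
  }

  tau <- room$delay_s_per_m * room$sensors$distance_m *
    (if (fan) room$fan_delay_factor else 1)
  relax <- 1 - exp(-dt / room$mixing_tau_s)
  for (s in seq_len(nrow(state$sensor))) {
    if (gen || (t_new - state$last_gen_on_s) <= tau[s]) {
      target <- delayed_mixed(state, t_new - tau[s])
      state$sensor[s, ] <- state$sensor[s, ] +
        (target - state$sensor[s, ]) * relax
    }
  }

  state$time_s <- t_new
  state$hist_t <- c(state$hist_t, t_new)
  state$hist_m <- rbind(state$hist_m, state$mixed)
  keep <- state$hist_t >= t_new - (max(tau, room$delay_s_per_m) + 2 * dt)
  if (!keep[1L]) { # always retain at least the oldest pre-window snapshot
    first <- max(which(!keep))
    keep[first] <- TRUE
  }
  state$hist_t <- state$hist_t[keep]
  state$hist_m <- state$hist_m[keep, , drop = FALSE]
  state
}

#' Mask model with per-donning fit variation
#'
#' A mask's realized efficacy differs from its nominal value on every
#' donning because the fit is never reproduced exactly. Each donning draws
#' an additive offset (percentage points) from a centred normal
#' distribution; with the default 5-point spread, 20 donnings span roughly
#' +/- 10 points around the nominal efficacy.
#'
#' @param nominal_pct Nominal efficacy in percent.
#' @param spread_sd_pct Standard deviation of the per-donning offset in
#'   percentage points (default 5).
#' @return An object of class `mask_model`; realized efficacy is clamped to
#'   [0, 100].
#' @export
mask_model <- function(nominal_pct, spread_sd_pct = 5) {
  nominal_pct <- as.numeric(nominal_pct)
  spread_sd_pct <- as.numeric(spread_sd_pct)
  if (nominal_pct < 0 || nominal_pct > 100)
    stop("mask_model: nominal_pct must be in [0, 100]")
  if (spread_sd_pct < 0) stop("mask_model: spread_sd_pct must be >= 0")
  structure(list(nominal_pct = nominal_pct, spread_sd_pct = spread_sd_pct,
                 donned_offset_pct = 0),
            class = "mask_model")
}

#' Don a mask, drawing a fresh fit offset
#'
#' Uses the R random number generator; seed it (or run under a seeded
#' backend) for reproducibility. Successive donnings are independent.
#'
#' @param mask A [mask_model()].
#' @return The mask with a new `donned_offset_pct`.
#' @export
don_mask <- function(mask) {
  stopifnot(inherits(mask, "mask_model"))
  mask$donned_offset_pct <- stats::rnorm(1, 0, mask$spread_sd_pct)
  mask
}

#' Realized efficacy of a donned mask
#' @param mask A [mask_model()].
#' @return Efficacy in percent, clamped to [0, 100].
#' @export
realized_efficacy <- function(mask) {
  stopifnot(inherits(mask, "mask_model"))
  min(max(mask$nominal_pct + mask$donned_offset_pct, 0), 100)
}

#' Simulated laser aerosol spectrometer
#'
#' @param device_id Character id (e.g. "LAS-0"); must match a sensor
#'   position in the [room_spec()].
#' @param bias Fixed multiplicative response factor (> 0); co-located real
#'   instruments were observed to differ by up to ~6%, so biases are
#'   typically drawn within 0.94--1.06.
#' @param flow_L_min Sample flow in litres per minute (default 1.2).
#' @param mask A [mask_model()] mounted in front of the inlet, or NULL.
#' @return An object of class `spectrometer_model`.
#' @export
spectrometer_model <- function(device_id, bias = 1, flow_L_min = 1.2,
                               mask = NULL) {
  if (bias <= 0) stop("spectrometer_model: bias must be > 0")
  if (!is.null(mask)) stopifnot(inherits(mask, "mask_model"))
  structure(list(device_id = as.character(device_id), bias = bias,
                 flow_L_min = flow_L_min, mask = mask),
            class = "spectrometer_model")
}

#' Read one sample from a simulated spectrometer
#'
#' The ambient per-bin concentration at the instrument's position (sensor
#' plume plus background) is attenuated by the mask's realized efficacy if
#' one is mounted, scaled by the device bias, and optionally perturbed by
#' Poisson counting noise on the expected number of particles in the
#' per-tick sample volume (flow x tick, 0.12 L at 1.2 L/min and 6 s).
#'
#' @param model A [spectrometer_model()].
#' @param state A [room_state()] containing the model's `device_id`.
#' @param grid A [size_bin_grid()].
#' @param tick_s Sample integration time in seconds (default 6).
#' @param noise Apply Poisson counting noise (default TRUE; uses the R RNG).
#' @param phase,repeat_index Metadata stamped on the reading.
#' @return A `spectrometer_reading`: list with `time_s`, `device_id`,
#'   `bins_per_L`, `total_per_L`, `pm2_5_ugm3`, `pm10_ugm3`, `phase`,
#'   `repeat_index`.
#' @export
read_spectrometer <- function(model, state, grid, tick_s = 6, noise = TRUE,
                              phase = "", repeat_index = 0L) {
  stopifnot(inherits(model, "spectrometer_model"),
            inherits(state, "room_state"))
  i <- match(model$device_id, rownames(state$sensor))
  if (is.na(i))
    stop(sprintf("read_spectrometer: unknown device id '%s'", model$device_id))
  ambient <- state$sensor[i, ] + state$bg_unit * state$background_ugm3
  expected <- ambient
  if (!is.null(model$mask))
    expected <- expected * (1 - realized_efficacy(model$mask) / 100)
  expected <- expected * model$bias
  if (noise) {
    vol_L <- model$flow_L_min / 60 * tick_s
    expected <- stats::rpois(length(expected), expected * vol_L) / vol_L
  }
  structure(list(
    time_s = state$time_s,
    device_id = model$device_id,
    bins_per_L = expected,
    total_per_L = sum(expected),
    pm2_5_ugm3 = pm_from_bins(expected, grid, state$density, state$cutoff),
    pm10_ugm3 = pm_from_bins(expected, grid, state$density, 10),
    phase = phase,
    repeat_index = as.integer(repeat_index)
  ), class = "spectrometer_reading")
}
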