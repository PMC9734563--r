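#' Simulated device backend
#'
#' Bundles the virtual room, aerosol source, size grid and a set of
#' simulated spectrometers into a mutable backend the acquisition loop can
#' drive. The backend owns all randomness of a run: it seeds the R RNG once
#' at construction, draws each instrument's bias (if requested) and each
#' mask's donning offset, and thereafter supplies Poisson counting noise.
#' A seed is mandatory whenever any stochastic element is active; refusing
#' to run is preferred over silently irreproducible data.
#'
#' @param room A [room_spec()].
#' @param source An [aerosol_source()].
#' @param grid A [size_bin_grid()].
#' @param masks Named list of [mask_model()]s keyed by device id (devices
#'   without an entry are bare).
#' @param biases Either "random" (each device's multiplicative bias drawn
#'   once per run uniformly within `bias_range`) or a named numeric vector
#'   keyed by device id (missing ids get 1).
#' @param bias_range Range for random biases (default 0.94--1.06, the
#'   maximum relative error observed between co-located instruments).
#' @param noise Apply Poisson counting noise (default TRUE).
#' @param seed Integer seed; required if `noise`, random biases, or any
#'   mask with a positive donning spread is present.
#' @param background_ugm3,mixed_per_L Initial room state, see [room_state()].
#' @param density,cutoff Mass-conversion parameters, see [room_state()].
#' @return An environment of class `sim_backend`.
#' @export
sim_backend <- function(room, source, grid, masks = list(),
                        biases = "random", bias_range = c(0.94, 1.06),
                        noise = TRUE, seed = NULL,
                        background_ugm3 = room$floor_ugm3,
                        mixed_per_L = NULL,
                        density = 0.914, cutoff = 2.53) {
  stopifnot(inherits(room, "room_spec"))
  random_bias <- identical(biases, "random")
  stochastic <- noise || random_bias ||
    any(vapply(masks, function(m) m$spread_sd_pct > 0, logical(1)))
  if (stochastic && is.null(seed))
    stop("sim_backend: a seed is required for stochastic backends ",
         "(noise, random biases or mask donning spread)")
  if (!is.null(seed)) set.seed(as.integer(seed))

  ids <- room$sensors$id
  bad <- setdiff(names(masks), ids)
  if (length(bad))
    stop("sim_backend: mask for unknown device id: ", paste(bad, collapse = ", "))
  b <- if (random_bias) {
    stats::setNames(stats::runif(length(ids), bias_range[1], bias_range[2]), ids)
  } else {
    full <- stats::setNames(rep(1, length(ids)), ids)
    full[names(biases)] <- biases
    full
  }
  models <- lapply(ids, function(id) {
    m <- masks[[id]]
    if (!is.null(m)) m <- don_mask(m)
    spectrometer_model(id, bias = b[[id]], mask = m)
  })
  names(models) <- ids

  e <- new.env(parent = emptyenv())
  e$room <- room; e$source <- source; e$grid <- grid
  e$models <- models
  e$noise <- noise
  e$seed <- seed
  e$devices <- c(generator = FALSE, purifier = FALSE, fan = FALSE)
  e$state <- room_state(room, source, grid, background_ugm3 = background_ugm3,
                        mixed_per_L = mixed_per_L, density = density,
                        cutoff = cutoff)
  class(e) <- "sim_backend"
  e
}

#' @export
print.sim_backend <- function(x, ...) {
  cat(sprintf("sim_backend: %d sensors, t = %.0f s, noise %s\n",
              length(x$models), x$state$time_s, if (x$noise) "on" else "off"))
  invisible(x)
}

#' Backend protocol: sensor ids, device-state application, time stepping,
#' sensor readout
#'
#' Any object implementing these four generics can be driven by
#' [acquire()].
#'
#' @param backend A backend object.
#' @param devices Named logical vector `generator`, `purifier`, `fan`.
#' @param dt Time step in seconds.
#' @param phase,repeat_index Metadata stamped on each reading.
#' @name backend-protocol
NULL

#' @rdname backend-protocol
#' @export
backend_sensors <- function(backend) UseMethod("backend_sensors")

#' @rdname backend-protocol
#' @export
backend_apply <- function(backend, devices) UseMethod("backend_apply")

#' @rdname backend-protocol
#' @export
backend_step <- function(backend, dt) UseMethod("backend_step")

#' @rdname backend-protocol
#' @export
backend_read <- function(backend, phase = "", repeat_index = 0L)
  UseMethod("backend_read")

#' @export
backend_sensors.sim_backend <- function(backend) names(backend$models)

#' @export
backend_apply.sim_backend <- function(backend, devices) {
  for (d in c("generator", "purifier", "fan"))
    if (!is.null(devices[[d]])) backend$devices[[d]] <- isTRUE(devices[[d]])
  invisible(backend)
}

#' @export
backend_step.sim_backend <- function(backend, dt) {
  backend$state <- step_room(backend$state, backend$devices, dt,
                             backend$room, backend$source, backend$grid)
  invisible(backend)
}

#' @export
backend_read.sim_backend <- function(backend, phase = "", repeat_index = 0L) {
  lapply(backend$models, read_spectrometer, state = backend$state,
         grid = backend$grid, noise = backend$noise, phase = phase,
         repeat_index = repeat_index)
}

#' Build a simulated backend from a config's `sim:` section
#'
#' Interprets the optional `sim:` mapping of a run configuration:
#' `room:` (fields of [room_spec()], with `sensors` as a list of
#' `{id, distance_m}` maps), `source:` ([aerosol_source()] fields),
#' `masks:` (device id -> `{nominal_pct, spread_sd_pct}`), `biases:`
#' (device id -> factor, or "random"), `noise:`, `background_ugm3:`.
#' Omitted sections use package defaults; the config seed is used.
#'
#' @param cfg An [experiment_config()].
#' @param grid A [size_bin_grid()] (default [default_bin_grid()]).
#' @return A [sim_backend()].
#' @export
sim_backend_from_config <- function(cfg, grid = default_bin_grid()) {
  stopifnot(inherits(cfg, "experiment_config"))
  sim <- if (is.null(cfg$sim)) list() else cfg$sim
  room_args <- sim$room %||% list()
  if (!is.null(room_args$sensors))
    room_args$sensors <- do.call(rbind, lapply(room_args$sensors, as.data.frame))
  room <- do.call(room_spec, room_args)
  source <- do.call(aerosol_source, sim$source %||% list())
  masks <- lapply(sim$masks %||% list(), function(m)
    do.call(mask_model, as.list(m)))
  sim_backend(room, source, grid,
              masks = masks,
              biases = sim$biases %||% "random",
              noise = sim$noise %||% TRUE,
              seed = cfg$seed,
              background_ugm3 = sim$background_ugm3 %||% room$floor_ugm3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
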