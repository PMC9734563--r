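# Shared fixtures: small rooms, backends and configs built in code.

demo_config_yaml <- function(seed = 42) sprintf("
id: demo
pre: [[20, CLEAN]]
repeats: 3
protocol:
  - [20, AEROSOL, during]
  - [10, PAUSE]
post: [[20, CLEAN]]
seed: %d
", seed)

tiny_room <- function(ids = c("LAS-0", "LAS-1"), distance_m = 1) {
  room_spec(sensors = data.frame(id = ids,
                                 distance_m = rep_len(distance_m, length(ids))))
}

unit_biases <- function(ids) stats::setNames(rep(1, length(ids)), ids)

# A static ambient field: room with everything off, sensors equilibrated at
# `mixed_per_L` counts per bin. Deterministic unless noise is on.
static_backend <- function(ids = c("LAS-0", "LAS-1"), mixed_per_L = NULL,
                           masks = list(), biases = NULL, noise = FALSE,
                           seed = NULL, grid = default_bin_grid(),
                           background_ugm3 = NULL) {
  room <- tiny_room(ids)
  src <- aerosol_source()
  if (is.null(mixed_per_L))
    mixed_per_L <- sample_size_fractions(src, grid) * 1e5
  if (is.null(biases)) biases <- unit_biases(ids)
  sim_backend(room, src, grid, masks = masks, biases = biases,
              noise = noise, seed = seed,
              background_ugm3 = background_ugm3 %||% room$floor_ugm3,
              mixed_per_L = mixed_per_L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw `n` noisy readings from a frozen backend state (no time stepping):
# returns a list of per-device numeric vectors of the chosen field.
sample_readings <- function(backend, n, field = "total_per_L") {
  ids <- backend_sensors(backend)
  out <- lapply(ids, function(id) numeric(n))
  names(out) <- ids
  for (k in seq_len(n)) {
    r <- backend_read(backend)
    for (id in ids) out[[id]][k] <- r[[id]][[field]]
  }
  out
}

# Backend wrapper whose sensor reads start failing after `fail_after` reads;
# used to exercise the abort contract of the acquisition loop.
failing_backend <- function(inner, fail_after) {
  e <- new.env(parent = emptyenv())
  e$inner <- inner
  e$fail_after <- fail_after
  e$reads <- 0L
  class(e) <- "failing_backend"
  e
}

registerS3method("backend_sensors", "failing_backend",
                 function(backend) backend_sensors(backend$inner),
                 envir = asNamespace("aerotest"))
registerS3method("backend_apply", "failing_backend",
                 function(backend, devices) backend_apply(backend$inner, devices),
                 envir = asNamespace("aerotest"))
registerS3method("backend_step", "failing_backend",
                 function(backend, dt) backend_step(backend$inner, dt),
                 envir = asNamespace("aerotest"))
registerS3method("backend_read", "failing_backend",
                 function(backend, phase = "", repeat_index = 0L) {
                   backend$reads <- backend$reads + 1L
                   if (backend$reads > backend$fail_after) stop("sensor dropout")
                   backend_read(backend$inner, phase, repeat_index)
                 },
                 envir = asNamespace("aerotest"))
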