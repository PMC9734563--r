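ACTIONS <- c("AEROSOL", "CLEAN", "PAUSE", "FAN_ON", "FAN_OFF")

#' Protocol step
#'
#' One timed action within an experiment protocol. `(20, "AEROSOL",
#' "during")` means: generate aerosol for 20 minutes, stamping the comment
#' "during" on every logged row. `CLEAN` runs the air purifier, `PAUSE`
#' only collects data, and `FAN_ON`/`FAN_OFF` toggle the fan persistently
#' for all subsequent steps.
#'
#' @param duration_min Step duration in minutes (> 0).
#' @param action One of "AEROSOL", "CLEAN", "PAUSE", "FAN_ON", "FAN_OFF".
#' @param comment Free text recorded into the data log (may be empty).
#' @return An object of class `protocol_step`.
#' @export
protocol_step <- function(duration_min, action, comment = "") {
  if (!is.numeric(duration_min) || length(duration_min) != 1 ||
      !is.finite(duration_min) || duration_min <= 0)
    stop("protocol_step: duration must be a positive number of minutes")
  action <- as.character(action)
  if (!(action %in% ACTIONS))
    stop(sprintf("protocol_step: unknown action '%s' (allowed: %s)",
                 action, paste(ACTIONS, collapse = ", ")))
  structure(list(duration_min = duration_min, action = action,
                 comment = as.character(comment)[1]),
            class = "protocol_step")
}

#' Experiment configuration
#'
#' The full description of a run: a unique id, steps executed once before
#' (`pre`), a block of `protocol` steps executed `repeats` times, steps
#' executed once after (`post`), the sampling tick, and the seed driving
#' every stochastic backend.
#'
#' @param id Unique, filesystem-safe run identifier.
#' @param protocol List of [protocol_step()]s, repeated; must be non-empty.
#' @param pre,post Lists of [protocol_step()]s run once before/after.
#' @param repeats Number of protocol repetitions (>= 1).
#' @param seed Integer seed, or NULL. Stochastic backends refuse to run
#'   without one rather than produce silently irreproducible data.
#' @param tick_s Sampling interval in seconds (default 6).
#' @param sim Optional named list of simulator parameters (see
#'   [sim_backend_from_config()]).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(id, protocol, pre = list(), post = list(),
                              repeats = 1L, seed = NULL, tick_s = 6,
                              sim = NULL) {
  cfg <- structure(list(id = as.character(id)[1], pre = pre,
                        repeats = as.integer(repeats), protocol = protocol,
                        post = post,
                        seed = if (is.null(seed)) NULL else as.integer(seed),
                        tick_s = as.numeric(tick_s), sim = sim),
                   class = "experiment_config")
  v <- validate_config(cfg)
  if (length(v)) stop("invalid experiment_config:\n  ", paste(v, collapse = "\n  "))
  cfg
}

#' Validate an experiment configuration
#'
#' Checks every structural invariant and returns the violations as a
#' character vector (empty when the configuration is valid); nothing is
#' raised, so the function can back a linting interface.
#'
#' @param cfg An `experiment_config` (possibly hand-built).
#' @return Character vector of violations, each naming field and rule.
#' @export
validate_config <- function(cfg) {
  v <- character()
  if (!length(cfg$id) || is.na(cfg$id) || !nzchar(cfg$id))
    v <- c(v, "id: must be non-empty")
  else if (grepl("[^A-Za-z0-9._-]", cfg$id))
    v <- c(v, "id: must be filesystem-safe (A-Za-z0-9._-)")
  if (!length(cfg$repeats) || is.na(cfg$repeats) || cfg$repeats < 1L)
    v <- c(v, "repeats: must be >= 1")
  if (!length(cfg$protocol))
    v <- c(v, "protocol: must contain at least one step")
  if (!is.numeric(cfg$tick_s) || cfg$tick_s <= 0)
    v <- c(v, "tick_s: must be > 0")
  for (block in c("pre", "protocol", "post")) {
    steps <- cfg[[block]]
    for (k in seq_along(steps)) {
      s <- steps[[k]]
      if (!inherits(s, "protocol_step")) {
        v <- c(v, sprintf("%s[%d]: not a protocol_step", block, k)); next
      }
      if (!is.finite(s$duration_min) || s$duration_min <= 0)
        v <- c(v, sprintf("%s[%d].duration: must be > 0 minutes", block, k))
      if (!(s$action %in% ACTIONS))
        v <- c(v, sprintf("%s[%d].action: unknown action '%s'", block, k, s$action))
    }
  }
  v
}

parse_step_list <- function(x, block) {
  if (is.null(x)) return(list())
  if (!is.list(x)) stop(sprintf("config: '%s' must be a list of steps", block))
  lapply(seq_along(x), function(k) {
    s <- x[[k]]
    if (!is.list(s) && !is.vector(s))
      stop(sprintf("config: %s[%d] is not a step", block, k))
    s <- as.list(s)
    if (length(s) < 2L || length(s) > 3L)
      stop(sprintf("config: %s[%d] must be (minutes, ACTION[, comment])", block, k))
    dur <- suppressWarnings(as.numeric(s[[1]]))
    if (is.na(dur))
      stop(sprintf("config: %s[%d] duration '%s' is not a number", block, k, s[[1]]))
    protocol_step(dur, s[[2]], if (length(s) == 3L) s[[3]] else "")
  })
}

#' Parse a YAML experiment configuration
#'
#' Reads the declarative run description: scalar keys `id`, `repeats`,
#' optional `seed` and `tick_s`, step lists `pre`, `protocol`, `post`
#' (each step a `[minutes, ACTION]` or `[minutes, ACTION, comment]`
#' sequence), and an optional `sim:` section with simulator parameters.
#' Unknown top-level keys are rejected.
#'
#' @param text YAML text, or a file path when `is_file = TRUE`.
#' @param is_file Interpret `text` as a path.
#' @return A validated [experiment_config()].
#' @examples
#' cfg <- parse_config("
#' id: demo
#' pre: [[20, CLEAN]]
#' repeats: 3
#' protocol:
#'   - [20, AEROSOL, during]
#'   - [10, PAUSE]
#' post: [[20, CLEAN]]
#' seed: 1
#' ")
#' cfg$repeats
#' @export
parse_config <- function(text, is_file = FALSE) {
  raw <- tryCatch(
    if (is_file) yaml::read_yaml(text) else yaml::yaml.load(text),
    error = function(e) stop("config syntax error: ", conditionMessage(e),
                             call. = FALSE))
  if (!is.list(raw)) stop("config: top level must be a mapping")
  known <- c("id", "pre", "repeats", "protocol", "post", "seed", "tick_s", "sim")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$id)) stop("config: 'id' is required")
  if (is.null(raw$protocol)) stop("config: 'protocol' is required")
  experiment_config(
    id = raw$id,
    pre = parse_step_list(raw$pre, "pre"),
    repeats = if (is.null(raw$repeats)) 1L else raw$repeats,
    protocol = parse_step_list(raw$protocol, "protocol"),
    post = parse_step_list(raw$post, "post"),
    seed = raw$seed,
    tick_s = if (is.null(raw$tick_s)) 6 else raw$tick_s,
    sim = raw$sim
  )
}

#' Expand a configuration into a deterministic schedule
#'
#' Lays out pre, `repeats` copies of the protocol, and post as contiguous
#' segments, mapping each action to a device-state vector: AEROSOL turns the
#' generator on (purifier off), CLEAN the purifier on (generator off), PAUSE
#' both off; FAN_ON/FAN_OFF change the fan state persistently for all
#' subsequent segments and leave generator/purifier off during their own
#' segment. The fan is initially off. Sampling ticks fall at exact
#' multiples of `tick_s`, the first at `t = tick_s`.
#'
#' @param cfg An [experiment_config()].
#' @param tick_s Sampling interval override in seconds (default: the
#'   config's).
#' @return An object of class `schedule`: list with `segments` (data frame
#'   with `t_start_s`, `t_end_s`, `generator`, `purifier`, `fan`, `phase`,
#'   `repeat_index`), `tick_s`, `total_duration_s`, `n_ticks`, `config_id`,
#'   `seed`.
#' @export
expand_schedule <- function(cfg, tick_s = cfg$tick_s) {
  stopifnot(inherits(cfg, "experiment_config"))
  v <- validate_config(cfg)
  if (length(v)) stop("invalid config:\n  ", paste(v, collapse = "\n  "))
  steps <- c(list(), lapply(cfg$pre, c, repeat_index = 0L))
  for (r in seq_len(cfg$repeats))
    steps <- c(steps, lapply(cfg$protocol, c, repeat_index = r))
  steps <- c(steps, lapply(cfg$post, c, repeat_index = 0L))

  n <- length(steps)
  fan <- FALSE
  t0 <- 0
  seg <- vector("list", n)
  for (k in seq_len(n)) {
    s <- steps[[k]]
    if (s$action == "FAN_ON") fan <- TRUE
    if (s$action == "FAN_OFF") fan <- FALSE
    dur_s <- s$duration_min * 60
    seg[[k]] <- data.frame(
      t_start_s = t0, t_end_s = t0 + dur_s,
      generator = s$action == "AEROSOL",
      purifier = s$action == "CLEAN",
      fan = fan,
      phase = s$comment,
      repeat_index = s$repeat_index,
      stringsAsFactors = FALSE)
    t0 <- t0 + dur_s
  }
  segments <- do.call(rbind, seg)
  structure(list(
    segments = segments,
    tick_s = tick_s,
    total_duration_s = t0,
    n_ticks = floor(t0 / tick_s),
    config_id = cfg$id,
    seed = cfg$seed
  ), class = "schedule")
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("schedule '%s': %d segments, %.0f s total, %d ticks @ %g s\n",
              x$config_id, nrow(x$segments), x$total_duration_s,
              x$n_ticks, x$tick_s))
  invisible(x)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("experiment_config '%s': %d pre, %d protocol x %d, %d post steps\n",
              x$id, length(x$pre), length(x$protocol), x$repeats,
              length(x$post)))
  invisible(x)
}
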