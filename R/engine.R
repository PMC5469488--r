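# Deterministic cycle engine.
#
# Per cycle: (1) acquire -- every enabled AI channel publishes its scaled
# sample for t = cycle/frequency; (2) every loaded, unpaused module executes
# once, in load order, reading inputs through the summed-fan-in gather rule;
# (3) the event queue is drained FIFO and update hooks run; (4) every enabled
# AO channel emits the clipped value of its gathered input. Structural
# changes (pause, period, load/unload, parameter writes) requested mid-cycle
# are applied at the next cycle boundary. Events posted while the queue is
# being drained are deferred to the next cycle.

#' Start an engine from a workspace
#'
#' Builds the mutable runtime for a validated workspace: per-module runtime
#' environments (running each module's INIT hook in load order), the port
#' table, the event queue and the analog-output traces. The engine can then
#' be advanced manually with [run_cycle()] or driven by [run()].
#'
#' @param ws Workspace.
#' @param sources Named list of input signal functions keyed by channel name
#'   (e.g. `list(AI0 = function(t) ...)`). Each function must accept a vector
#'   of times (seconds) and return volts. Channels without a source read 0 V.
#' @return An `ll_engine` environment.
#' @export
start_engine <- function(ws, sources = list()) {
  validate_workspace(ws)
  eng <- new.env(parent = emptyenv())
  class(eng) <- "ll_engine"
  eng$frequency <- ws$engine$frequency
  eng$period <- ws$engine$period
  eng$mode <- ws$engine$mode
  eng$seed <- ws$engine$seed
  eng$channels <- ws$channels
  eng$sources <- sources
  eng$connections <- ws$connections
  eng$next_connection_id <- ws$next_connection_id
  eng$incoming <- incoming_map(ws)
  eng$ports <- new.env(parent = emptyenv())
  eng$queue <- list()
  eng$draining <- FALSE
  eng$requests <- list()
  eng$cycle <- 0L
  eng$epoch_time <- 0
  eng$epoch_cycle <- 0L
  eng$events_processed <- 0L
  eng$nan_cycles <- 0L
  eng$recorder <- NULL
  eng$benchmarks <- NULL
  eng$modules <- list()
  eng$load_order <- character()
  eng$ao <- list()
  for (key in names(ws$channels))
    if (ws$channels[[key]]$direction %in% c("AO", "DIO") && ws$channels[[key]]$enabled)
      eng$ao[[key]] <- new_trace()
  set.seed(eng$seed)
  for (m in ws$modules) engine_add_module(eng, m)
  eng
}

#' @export
print.ll_engine <- function(x, ...) {
  cat("<ll_engine> ", x$frequency, " Hz, mode=", x$mode,
      ", cycle=", x$cycle, " (t=", format(engine_time(x)), " s)\n", sep = "")
  cat("  modules: ", paste(x$load_order, collapse = ", "), "\n")
  invisible(x)
}

#' Current simulated time of an engine
#' @param eng Engine.
#' @return Time in seconds of the next cycle to run.
#' @export
engine_time <- function(eng) eng$epoch_time + (eng$cycle - eng$epoch_cycle) * eng$period

# growing numeric trace ------------------------------------------------------
new_trace <- function(capacity = 1024L) {
  tr <- new.env(parent = emptyenv())
  tr$values <- numeric(capacity)
  tr$n <- 0L
  tr
}
trace_push <- function(tr, v) {
  n <- tr$n + 1L
  if (n > length(tr$values)) tr$values <- c(tr$values, numeric(length(tr$values)))
  tr$values[n] <- v
  tr$n <- n
}
trace_push_vec <- function(tr, v) {
  need <- tr$n + length(v)
  if (need > length(tr$values))
    tr$values <- c(tr$values, numeric(max(length(tr$values), need)))
  tr$values[(tr$n + 1L):need] <- v
  tr$n <- need
}
trace_values <- function(tr) tr$values[seq_len(tr$n)]

# module runtime -------------------------------------------------------------
engine_add_module <- function(eng, inst) {
  def <- module_type(inst$type)
  mod <- new.env(parent = emptyenv())
  mod$id <- inst$id
  mod$type <- inst$type
  mod$def <- def
  mod$params <- inst$params
  mod$states <- inst$states
  mod$paused <- FALSE
  eng$modules[[inst$id]] <- mod
  eng$load_order <- c(eng$load_order, inst$id)
  for (p in def$outputs) eng$ports[[paste0(inst$id, ".", p)]] <- 0
  if (!is.null(def$init)) def$init(mod, eng)
  mod
}

rebuild_incoming <- function(eng) {
  ws <- list(connections = eng$connections)
  eng$incoming <- incoming_map(ws)
}

#' Post a real-time event
#'
#' Appends an event to the FIFO queue. Events posted during the execute
#' phase are drained in the same cycle, after every execute; events posted
#' while the queue is being drained, or between cycles, are drained in the
#' next cycle.
#'
#' @param eng Engine.
#' @param kind One of `"param_modified"`, `"period_changed"`,
#'   `"module_loaded"`, `"module_unloaded"`, `"pause_changed"`, `"custom"`.
#' @param source Module id posting the event (or `"engine"`).
#' @param payload Named list of event data.
#' @return The event, invisibly.
#' @export
post_event <- function(eng, kind, source = "engine", payload = list()) {
  kinds <- c("param_modified", "period_changed", "module_loaded",
             "module_unloaded", "pause_changed", "custom")
  if (!kind %in% kinds) stop("unknown event kind: ", kind)
  if (!identical(source, "engine") && is.null(eng$modules[[source]]))
    stop("unknown source module id: ", source)
  ev <- list(kind = kind, source = source, payload = payload, cycle = eng$cycle)
  eng$queue[[length(eng$queue) + 1L]] <- ev
  invisible(ev)
}

# --- boundary requests ------------------------------------------------------

#' Change the engine frequency
#'
#' On a workspace this is immediate. On a running engine the change is
#' applied at the next cycle boundary: the period is recomputed and every
#' module's update hook is invoked with state `PERIOD` before that cycle's
#' executes, so period-dependent module state (filter coefficients, window
#' lengths in samples, integrator dt) is rebuilt in time. Requesting the
#' current frequency is a no-op (no notification is emitted).
#'
#' @param x Workspace or engine.
#' @param frequency New rate in Hz, > 0.
#' @return The updated workspace, or the engine invisibly.
#' @export
set_period <- function(x, frequency) {
  if (!is.numeric(frequency) || length(frequency) != 1L || !is.finite(frequency) ||
      frequency <= 0)
    stop("frequency must be a positive finite number")
  if (inherits(x, "ll_workspace")) {
    x$engine$frequency <- as.numeric(frequency)
    x$engine$period <- 1 / as.numeric(frequency)
    return(x)
  }
  stopifnot(inherits(x, "ll_engine"))
  if (frequency != x$frequency)
    x$requests[[length(x$requests) + 1L]] <- list(op = "period", frequency = frequency)
  invisible(x)
}

#' Load a module into a running engine
#'
#' Applied at the next cycle boundary without interrupting acquisition: the
#' INIT hook runs at the boundary and the first execute happens in that
#' cycle. A `module_loaded` event is broadcast. Validation (type registered,
#' parameter names legal) happens immediately, before INIT.
#'
#' @param eng Engine.
#' @param type Registered module type.
#' @param id Instance id (default: type name, uniquified).
#' @param params Named list of parameter overrides.
#' @return The new module id.
#' @export
load_module <- function(eng, type, id = NULL, params = list()) {
  stopifnot(inherits(eng, "ll_engine"))
  if (is.null(id)) {
    id <- type
    n <- 1L
    while (!is.null(eng$modules[[id]]) ||
           id %in% vapply(eng$requests, function(r)
             if (identical(r$op, "load")) r$inst$id else "", "")) {
      n <- n + 1L
      id <- paste0(type, n)
    }
  }
  if (!is.null(eng$modules[[id]])) stop("module id already in use: ", id)
  inst <- new_module_instance(type, id, params)   # validates before INIT
  eng$requests[[length(eng$requests) + 1L]] <- list(op = "load", inst = inst)
  id
}

#' Unload a module from a running engine
#'
#' Applied at the next cycle boundary. Connections touching the module are
#' removed with it; remaining sources on any shared fan-in keep being summed.
#' A `module_unloaded` event is broadcast.
#'
#' @param eng Engine. @param id Module id.
#' @return The engine, invisibly.
#' @export
unload_module <- function(eng, id) {
  stopifnot(inherits(eng, "ll_engine"))
  if (is.null(eng$modules[[id]])) stop("unload of non-existent module id: ", id)
  eng$requests[[length(eng$requests) + 1L]] <- list(op = "unload", id = id)
  invisible(eng)
}

#' Pause or unpause a module
#'
#' Applied at the next cycle boundary. A paused module's execute hook is not
#' invoked; its output ports retain their last-written values. The module's
#' update hook is notified with `PAUSED`/`UNPAUSED`.
#'
#' @param eng Engine. @param id Module id. @param paused Logical.
#' @return The engine, invisibly.
#' @export
pause_module <- function(eng, id, paused = TRUE) {
  stopifnot(inherits(eng, "ll_engine"))
  if (is.null(eng$modules[[id]])) stop("no such module: ", id)
  eng$requests[[length(eng$requests) + 1L]] <-
    list(op = "pause", id = id, paused = isTRUE(paused))
  invisible(eng)
}

#' Modify a module parameter on the fly
#'
#' Posts a `param_modified` event; the new value takes effect when the queue
#' is drained (same cycle if posted during execute, next cycle otherwise),
#' at which point the module's update hook runs with state `MODIFY` and, if a
#' recorder is attached and active, the change is logged with its timestamp.
#'
#' @param eng Engine. @param id Module id. @param name Parameter name.
#' @param value New value.
#' @return The engine, invisibly.
#' @export
set_param <- function(eng, id, name, value) {
  stopifnot(inherits(eng, "ll_engine"))
  mod <- eng$modules[[id]]
  if (is.null(mod)) stop("no such module: ", id)
  if (!name %in% names(mod$params))
    stop("module '", id, "' has no parameter '", name, "'")
  post_event(eng, "param_modified", source = id,
             payload = list(module = id, name = name, value = value))
  invisible(eng)
}

apply_requests <- function(eng) {
  if (!length(eng$requests)) return(invisible())
  reqs <- eng$requests
  eng$requests <- list()
  for (r in reqs) {
    switch(r$op,
      period = {
        t_now <- engine_time(eng)
        eng$epoch_time <- t_now
        eng$epoch_cycle <- eng$cycle
        eng$frequency <- r$frequency
        eng$period <- 1 / r$frequency
        for (id in eng$load_order)
          notify_module(eng, eng$modules[[id]], "PERIOD", NULL)
      },
      load = {
        engine_add_module(eng, r$inst)
        post_event(eng, "module_loaded", source = r$inst$id,
                   payload = list(module = r$inst$id))
      },
      unload = {
        id <- r$id
        if (is.null(eng$modules[[id]])) next
        eng$modules[[id]] <- NULL
        eng$load_order <- setdiff(eng$load_order, id)
        keep <- vapply(eng$connections, function(cn)
          endpoint_owner(cn$src) != id && endpoint_owner(cn$dst) != id, logical(1))
        eng$connections <- eng$connections[keep]
        rebuild_incoming(eng)
        # the event is posted by the engine: the source module is gone
        post_event(eng, "module_unloaded", payload = list(module = id))
      },
      pause = {
        mod <- eng$modules[[r$id]]
        if (is.null(mod)) next
        if (mod$paused != r$paused) {
          mod$paused <- r$paused
          notify_module(eng, mod, if (r$paused) "PAUSED" else "UNPAUSED", NULL)
          post_event(eng, "pause_changed", source = r$id,
                     payload = list(module = r$id, paused = r$paused))
        }
      })
  }
  invisible()
}

notify_module <- function(eng, mod, flag, event) {
  if (!is.null(mod$def$update)) mod$def$update(mod, flag, event, eng)
}

drain_events <- function(eng, t) {
  q <- eng$queue
  eng$queue <- list()
  if (!length(q)) return(0L)
  eng$draining <- TRUE
  on.exit(eng$draining <- FALSE)
  for (ev in q) {
    switch(ev$kind,
      param_modified = {
        mod <- eng$modules[[ev$payload$module]]
        if (!is.null(mod)) {
          mod$params[[ev$payload$name]] <- ev$payload$value
          notify_module(eng, mod, "MODIFY", ev)
          if (!is.null(eng$recorder) && isTRUE(eng$recorder$active))
            log_param_change(eng$recorder, t, ev$payload$module,
                             ev$payload$name, ev$payload$value)
        }
      },
      period_changed = {
        for (id in eng$load_order) notify_module(eng, eng$modules[[id]], "PERIOD", ev)
      })
    # subscription-based delivery for every kind (including the above)
    for (id in eng$load_order) {
      mod <- eng$modules[[id]]
      if (ev$kind %in% mod$def$subscribes) notify_module(eng, mod, "EVENT", ev)
    }
  }
  eng$events_processed <- eng$events_processed + length(q)
  length(q)
}

clip_range <- function(v, range) pmin(pmax(v, range[1]), range[2])

#' Run one engine cycle
#'
#' Advances the engine by exactly one cycle: boundary requests, acquire,
#' module executes in load order, FIFO event drain, analog-output emit,
#' recorder and benchmark observers. Mostly useful for instrumented tests
#' and interactive stepping; [run()] drives whole experiments.
#'
#' @param eng Engine.
#' @return Cycle summary: list with `cycle`, `t` (seconds), `events_drained`,
#'   and `nan_outputs` (character vector of ports that produced NaN, flagged
#'   but propagated).
#' @export
run_cycle <- function(eng) {
  stopifnot(inherits(eng, "ll_engine"))
  wall0 <- if (!is.null(eng$benchmarks)) proc.time()[[3]] else NULL
  apply_requests(eng)
  t <- engine_time(eng)
  dt <- eng$period
  nan_ports <- character()

  # (1) acquire
  for (key in names(eng$channels)) {
    ch <- eng$channels[[key]]
    if (!ch$enabled || !(ch$direction %in% c("AI", "DIO"))) next
    src <- eng$sources[[key]]
    raw <- if (is.null(src)) 0 else src(t)
    eng$ports[[key]] <- if (ch$direction == "AI") scale_ai(raw, ch)
                        else clip_range(raw, ch$range)
  }

  # (2) execute, in load order
  for (id in eng$load_order) {
    mod <- eng$modules[[id]]
    if (mod$paused || is.null(mod$def$execute)) next
    inputs <- list()
    for (p in mod$def$inputs)
      inputs[[p]] <- gather_input(eng$ports, eng$incoming[[paste0(id, ".", p)]])
    out <- tryCatch(mod$def$execute(mod, inputs, t, dt, eng),
                    error = function(e)
                      stop(errorCondition(
                        paste0("module '", id, "' failed at cycle ", eng$cycle,
                               ": ", conditionMessage(e)),
                        class = "ll_module_error", module = id,
                        cycle = eng$cycle)))
    for (p in names(out)) {
      v <- out[[p]]
      if (length(v) == 1 && is.nan(v)) nan_ports <- c(nan_ports, paste0(id, ".", p))
      eng$ports[[paste0(id, ".", p)]] <- v
    }
  }

  # (3) drain the event queue
  n_ev <- drain_events(eng, t)

  # (4) emit
  for (key in names(eng$ao)) {
    ch <- eng$channels[[key]]
    v <- gather_input(eng$ports, eng$incoming[[key]])
    if (is.nan(v)) nan_ports <- c(nan_ports, key)   # propagate, never clamp
    else v <- clip_range(v, ch$range)
    eng$ports[[key]] <- v
    trace_push(eng$ao[[key]], v)
  }

  if (length(nan_ports)) eng$nan_cycles <- eng$nan_cycles + 1L

  if (!is.null(eng$recorder) && isTRUE(eng$recorder$active))
    record_engine_cycle(eng$recorder, eng$cycle, eng$ports)

  if (!is.null(eng$benchmarks))
    record_cycle_timing(eng$benchmarks, t, t + (proc.time()[[3]] - wall0))

  eng$cycle <- eng$cycle + 1L
  list(cycle = eng$cycle - 1L, t = t, events_drained = n_ev, nan_outputs = nan_ports)
}

# --- whole-run driver -------------------------------------------------------

#' Run a workspace for a duration of simulated time
#'
#' Invokes the cycle loop for `round(duration * frequency)` cycles. In
#' simulated mode no wall-clock sleeping occurs and the run is fully
#' deterministic given the workspace and seed; in wallclock mode the engine
#' sleeps to each deadline (best effort, no hard guarantee). Module-free
#' workspaces (pure DAQ loopback) are evaluated in vectorized chunks, which
#' makes half-hour characterization runs at 20 kHz practical; the produced
#' traces are identical to the per-cycle path.
#'
#' @param ws Workspace.
#' @param duration Simulated seconds, > 0.
#' @param sources Named list of AI source functions (see [start_engine()]).
#' @param recorder Optional recording handle from [create_recording()];
#'   a trial is started and stopped around the run.
#' @param record_signals Character vector of port endpoints to record.
#' @param downsample Global downsample factor for the recorder (keep cycles
#'   with index divisible by it).
#' @param benchmarks Attach a [new_benchmark_stats()] observer (default TRUE).
#' @param chunk Chunk length in cycles for the vectorized path.
#' @return An `ll_run` list: `log` (the run log), `engine`, `ao` (named list
#'   of analog-output traces), `benchmarks`, and `trial` (recorder metadata,
#'   if recording).
#' @export
run <- function(ws, duration, sources = list(), recorder = NULL,
                record_signals = character(), downsample = 1L,
                benchmarks = TRUE, chunk = 1000000L) {
  stopifnot(inherits(ws, "ll_workspace"))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  n <- as.integer(round(duration * ws$engine$frequency))
  if (n < 1L) stop("duration shorter than one cycle period")
  eng <- start_engine(ws, sources)
  if (benchmarks) eng$benchmarks <- new_benchmark_stats(eng$period)
  trial <- NULL
  if (!is.null(recorder)) {
    h <- start_trial(recorder, ws, signals = record_signals, downsample = downsample)
    eng$recorder <- h
  }
  fast <- eng$mode == "simulated" && length(eng$modules) == 0L &&
    length(eng$queue) == 0L && length(eng$requests) == 0L
  log <- list(n_cycles = 0L, frequency = eng$frequency, start_time = 0,
              end_time = NA_real_, termination = "error",
              events_processed = 0L, nan_cycles = 0L)
  finish <- function() {
    log$n_cycles <<- eng$cycle
    log$end_time <<- engine_time(eng)
    log$events_processed <<- eng$events_processed
    log$nan_cycles <<- eng$nan_cycles
  }
  res <- tryCatch({
    if (fast) run_chunked(eng, n, chunk)
    else {
      wall_start <- proc.time()[[3]]
      for (k in seq_len(n)) {
        run_cycle(eng)
        if (eng$mode == "wallclock") {
          ahead <- eng$cycle * eng$period - (proc.time()[[3]] - wall_start)
          if (ahead > 0) Sys.sleep(ahead)
        }
      }
    }
    log$termination <- "completed"
    NULL
  }, error = function(e) e)
  finish()
  if (!is.null(res)) {
    if (!is.null(eng$recorder)) try(stop_trial(eng$recorder), silent = TRUE)
    stop(errorCondition(conditionMessage(res), class = "ll_run_error",
                        log = log, call = sys.call()))
  }
  if (!is.null(eng$recorder)) trial <- stop_trial(eng$recorder)
  structure(list(log = log, engine = eng,
                 ao = lapply(eng$ao, trace_values),
                 benchmarks = eng$benchmarks, trial = trial),
            class = "ll_run")
}

#' @export
print.ll_run <- function(x, ...) {
  cat("<ll_run> ", x$log$n_cycles, " cycles @ ", x$log$frequency, " Hz (",
      format(x$log$end_time), " s simulated), ", x$log$termination, "\n", sep = "")
  cat("  events processed: ", x$log$events_processed,
      ", cycles with NaN outputs: ", x$log$nan_cycles, "\n", sep = "")
  invisible(x)
}

# Vectorized evaluation for module-free (pure loopback) workspaces. Cycle
# semantics collapse to acquire + emit; results are identical to the
# per-cycle path because no module, event, or request can intervene.
run_chunked <- function(eng, n, chunk) {
  ai_keys <- names(eng$channels)[vapply(eng$channels, function(ch)
    ch$enabled && ch$direction %in% c("AI", "DIO"), logical(1))]
  for (key in names(eng$ao)) {
    tr <- eng$ao[[key]]
    tr$values <- numeric(n)
  }
  k0 <- 0L
  chunk <- as.integer(chunk)
  while (k0 < n) {
    k1 <- min(k0 + chunk, n)
    tt <- (k0:(k1 - 1L)) * eng$period
    vals <- list()
    for (key in ai_keys) {
      ch <- eng$channels[[key]]
      src <- eng$sources[[key]]
      raw <- if (is.null(src)) numeric(length(tt)) else src(tt)
      vals[[key]] <- if (ch$direction == "AI") scale_ai(raw, ch)
                     else clip_range(raw, ch$range)
    }
    for (key in names(eng$ao)) {
      ch <- eng$channels[[key]]
      srcs <- eng$incoming[[key]]
      v <- numeric(length(tt))
      for (s in srcs) v <- v + (if (is.null(vals[[s]])) 0 else vals[[s]])
      nan <- is.nan(v)
      v[!nan] <- clip_range(v[!nan], ch$range)
      if (any(nan)) eng$nan_cycles <- eng$nan_cycles + sum(nan)
      tr <- eng$ao[[key]]
      tr$values[(k0 + 1L):k1] <- v
      tr$n <- k1
      vals[[key]] <- v
    }
    if (!is.null(eng$recorder) && isTRUE(eng$recorder$active))
      record_chunk(eng$recorder, k0, vals, k1 - k0)
    if (!is.null(eng$benchmarks))
      record_timing_bulk(eng$benchmarks, k1 - k0)
    # keep port table consistent with the last evaluated cycle
    for (key in c(ai_keys, names(eng$ao)))
      if (!is.null(vals[[key]])) eng$ports[[key]] <- vals[[key]][length(tt)]
    eng$cycle <- k1
    k0 <- k1
  }
  invisible(eng)
}
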