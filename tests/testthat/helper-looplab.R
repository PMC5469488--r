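# Shared builders for the suite. Instrumented module types are registered
# once per session (overwrite = TRUE keeps re-sourcing idempotent).

loopback_ws <- function(frequency = 20000, seed = 1L) case1_workspace(frequency, seed)

# constant-output generator whose execute invocations are counted
define_module_type("t_const", outputs = "out",
  params = list(value = 1),
  init = function(mod, engine) mod$n_exec <- 0L,
  execute = function(mod, inputs, t, dt, engine) {
    mod$n_exec <- mod$n_exec + 1L
    list(out = mod$params$value)
  },
  overwrite = TRUE)

# pass-through that logs the cycle at which each input value arrives
define_module_type("t_relay", inputs = "in", outputs = "out",
  init = function(mod, engine) mod$seen <- numeric(),
  execute = function(mod, inputs, t, dt, engine) {
    mod$seen <- c(mod$seen, inputs[["in"]])
    list(out = inputs[["in"]])
  },
  overwrite = TRUE)

# posts a custom event during execute at a configured cycle
define_module_type("t_poster", outputs = "out",
  params = list(post_at = 0),
  execute = function(mod, inputs, t, dt, engine) {
    if (engine$cycle == mod$params$post_at)
      post_event(engine, "custom", source = mod$id,
                 payload = list(tag = mod$id))
    list(out = 0)
  },
  overwrite = TRUE)

# subscriber that logs (execute/update, cycle) pairs; optionally re-posts
# one event from inside the drain
define_module_type("t_listener", outputs = "out",
  params = list(repost = 0),
  subscribes = "custom",
  init = function(mod, engine) {
    mod$log <- list()
    mod$reposted <- FALSE
  },
  execute = function(mod, inputs, t, dt, engine) {
    mod$log[[length(mod$log) + 1L]] <- list(what = "execute", cycle = engine$cycle)
    list(out = 0)
  },
  update = function(mod, flag, event, engine) {
    if (flag != "EVENT") return()
    mod$log[[length(mod$log) + 1L]] <-
      list(what = "update", cycle = engine$cycle, source = event$source,
           posted = event$cycle)
    if (mod$params$repost > 0 && !mod$reposted) {
      mod$reposted <- TRUE
      post_event(engine, "custom", source = mod$id, payload = list(tag = "repost"))
    }
  },
  overwrite = TRUE)

# PERIOD-sensitive module: recomputes a window length in samples
define_module_type("t_windowed", outputs = "out",
  params = list(window_s = 0.010),
  init = function(mod, engine)
    mod$window_n <- round(mod$params$window_s * engine$frequency),
  execute = function(mod, inputs, t, dt, engine) list(out = mod$window_n),
  update = function(mod, flag, event, engine) {
    if (flag == "PERIOD") {
      mod$n_period_events <- (mod$n_period_events %||% 0L) + 1L
      mod$window_n <- round(mod$params$window_s * engine$frequency)
    }
  },
  overwrite = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip bookkeeping attributes before workspace comparisons
norm_ws <- function(ws) {
  attr(ws, "connection_id") <- NULL
  ws
}

random_workspace <- function(seed) {
  set.seed(seed)
  ws <- new_workspace(frequency = sample(c(1000, 2000, 10000, 20000), 1),
                      mode = sample(c("simulated", "wallclock"), 1),
                      seed = sample.int(1000, 1))
  for (i in seq_len(sample(0:3, 1)))
    ws <- tryCatch(add_channel(ws, i - 1, sample(c("AI", "AO", "DIO"), 1),
                               mode = sample(c("ground_referenced", "differential"), 1),
                               range = sort(stats::runif(2, -12, 12)),
                               gain = stats::runif(1, 0.5, 2),
                               offset = stats::runif(1, -1, 1),
                               enabled = sample(c(TRUE, FALSE), 1)),
                   error = function(e) ws)
  types <- c("signal_generator", "hh_neuron", "spike_detector", "dynamic_clamp")
  for (i in seq_len(sample(0:3, 1))) {
    ty <- sample(types, 1)
    params <- switch(ty,
      signal_generator = list(kind = sample(c("dc", "sine", "square"), 1),
                              value = stats::runif(1), amplitude = stats::runif(1),
                              frequency = stats::runif(1, 1, 100)),
      hh_neuron = list(gNa = stats::runif(1, 100, 140)),
      spike_detector = list(threshold = stats::runif(1, -30, 0)),
      dynamic_clamp = list(G_leak = stats::runif(1, -80, 80)))
    ws <- add_module(ws, ty, params = params)
  }
  # wire some random legal connections
  outs <- character(); ins <- character()
  for (m in ws$modules) {
    def <- module_type(m$type)
    outs <- c(outs, paste0(m$id, ".", def$outputs))
    ins <- c(ins, paste0(m$id, ".", def$inputs))
  }
  for (key in names(ws$channels)) {
    ch <- ws$channels[[key]]
    if (ch$direction == "AI") outs <- c(outs, key)
    if (ch$direction == "AO") ins <- c(ins, key)
  }
  if (length(outs) && length(ins))
    for (i in seq_len(sample(0:4, 1))) {
      ws <- tryCatch(connect(ws, sample(outs, 1), sample(ins, 1)),
                     error = function(e) ws)
    }
  norm_ws(ws)
}
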