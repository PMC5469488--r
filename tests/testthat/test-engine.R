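test_that("SISO loopback passes samples through within the same cycle", {
  ws <- loopback_ws()
  eng <- start_engine(ws, sources = list(AI0 = function(t) rep(2.5, length(t))))
  s <- run_cycle(eng)
  expect_identical(s$cycle, 0L)
  expect_identical(looplab:::trace_values(eng$ao$AO0), 2.5)
  # AI scaling applies before the loop: gain 2, offset 0.5 -> 5.5 clipped
  ws2 <- new_workspace()
  ws2 <- add_channel(ws2, 0, "AI", gain = 2, offset = 0.5, range = c(-4, 4))
  ws2 <- add_channel(ws2, 0, "AO")
  ws2 <- connect(ws2, "AI0", "AO0")
  eng2 <- start_engine(ws2, sources = list(AI0 = function(t) rep(2.5, length(t))))
  run_cycle(eng2)
  expect_identical(looplab:::trace_values(eng2$ao$AO0), 4)   # clipped at AI
})

test_that("chunked and per-cycle evaluation produce identical traces", {
  pt <- make_pulse_train(0.5, 5, seed = 11)
  ws <- loopback_ws(frequency = 5000)
  fast <- run(ws, 0.5, sources = list(AI0 = pt$signal), chunk = 777L)
  eng <- start_engine(ws, sources = list(AI0 = pt$signal))
  for (k in seq_len(2500)) run_cycle(eng)
  expect_identical(fast$ao$AO0, looplab:::trace_values(eng$ao$AO0))
  expect_identical(fast$log$n_cycles, 2500L)
})

test_that("events post during execute and drain after all executes, same cycle", {
  ws <- new_workspace(frequency = 1000)
  ws <- add_module(ws, "t_poster", id = "A", params = list(post_at = 3))
  ws <- add_module(ws, "t_listener", id = "B")
  eng <- start_engine(ws)
  for (k in 1:6) run_cycle(eng)
  log <- eng$modules$B$log
  upd <- Filter(function(e) e$what == "update", log)
  expect_length(upd, 1L)
  expect_identical(upd[[1]]$cycle, 3L)      # same cycle as the post
  expect_identical(upd[[1]]$posted, 3L)
  # within cycle 3, B's execute precedes B's update
  kinds <- vapply(Filter(function(e) e$cycle == 3L, log), `[[`, "", "what")
  expect_identical(kinds, c("execute", "update"))
})

test_that("event queue drains FIFO in module load order", {
  ws <- new_workspace(frequency = 1000)
  ws <- add_module(ws, "t_poster", id = "A", params = list(post_at = 1))
  ws <- add_module(ws, "t_poster", id = "B", params = list(post_at = 1))
  ws <- add_module(ws, "t_listener", id = "C")
  eng <- start_engine(ws)
  run_cycle(eng); run_cycle(eng)
  srcs <- vapply(Filter(function(e) e$what == "update", eng$modules$C$log),
                 `[[`, "", "source")
  expect_identical(srcs, c("A", "B"))
})

test_that("events posted while draining are deferred to the next cycle", {
  ws <- new_workspace(frequency = 1000)
  ws <- add_module(ws, "t_poster", id = "A", params = list(post_at = 2))
  ws <- add_module(ws, "t_listener", id = "B", params = list(repost = 1))
  eng <- start_engine(ws)
  for (k in 1:5) run_cycle(eng)
  upd <- Filter(function(e) e$what == "update", eng$modules$B$log)
  expect_length(upd, 2L)
  expect_identical(upd[[1]]$cycle, 2L)      # original event
  expect_identical(upd[[2]]$cycle, 3L)      # reposted during drain -> next cycle
})

test_that("paused modules keep their last output and skip execute", {
  ws <- new_workspace(frequency = 1000)
  ws <- add_channel(ws, 0, "AO")
  ws <- add_module(ws, "t_const", id = "gen", params = list(value = 1.25))
  ws <- connect(ws, "gen.out", "AO0")
  eng <- start_engine(ws)
  run_cycle(eng); run_cycle(eng)
  pause_module(eng, "gen")
  run_cycle(eng); run_cycle(eng)
  expect_identical(eng$modules$gen$n_exec, 2L)
  expect_identical(looplab:::trace_values(eng$ao$AO0), rep(1.25, 4))
  pause_module(eng, "gen", paused = FALSE)
  run_cycle(eng)
  expect_identical(eng$modules$gen$n_exec, 3L)
})

test_that("modules load and unload at cycle boundaries without halting the loop", {
  ws <- new_workspace(frequency = 1000)
  ws <- add_channel(ws, 0, "AO", range = c(-100, 100))
  ws <- add_module(ws, "t_const", id = "g1", params = list(value = 1))
  ws <- add_module(ws, "t_const", id = "g2", params = list(value = 10))
  ws <- connect(ws, "g1.out", "AO0")
  ws <- connect(ws, "g2.out", "AO0")
  eng <- start_engine(ws)
  run_cycle(eng)                              # cycle 0: 11
  id <- load_module(eng, "t_const", id = "g3", params = list(value = 100))
  expect_identical(id, "g3")
  run_cycle(eng)                              # cycle 1: g3 loaded+executes
  expect_identical(eng$modules$g3$n_exec, 1L)
  unload_module(eng, "g2")
  run_cycle(eng)                              # cycle 2: g2 gone, g1 still summed
  expect_identical(looplab:::trace_values(eng$ao$AO0), c(11, 11, 1))
  expect_null(eng$modules$g2)
  expect_error(unload_module(eng, "g2"), "non-existent")
  expect_error(load_module(eng, "t_const", params = list(bogus = 1)),
               "invalid parameter")
})

test_that("run computes round(duration x frequency) cycles", {
  ws <- loopback_ws(frequency = 20000)
  expect_identical(run(ws, 1, benchmarks = FALSE)$log$n_cycles, 20000L)
  ws2 <- loopback_ws(frequency = 2000)
  expect_identical(run(ws2, 0.0005, benchmarks = FALSE)$log$n_cycles, 1L)
  expect_error(run(ws2, 0), "duration")
})

test_that("set_period rescales dependent module state before the next execute", {
  ws <- new_workspace(frequency = 20000)
  expect_equal(ws$engine$period, 50e-6, tolerance = 1e-12)
  ws <- add_channel(ws, 0, "AO", range = c(-1000, 1000))
  ws <- add_module(ws, "t_windowed", id = "w")   # 10 ms window
  ws <- connect(ws, "w.out", "AO0")
  eng <- start_engine(ws)
  run_cycle(eng)
  set_period(eng, 2000)
  run_cycle(eng)                               # boundary applies + executes
  ao <- looplab:::trace_values(eng$ao$AO0)
  expect_identical(ao, c(200, 20))             # 10 ms = 200 then 20 samples
  expect_identical(eng$modules$w$n_period_events, 1L)
  # idempotence: same frequency again -> no notification
  set_period(eng, 2000)
  run_cycle(eng)
  expect_identical(eng$modules$w$n_period_events, 1L)
  expect_error(set_period(eng, 0), "positive")
})

test_that("load order only shifts same-cycle visibility by one cycle", {
  build <- function(order) {
    ws <- new_workspace(frequency = 1000)
    ws <- add_channel(ws, 0, "AO")
    mods <- list(
      gen = function(w) add_module(w, "t_const", id = "gen", params = list(value = 3)),
      relay = function(w) add_module(w, "t_relay", id = "relay"))
    for (nm in order) ws <- mods[[nm]](ws)
    ws <- connect(ws, "gen.out", "relay.in")
    connect(ws, "relay.out", "AO0")
  }
  up_first <- start_engine(build(c("gen", "relay")))
  down_first <- start_engine(build(c("relay", "gen")))
  for (k in 1:4) { run_cycle(up_first); run_cycle(down_first) }
  expect_identical(up_first$modules$relay$seen, rep(3, 4))
  expect_identical(down_first$modules$relay$seen, c(0, 3, 3, 3))  # one-cycle skew
})

test_that("identical seeded runs are identical", {
  pt <- make_pulse_train(0.3, 3, seed = 5)
  ws <- case3_workspace(frequency = 5000)
  r1 <- run(ws, 0.3, sources = list(AI0 = pt$signal), benchmarks = FALSE)
  r2 <- run(ws, 0.3, sources = list(AI0 = pt$signal), benchmarks = FALSE)
  expect_identical(r1$ao, r2$ao)
})

test_that("module errors abort the run with module id, cycle, and a partial log", {
  define_module_type("t_bomb", outputs = "out",
    params = list(fail_at = 4),
    execute = function(mod, inputs, t, dt, engine) {
      if (engine$cycle >= mod$params$fail_at) stop("boom")
      list(out = 0)
    }, overwrite = TRUE)
  ws <- new_workspace(frequency = 1000)
  ws <- add_module(ws, "t_bomb", id = "bomb")
  err <- tryCatch(run(ws, 0.01, benchmarks = FALSE), error = function(e) e)
  expect_s3_class(err, "ll_run_error")
  expect_match(conditionMessage(err), "bomb")
  expect_match(conditionMessage(err), "cycle 4")
  expect_identical(err$log$n_cycles, 4L)
  expect_identical(err$log$termination, "error")
})

test_that("NaN outputs propagate to AO and are flagged, never clamped", {
  define_module_type("t_nan", outputs = "out",
    execute = function(mod, inputs, t, dt, engine) list(out = NaN),
    overwrite = TRUE)
  ws <- new_workspace(frequency = 1000)
  ws <- add_channel(ws, 0, "AO", range = c(-1, 1))
  ws <- add_module(ws, "t_nan", id = "n")
  ws <- connect(ws, "n.out", "AO0")
  eng <- start_engine(ws)
  s <- run_cycle(eng)
  expect_true(all(c("n.out", "AO0") %in% s$nan_outputs))
  expect_true(is.nan(looplab:::trace_values(eng$ao$AO0)))
})

test_that("post_event validates the source module id", {
  eng <- start_engine(loopback_ws())
  expect_error(post_event(eng, "custom", source = "nope"), "unknown source")
  expect_error(post_event(eng, "frobnicate"), "unknown event kind")
  expect_silent(post_event(eng, "custom"))
})
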