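simple_ws <- function() {
  ws <- new_workspace(frequency = 1000)
  ws <- add_channel(ws, 0, "AI", gain = 2)
  ws <- add_channel(ws, 0, "AO")
  ws <- add_module(ws, "signal_generator", id = "gen",
                   params = list(kind = "dc", value = 1.5))
  connect(ws, "gen.out", "AO0")
}

test_that("trials are numbered sequentially; append/overwrite is explicit", {
  path <- withr::local_tempfile(fileext = ".h5")
  ws <- simple_ws()
  rec <- create_recording(path)
  for (i in 1:2) {
    h <- start_trial(rec, ws, signals = "gen.out")
    record_cycle(h, 0L, 1.5)
    stop_trial(h)
  }
  expect_identical(count_trials(path), 2L)
  expect_error(create_recording(path), "append|overwrite")
  rec2 <- create_recording(path, append = TRUE)
  h <- start_trial(rec2, ws, signals = "gen.out")
  expect_identical(h$trial, 3L)
  stop_trial(h)
  rec3 <- create_recording(path, overwrite = TRUE)
  h <- start_trial(rec3, ws, signals = "gen.out")
  expect_identical(h$trial, 1L)
  stop_trial(h)
  expect_identical(count_trials(path), 1L)
})

test_that("downsampling stores ceil(n_cycles / k) rows", {
  path <- withr::local_tempfile(fileext = ".h5")
  ws <- simple_ws()
  cases <- rbind(c(100, 10), c(101, 10), c(100, 1), c(7, 3), c(0, 5))
  set.seed(17)
  cases <- rbind(cases, cbind(sample(1:200, 10), sample(1:13, 10, replace = TRUE)))
  for (i in seq_len(nrow(cases))) {
    n <- cases[i, 1]; k <- cases[i, 2]
    rec <- create_recording(path, overwrite = TRUE)
    h <- start_trial(rec, ws, signals = "gen.out", downsample = k)
    for (cyc in seq_len(n) - 1L) record_cycle(h, cyc, 0.5)
    out <- stop_trial(h)
    expect_identical(out$rows, as.integer(ceiling(n / k)),
                     info = sprintf("n=%d k=%d", n, k))
    expect_identical(out$n_cycles, as.integer(n))
  }
  rec <- create_recording(path, overwrite = TRUE)
  expect_error(start_trial(rec, ws, signals = "gen.out", downsample = 0),
               "positive integer")
})

test_that("value count mismatches and unresolved signals are rejected", {
  path <- withr::local_tempfile(fileext = ".h5")
  rec <- create_recording(path)
  ws <- simple_ws()
  expect_error(start_trial(rec, ws, signals = "gen.nope"), "resolve")
  h <- start_trial(rec, ws, signals = c("gen.out", "AO0"))
  expect_error(record_cycle(h, 0L, 1), "mismatch")
  stop_trial(h)
  expect_error(stop_trial(h), "already stopped")
})

test_that("a written trial reads back exactly", {
  path <- withr::local_tempfile(fileext = ".h5")
  ws <- simple_ws()
  rec <- create_recording(path)
  h <- start_trial(rec, ws, signals = c("gen.out", "AO0"), downsample = 2)
  vals <- matrix(stats::rnorm(20), ncol = 2)
  for (cyc in 0:9) record_cycle(h, cyc, vals[cyc + 1, ])
  add_tag(h, 0.003, "stimulus on")
  add_tag(h, 0.007, "stimulus off")
  log_param_change(h, 0.004, "gen", "value", 2.5)
  log_param_change(h, 0.004, "gen", "amplitude", 0.1)   # same-cycle, in order
  expect_error(log_param_change(h, 0.005, "gen", "nope", 1), "unknown parameter")
  stop_trial(h)

  tr <- read_trial(path, 1)
  expect_identical(unname(tr$data), vals[seq(1, 9, by = 2), ])  # bitwise
  expect_identical(colnames(tr$data), c("gen.out", "AO0"))
  expect_equal(tr$period, 1e-3)
  expect_equal(tr$downsample, 2L)
  expect_equal(tr$stop_time, 10 * 1e-3)
  expect_identical(tr$parameters$initial[["gen.value"]], 1.5)
  expect_identical(tr$parameters$initial[["gen.kind"]], "dc")
  expect_identical(unname(tr$parameters$changes[["gen.value"]][, "value"]), 2.5)
  expect_identical(tr$tags$text, c("stimulus on", "stimulus off"))
  expect_identical(tr$tags$time, c(0.003, 0.007))
  expect_identical(rownames(tr$system_settings$channels), "AI0")
  expect_equal(tr$system_settings$channels[1, "gain"], 2, ignore_attr = TRUE)
})

test_that("on-the-fly parameter changes log with timestamps and apply via MODIFY", {
  path <- withr::local_tempfile(fileext = ".h5")
  ws <- simple_ws()
  eng <- start_engine(ws)
  rec <- create_recording(path)
  h <- start_trial(rec, ws, signals = "gen.out")
  eng$recorder <- h
  run_cycle(eng)                        # cycle 0 at old value
  set_param(eng, "gen", "value", 9)     # event drains during cycle 1
  run_cycle(eng)
  run_cycle(eng)                        # first execute at the new value
  stop_trial(h)
  expect_identical(eng$modules$gen$params$value, 9)
  tr <- read_trial(path, 1)
  ch <- tr$parameters$changes[["gen.value"]]
  expect_identical(unname(ch[1, "value"]), 9)
  expect_equal(unname(ch[1, "time"]), 1e-3)   # drained in cycle 1
  # the change reached the module after cycle 1's execute, so the recorded
  # trace shows the new value from cycle 2 on
  expect_identical(unname(tr$data[, 1]), c(1.5, 1.5, 9))
})

test_that("changes while the recorder is idle update the module but log nothing", {
  ws <- simple_ws()
  eng <- start_engine(ws)
  set_param(eng, "gen", "value", 4)
  run_cycle(eng)
  expect_identical(eng$modules$gen$params$value, 4)
  expect_null(eng$recorder)
})

test_that("randomized trials round-trip through HDF5", {
  path <- withr::local_tempfile(fileext = ".h5")
  ws <- simple_ws()
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(0:60, 1); k <- sample(1:5, 1)
    rec <- create_recording(path, overwrite = TRUE)
    h <- start_trial(rec, ws, signals = c("gen.out", "AO0"), downsample = k)
    vals <- matrix(stats::rnorm(2 * n), ncol = 2)
    for (cyc in seq_len(n) - 1L) record_cycle(h, cyc, vals[cyc + 1L, ])
    nt <- sample(0:3, 1)
    for (j in seq_len(nt)) add_tag(h, j * 1e-3, paste("tag", j))
    stop_trial(h)
    tr <- read_trial(path, 1)
    keep <- seq_len(n)[(seq_len(n) - 1L) %% k == 0L]
    expect_identical(unname(tr$data), vals[keep, , drop = FALSE])
    expect_identical(nrow(tr$tags), nt)
  }
})
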