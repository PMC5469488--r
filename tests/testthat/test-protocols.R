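test_that("signal generator produces the standard waveforms", {
  expect_identical(signal_generator("dc", list(value = 1.2), c(0, 5, 99)),
                   rep(1.2, 3))
  # 5 Vpp square, 50% duty: mid-high-phase sits at +2.5 V, mid-low at -2.5 V
  expect_identical(signal_generator("square", list(vpp = 5, frequency = 1), 0.25), 2.5)
  expect_identical(signal_generator("square", list(vpp = 5, frequency = 1), 0.75), -2.5)
  expect_equal(signal_generator("sine", list(amplitude = 3, frequency = 7), 0), 0)
  expect_error(signal_generator("wiggle", list(), 0), "unknown signal kind")
  pt <- signal_generator("pulse_train",
                         list(onsets = c(0.1, 0.5), width = 0.1, level = 5),
                         c(0, 0.15, 0.25, 0.55, 0.9))
  expect_identical(pt, c(0, 5, 0, 5, 0))
  fw <- signal_generator("file_waveform", list(samples = c(1, 2, 3), rate = 10),
                         c(0, 0.1, 0.25, 0.31))
  expect_identical(fw, c(1, 2, 3, 0))
})

test_that("HH neuron rests quietly at I = 0 and matches a fine-step reference", {
  skip_if_not_installed("deSolve")
  p <- hh_params()
  # independent reference: adaptive LSODA on the same vector field
  ref <- function(I, times) {
    deriv <- function(t, y, parms) {
      V <- y[1]
      xm <- V + 40; xn <- V + 55
      am <- if (abs(xm) < 1e-7) 1 else 0.1 * xm / (1 - exp(-xm / 10))
      bm <- 4 * exp(-(V + 65) / 18)
      ah <- 0.07 * exp(-(V + 65) / 20)
      bh <- 1 / (1 + exp(-(V + 35) / 10))
      an <- if (abs(xn) < 1e-7) 0.1 else 0.01 * xn / (1 - exp(-xn / 10))
      bn <- 0.125 * exp(-(V + 65) / 80)
      list(c((I - p$gNa * y[2]^3 * y[3] * (V - p$ENa) - p$gK * y[4]^4 * (V - p$EK) -
                p$gL * (V - p$EL)) / p$Cm,
             am * (1 - y[2]) - bm * y[2],
             ah * (1 - y[3]) - bh * y[3],
             an * (1 - y[4]) - bn * y[4]))
    }
    deSolve::lsoda(unname(hh_steady_state(-65, p)), times, deriv, NULL,
                   rtol = 1e-10, atol = 1e-10)
  }
  # 500 ms at rest: V settles near the resting potential, no spikes
  st <- hh_steady_state(-65, p)
  for (i in 1:10000) st <- hh_step(st, 0, 5e-5, p)
  refV <- ref(0, c(0, 500))[2, 2]
  expect_lt(abs(st[["V"]] - refV), 0.1)
  expect_lt(abs(st[["V"]] + 65), 2)

  # sustained 10 uA/cm^2: repetitive spiking with matching spike times
  times <- seq(0, 1000, by = 0.05)          # ms
  refsol <- ref(10, times)
  ref_spikes <- times[which(diff(sign(refsol[, 2])) == 2)] / 1000
  st <- hh_steady_state(-65, p)
  ours <- numeric(20000); prev <- st[["V"]]
  our_spikes <- c()
  for (i in 1:20000) {
    st <- hh_step(st, 10, 5e-5, p)
    if (prev < 0 && st[["V"]] >= 0) our_spikes <- c(our_spikes, i * 5e-5)
    prev <- st[["V"]]
  }
  expect_gt(length(our_spikes), 0)
  expect_identical(length(our_spikes), length(ref_spikes))
  expect_lt(max(abs(our_spikes - ref_spikes)), 1e-3)
})

test_that("halving the integrator substep moves spike times by < 1 ms", {
  p <- hh_params()
  spikes <- function(max_substep) {
    st <- hh_steady_state(-65, p); prev <- st[["V"]]; out <- c()
    for (i in 1:10000) {
      st <- hh_step(st, 10, 5e-5, p, max_substep = max_substep)
      if (prev < 0 && st[["V"]] >= 0) out <- c(out, i * 5e-5)
      prev <- st[["V"]]
    }
    out
  }
  s50 <- spikes(50e-6); s25 <- spikes(25e-6)
  expect_identical(length(s50), length(s25))
  expect_lt(max(abs(s50 - s25)), 1e-3)
})

test_that("gates stay in [0, 1] for arbitrary states and currents", {
  set.seed(13)
  for (i in 1:50) {
    st <- c(V = stats::runif(1, -90, 40), m = stats::runif(1),
            h = stats::runif(1), n = stats::runif(1))
    I <- stats::runif(1, -30, 60)
    for (k in 1:20) st <- hh_step(st, I, 1e-4)
    expect_true(all(st[c("m", "h", "n")] >= 0 & st[c("m", "h", "n")] <= 1))
    expect_true(is.finite(st[["V"]]))
  }
  expect_error(hh_step(c(V = NaN, m = 0, h = 0, n = 0), 0, 1e-4), "non-finite")
  expect_error(hh_step(hh_steady_state(-65), 0, 0), "dt must be")
})

test_that("spike detector fires once per crossing, honouring the refractory", {
  det <- new_spike_detector(threshold = 0, refractory = 0.001,
                            pulse_width = 0.0005, pulse_level = 5)
  # constant below threshold: always 0
  out <- vapply(1:100, function(i) spike_detect(-50, det, i * 1e-4), numeric(1))
  expect_identical(unique(out), 0)
  expect_identical(det$n_spikes, 0L)

  # a single synthetic spike: exactly one pulse of the configured width
  det <- new_spike_detector(0, 0.001, 0.0005, 5)
  V <- c(rep(-60, 10), seq(-60, 30, length.out = 5), seq(30, -60, length.out = 5),
         rep(-60, 20))
  out <- vapply(seq_along(V), function(i) spike_detect(V[i], det, i * 1e-4), numeric(1))
  expect_identical(det$n_spikes, 1L)
  expect_identical(sum(diff(c(0, out) > 2.5) == 1), 1L)
  expect_identical(sum(out > 0) * 1e-4, 0.0005)

  # sinusoid crossing threshold 5 times, refractory shorter than the period:
  # brute-force count of armed upward crossings is the oracle
  dt <- 1e-4
  t <- seq(0, 0.5 - dt, by = dt)
  V <- 40 * sin(2 * pi * 10 * t) - 10          # crosses 0 upward 5 times
  oracle <- sum(diff(V >= 0) == 1)
  det <- new_spike_detector(0, 0.002, 0.0005, 5)
  for (i in seq_along(t)) spike_detect(V[i], det, t[i])
  expect_identical(det$n_spikes, as.integer(oracle))
  expect_identical(oracle, 5L)
})

test_that("dynamic clamp current follows I = -G(V - E) with the stated sign", {
  expect_identical(dynamic_clamp_current(-65, -60, -65), 0)       # V == E
  expect_identical(dynamic_clamp_current(-40, 0, -65), 0)         # G == 0
  # G_leak = -60 nS, V - E = +10 mV -> +600 pA, depolarizing
  expect_identical(dynamic_clamp_current(-55, -60, -65), 600)
  expect_identical(dynamic_clamp_current(-75, -60, -65), -600)
})

test_that("case 3 closed loop: pulses during events, silence between them", {
  dur <- 1.2
  pt <- make_pulse_train(dur, 3, width = 0.06, seed = 8)
  ws <- case3_workspace(frequency = 10000)
  res <- run(ws, dur, sources = list(AI0 = pt$signal), benchmarks = FALSE)
  ttl <- res$ao$AO0
  tt <- (seq_along(ttl) - 1) / 10000
  edges <- tt[detect_edges(ttl, 2.5)]
  # every suprathreshold trigger event yields at least one TTL pulse
  for (on in pt$onsets)
    expect_true(any(edges >= on & edges <= on + 0.06 + 0.005))
  # no pulses outside events (allowing the spike in flight at pulse end)
  in_event <- vapply(edges, function(e)
    any(e >= pt$onsets & e <= pt$onsets + 0.06 + 0.005), logical(1))
  expect_true(all(in_event))
})
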