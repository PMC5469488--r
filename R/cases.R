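# Pre-wired characterization cases: the loopback / MIMO / neuron-in-the-loop
# configurations used to exercise the engine end to end, each driven by the
# seeded random trigger train.

#' Case 1: single-input single-output loopback workspace
#'
#' One AI channel mirrored to one AO channel with no processing in the
#' loop, at 20 kHz.
#'
#' @param frequency Engine rate, Hz. @param seed Engine seed.
#' @return Workspace.
#' @export
case1_workspace <- function(frequency = 20000, seed = 1L) {
  ws <- new_workspace(frequency = frequency, seed = seed)
  ws <- add_channel(ws, 0, "AI")
  ws <- add_channel(ws, 0, "AO")
  connect(ws, "AI0", "AO0")
}

#' Case 2: two-in two-out loopback workspace
#'
#' As case 1 plus a second AI (left floating, modelled as a constant 0 V)
#' connected directly to a second AO.
#'
#' @inheritParams case1_workspace
#' @return Workspace.
#' @export
case2_workspace <- function(frequency = 20000, seed = 1L) {
  ws <- case1_workspace(frequency, seed)
  ws <- add_channel(ws, 1, "AI")
  ws <- add_channel(ws, 1, "AO")
  connect(ws, "AI1", "AO1")
}

#' Case 3: trigger -> neuron -> spike detector -> AO workspace
#'
#' The trigger signal drives a Hodgkin-Huxley neuron; its membrane
#' potential feeds a threshold-crossing spike detector whose TTL pulse
#' leaves through the AO channel.
#'
#' @inheritParams case1_workspace
#' @return Workspace.
#' @export
case3_workspace <- function(frequency = 20000, seed = 1L) {
  ws <- new_workspace(frequency = frequency, seed = seed)
  ws <- add_channel(ws, 0, "AI")
  ws <- add_channel(ws, 0, "AO")
  ws <- add_module(ws, "hh_neuron", id = "neuron")
  ws <- add_module(ws, "spike_detector", id = "det")
  ws <- connect(ws, "AI0", "neuron.input")
  ws <- connect(ws, "neuron.Vm", "det.Vm")
  connect(ws, "det.TTL", "AO0")
}

#' Run a loopback characterization with external-sampler latency analysis
#'
#' Runs the case-1 loopback for `duration` seconds with a seeded random
#' trigger train of `n_events` pulses, then analyses input and output on
#' the external 250 kHz sampler grid: per-event latency (seconds and engine
#' periods) and missed events.
#'
#' @param duration Simulated seconds (the half-hour bench uses 1800).
#' @param n_events Trigger count (the bench uses 1800).
#' @param frequency Engine rate, Hz.
#' @param sampler_rate External sampler rate, Hz.
#' @param seed Seed for the trigger train and engine.
#' @return List: `latency` (per-event data.frame), `missed`, `run` (the
#'   `ll_run`), `events` (trigger onset times).
#' @export
run_loopback_case <- function(duration = 1800, n_events = 1800,
                              frequency = 20000, sampler_rate = 250000,
                              seed = 1L) {
  pt <- make_pulse_train(duration, n_events, seed = seed)
  ws <- case1_workspace(frequency, seed)
  res <- run(ws, duration, sources = list(AI0 = pt$signal))
  lat <- measure_loopback_latency(pt$signal, res$ao$AO0, frequency, duration,
                                  sampler_rate = sampler_rate)
  list(latency = lat$latency, missed = lat$missed, run = res,
       events = pt$onsets)
}
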