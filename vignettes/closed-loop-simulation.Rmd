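---
title: "Cycle semantics, numerics, and design of the looplab engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle semantics, numerics, and design of the looplab engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(looplab)
```

`looplab` simulates the control loop of a hard real-time closed-loop
electrophysiology system: a fixed-rate cycle that acquires analog inputs,
executes a user-configurable graph of processing modules, services a
real-time event queue, and emits analog outputs — with a trial recorder and
benchmark statistics observing every cycle. This vignette is the package's
account of what exactly is simulated, which choices were genuinely open,
and what the numbers produced by the test suite do and do not establish.

## The cycle contract

The engine advances in cycles of period `1/frequency` seconds of
*simulated* time. At 20 kHz each cycle represents a 50 µs budget in which a
real rig must finish input, processing, and output. Within one cycle the
order of effects is fixed:

1. **Acquire.** Every enabled analog-input channel publishes
   `clip(gain · raw + offset, [lo, hi])` of its source signal evaluated at
   `t = k / f`. Digital channels are modelled as 0/5 V analog levels.
2. **Execute.** Every loaded, unpaused module runs exactly once, in load
   order. Each input port reads the *sum* of all connected source ports
   (an unconnected input reads 0; the empty sum), added in ascending
   connection-id order so float results are reproducible under set
   re-enumeration.
3. **Drain.** Events posted during execution are serviced FIFO, after the
   last execute of the cycle, so a parameter change posted by module A is
   observed by module B's update hook in the same cycle but never between
   two executes. Events posted *while draining* are deferred to the next
   cycle — without this rule a pair of modules that notify each other
   could stall a cycle indefinitely.
4. **Emit.** Every enabled analog-output channel emits the clipped value of
   its gathered input, timestamped with the cycle time.

Structural operations — pause/unpause, load/unload, period changes,
parameter writes — are applied at the next cycle boundary, mirroring
platforms that modify a running loop without halting it. Period changes
additionally invoke every module's `PERIOD` update hook *at the boundary*,
before that cycle's executes, so period-dependent state (window lengths in
samples, integrator steps, filter designs) is correct for the first cycle
at the new rate.

Two consequences are worth stating because they are contracts, not
accidents:

* **Load-order skew.** Whether a module reads a same-cycle or
  previous-cycle value from another module depends only on their relative
  load order: a downstream module loaded after its source sees same-cycle
  values; loaded before, it sees the value of the previous cycle (ports
  start at 0). Permuting load order shifts first observation by exactly
  one cycle and never changes the set of values. The engine makes no
  attempt to topologically sort the graph — loops are legal and common
  (the dynamic clamp reads the neuron it drives).
* **Single-sample latency.** In a pure loopback, an input edge that occurs
  strictly inside a cycle is acquired at the next cycle boundary and
  emitted the same cycle, so the externally measured delay never exceeds
  one period. This is the invariant the characterization harness checks.

### Simulated versus wall-clock time

The primary mode is simulated time: the cycle counter times the period.
Every run is then a pure function of (workspace, sources, seed), which is
what makes byte-identical recorder files and property-style testing
possible. A `wallclock` mode sleeps to each deadline for demonstrations,
but an ordinary operating system scheduler cannot bound its jitter, and
the package makes no hard real-time claim for it. The three threads of a
real platform (real-time loop, UI, storage) collapse to one logical
process here: the recorder and benchmark "observers" are called
synchronously after each cycle. Only the observable contract of the
concurrent design is reproduced, not its concurrency.

### Other engine policies

* **NaN policy.** A NaN produced on a port is propagated and flagged in
  the cycle summary, never silently clamped into range; model blow-ups
  should surface, not disappear into a rail voltage.
* **Errors.** A module execute that throws aborts the run with the module
  id and cycle index, and the partial run log is attached to the
  condition.
* **Module-free fast path.** Workspaces with no modules (the loopback
  characterization cases) are evaluated in vectorized chunks of one
  million cycles. Because no module, event, or boundary request can
  intervene, the chunked results are identical to the per-cycle path —
  the equivalence is asserted in the test suite. This is what makes a
  36-million-cycle (30 simulated minutes at 20 kHz) characterization run
  practical in a couple of minutes on one core.

## Persistence

Workspaces round-trip through a versioned XML dialect (engine config,
channel configs, modules with parameter and state values, connections);
numeric values are serialized with 17 significant digits so the round trip
is the identity on doubles. Trials round-trip through plain HDF5 with no
custom filters: `/Trial N` holds a 2-D float64 `Synchronous Data` matrix
(column names as an attribute), a `Parameters` group with one change table
per parameter (initial value as an attribute), the enabled input-channel
configurations under `System Settings`, and experiment `Tags`. Times are
stored as float64 seconds of simulated time; nothing in the file depends
on the wall clock, which is why two identical seeded runs write
byte-identical files. The grouping follows the published layout of such
recorders; the dataset names are this package's own, versioned here rather
than claimed compatible with any external tool.

Downsampling keeps cycles whose index is divisible by k (decimation
without an anti-alias filter, as is conventional for these recorders), so
a trial of n cycles stores `ceiling(n/k)` rows.

## Benchmarks and the hard real-time rule

For each cycle the collector derives the realized period
`p_k = t_start(k) − t_start(k−1)`, the signed jitter `j_k = p_k − nominal`
(the absolute maximum is also reported, since either convention is found
in practice), and the computation time `c_k`. The pass rule is
`max p_k ≤ 2 × nominal`: one realized period above twice nominal means a
deadline was missed and hard real-time behavior is lost. The check is
monotone — more cycles can only preserve or break a pass. In simulated
mode `p_k` equals nominal identically; `c_k` is measured wall-clock of the
cycle body and is informational only (it appears in no assertion, because
it is the one quantity that genuinely depends on the host machine).

## The protocol modules

**Hodgkin–Huxley neuron.** The standard four-dimensional squid-axon model
with the classic constants (`Cm = 1 µF/cm²`, `gNa = 120`, `gK = 36`,
`gL = 0.3 mS/cm²`, `ENa = 50`, `EK = −77`, `EL = −54.4 mV`; resting
potential ≈ −65 mV), all configurable. The input port maps volts to
current density at 10 (µA/cm²)/V by default — the platform being emulated
names the model but not its constants or port scaling, so these are the
field's defaults, stated here once. Integration is classical RK4 at the
engine period with automatic substepping to at most 25 µs per substep:
at 20 kHz that is two substeps, which keeps the upstroke stable without
changing engine semantics; gates are clamped to [0, 1] after every
substep. The test suite compares spike times against an adaptive LSODA
reference integration at tolerances of 1e-10 and requires agreement within
1 ms over a second of repetitive firing.

**Spike detector.** Fires on an upward threshold crossing while armed,
emits a TTL pulse of configurable width, and re-arms only after the
refractory period has elapsed *and* the potential has fallen back below
threshold. The hysteresis re-arm is a choice: a bare "threshold crossing"
rule would double-fire on noisy plateaus.

**Dynamic clamp.** `I = −G_leak (V − E_leak)` in pA (nS × mV), computed
fresh every cycle from the latest potential; positive command current is
depolarizing, so negative `G_leak` adds a *negative* leak conductance and
increases excitability. `E_leak` defaults to the neuron's resting
potential, exposed as a parameter since the emulated experiments do not
publish it. The closed-loop probe `measure_rheobase()` bisects the DC
drive for the smallest spike-eliciting input; its default command scale
maps −60 nS to −0.06 mS/cm² of membrane-density conductance — one fifth
of the model's own leak — because the mapping between a whole-cell
conductance in nS and a density in mS/cm² depends on cell size, which is
not part of the model. With a much larger coupling the one-cycle feedback
delay of the loop can destabilize the integration; the chosen scale keeps
the probe well-behaved while preserving the directional claim (a negative
virtual leak lowers the rheobase), which is the property the suite
asserts.

## The syllable detector

The detector is a two-mode state machine evaluated every millisecond
(1 kHz), the only cadence the emulated system states. Idle mode computes
the RMS of the trailing 10 ms; when it exceeds the gate threshold the
detector switches to triggered mode, where each evaluation computes the
magnitude spectrogram of the trailing 20 ms and its Pearson correlation
with the template spectrogram, fired when r exceeds the correlation
threshold (subject to a refractory). Triggered mode falls back to idle
when the gate closes and no feedback is playing.

STFT settings are not published for the original detector; the defaults
here are a 128-sample Hann window with hop 64 at 30 kHz, restricted to
0.5–10 kHz — resolution fine enough to separate harmonic stacks a few
hundred hertz apart while keeping a 20 ms segment eight frames wide. A
zero-variance spectrogram is defined to correlate 0 with anything
(silence cannot match a template). The refractory defaults to the
feedback-clip duration so the detector cannot retrigger on its own
feedback; muting during playback is available but off by default, since
the emulated rig demonstrably picks its own feedback up on the
microphone.

Two implementations of the same state machine exist deliberately: a
per-sample streaming step (`daf_step()`) and an evaluation-instant run
(`daf_run()`). Their detections are asserted equal, and both are asserted
equal to an offline full scan written independently in the tests. On the
clean synthetic songs the hit rate is 1.0 with zero false positives; note
that the template is the trailing 20 ms of a near-stationary syllable, so
a detection legitimately fires as soon as a full syllable-interior window
is buffered, not only after the syllable ends. What these numbers do *not*
establish is performance on real birdsong — natural acoustic variability,
the very thing that caused the published detectors' misses, is exactly
what the fixtures omit.

## The alpha-feedback controller

Incoming EEG is band-passed with a causal 6th-order Butterworth 8–12 Hz
filter (designed by bilinear transform; the design is rejected at
configuration time if any pole reaches the unit circle). "Mean oscillation
power with a 1 second window" is read as the mean of squared filtered
samples over the trailing second — the simplest reading; a Hilbert
envelope variant is available behind a flag and agrees for narrowband
signals. Calibration takes one power value per second over a 60 s
eyes-open and a 60 s eyes-closed phase and sets
`θ = 1.05 × (mean(P_EO) + mean(P_EC)) / 2` — the factor and the averaging
rule are stated by the emulated protocol and are asserted exactly. The run
phase then evaluates the trailing 1 s window at each 4 s epoch boundary
(0.25 Hz): power *strictly* above θ turns stimulation on for the first 2 s
of the epoch that begins at that boundary — i.e. one epoch after the
activity that produced the decision. The trailing-window reading and the
strict inequality are choices the source protocol leaves open; both are
fixed and documented here. The stimulation waveform is
`A sin(2π · 40 · (t − epoch start))`: 80 cycles in 2 s, zero-crossing at
the epoch start. The dose-matched random arm counts the feedback arm's
stimulation epochs and delivers the same number at seeded uniform-random
epoch positions, independent of measured power.

A numerical caveat: the band-pass runs as an order-12 direct-form
recursion with poles of radius ≈ 0.9974, which amplifies float rounding;
the streaming and vectorized paths agree to ~1e-5 relative rather than to
machine precision, and the suite's equivalence tolerances reflect that.
The filter is causal by construction — no output sample depends on future
input — which is the streaming contract; an offline zero-phase filter
would produce different (acausal) output and is deliberately not used.

## Synthetic fixtures

All generators are pure functions of their specification and seed.

* **Trigger trains** place exactly n rectangular 0→5 V pulses in a
  duration, with gaps of a minimum spacing plus a uniform share of the
  remaining slack. "Randomly triggered" is under-specified by the source
  material; uniform jitter around the mean interval is this package's
  model of it, and the pulse width defaults to half the nominal period of
  the equivalent 50%-duty square waveform.
* **Songs** repeat a motif of three spectrally distinct syllables
  (harmonic stacks at 2 and 4 kHz, a 3→5 kHz sweep; 40–80 ms) separated
  by ~80 ms gaps with Gaussian jitter, over an optional noise floor
  (default 0, so the RMS gate is provably quiet between syllables).
  Ground-truth onsets are returned for scoring.
* **EEG** is pink (1/f) noise plus a 10 Hz sinusoid whose amplitude
  follows the eye-state schedule (defaults: amplitude 1 eyes-open, 3
  eyes-closed, on a unit-SD background — cleanly separated states, chosen
  so gating accuracy is a property of the controller, not of a classifier
  fighting noise). The standard session schedule is 60 s EO + 60 s EC
  calibration followed by either constant EO or 30 s EO/EC alternation.

Passing tests on these fixtures establish the *mechanics* — gating,
ordering, latency, determinism, round-trips — under clean, well-separated
conditions. They do not establish detection rates on real song, alpha
suppression in real cortex, or scheduling jitter on real hardware; the
biological and hardware-distribution results of the emulated experiments
are outside what a simulation of this kind can reproduce.

## Problem sizes used by the suite

The characterization run reproduces the full bench condition — 30
simulated minutes at 20 kHz (36 million cycles) with 1800 trigger events,
analyzed on a 250 kHz sampler grid — via the chunked loopback path. The
neuron-in-the-loop determinism check records one second at 20 kHz; the
syllable-detection equivalence uses about a minute of synthetic song at
30 kHz; controller sessions in the unit tests use shortened calibration
phases (the calibration length is a parameter) with the full 12-minute
session exercised through the session helper. These sizes are the
package's choice of a thorough-but-quick default; every one of them scales
up by changing a single argument.

## Known limitations

* No kernel preemption, interrupt handling, or memory locking is
  modelled; wallclock mode is best-effort by design.
* Scalar ports only (one sample per cycle); buffered data lives inside
  modules, as in the DAF detector's ring buffer.
* The recorder buffers a trial in memory and writes at stop; streaming
  writes for very long high-rate recorded trials are out of scope (the
  chunked loopback path records incrementally but still flushes at stop).
* The order-12 direct-form band-pass trades a few digits of agreement
  between its two execution paths for implementation simplicity, as noted
  above.
* WAV support is minimal mono 16-bit PCM, sufficient for the audio
  fixtures.
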